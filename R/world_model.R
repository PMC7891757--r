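# AOI world model: the ordered registry of named panel regions that turns
# gaze coordinates into symbols and supplies the geometry behind transition
# amplitudes. Region order (by id) fixes the row/column order of every
# transition matrix downstream.

#' Construct an AOI region
#'
#' An AOI (area of interest) is a named planar region of the instrument
#' panel, either an axis-aligned rectangle or a simple polygon. Region ids
#' are small positive integers; id 0 is reserved for "outside all AOIs" and
#' may not be used for a region.
#'
#' @param id Positive integer region index.
#' @param label Short region name (e.g. `"ATT"`, `"OTW"`).
#' @param rect Numeric length-4 vector `c(xmin, ymin, xmax, ymax)`, or `NULL`.
#' @param polygon Two-column numeric matrix of vertices (one row per vertex,
#'   not closed), or `NULL`. Exactly one of `rect`/`polygon` must be given.
#' @return A list of class `"aoi_region"` with the shape, its area and its
#'   centroid (area centroid for polygons).
#' @export
aoi_region <- function(id, label, rect = NULL, polygon = NULL) {
  if (!is_count(id) || id < 1)
    stop_input("AOI id must be a positive integer (0 is reserved for 'outside')")
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_input("AOI label must be a non-empty string")
  if (is.null(rect) == is.null(polygon))
    stop_input("exactly one of 'rect' or 'polygon' must be supplied")
  if (!is.null(rect)) {
    rect <- as.numeric(rect)
    if (length(rect) != 4L || any(!is.finite(rect)))
      stop_input("'rect' must be c(xmin, ymin, xmax, ymax)")
    if (rect[3] <= rect[1] || rect[4] <= rect[2])
      stop_input("degenerate rectangle for AOI ", id, " ('", label,
                 "'): needs positive width and height")
    centroid <- c((rect[1] + rect[3]) / 2, (rect[2] + rect[4]) / 2)
    area <- (rect[3] - rect[1]) * (rect[4] - rect[2])
    shape <- list(type = "rect", rect = rect)
  } else {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L || any(!is.finite(polygon)))
      stop_input("'polygon' must be a numeric matrix with >= 3 rows and 2 columns")
    ca <- polygon_centroid_area(polygon)
    if (ca$area <= 0)
      stop_input("degenerate polygon for AOI ", id, " ('", label,
                 "'): zero or negative area")
    centroid <- ca$centroid
    area <- ca$area
    shape <- list(type = "polygon", vertices = polygon)
  }
  structure(
    list(id = as.integer(id), label = label, shape = shape,
         centroid = centroid, area = area),
    class = "aoi_region"
  )
}

# Signed-area centroid of a simple polygon; area returned as absolute value.
polygon_centroid_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a2 <- sum(cross)
  if (abs(a2) < .Machine$double.eps * 100)
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  cx <- sum((x + xn) * cross) / (3 * a2)
  cy <- sum((y + yn) * cross) / (3 * a2)
  list(area = abs(a2) / 2, centroid = c(cx, cy))
}

#' Construct and validate a world model
#'
#' @param regions List of [aoi_region()] objects.
#' @param units Single string naming the coordinate unit shared by all
#'   regions (e.g. `"cm"` or `"deg"`); it is carried through opaquely into
#'   transition amplitudes.
#' @return A list of class `"world_model"` with `regions` sorted by id,
#'   `units`, and the AOI count `m`.
#' @details Ids must be unique and contiguous from 1; at least two regions
#'   are required. Region order by id defines the row/column order of every
#'   transition matrix computed from the model.
#' @export
world_model <- function(regions, units = "unit") {
  if (!is.list(regions) || length(regions) < 2L)
    stop_input("a world model needs at least 2 regions")
  if (!all(vapply(regions, inherits, logical(1), "aoi_region")))
    stop_input("'regions' must be a list of aoi_region objects")
  ids <- vapply(regions, `[[`, integer(1), "id")
  if (anyDuplicated(ids))
    stop_input("duplicate AOI id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!setequal(ids, seq_along(ids)))
    stop_input("AOI ids must be contiguous from 1 (got ",
               paste(sort(ids), collapse = ", "), ")")
  regions <- regions[order(ids)]
  structure(
    list(regions = regions, units = as.character(units)[1],
         m = length(regions)),
    class = "world_model"
  )
}

#' @export
print.world_model <- function(x, ...) {
  cat("World model:", x$m, "AOIs (units:", x$units, ")\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.world_model <- function(x, ...) {
  data.frame(
    id = vapply(x$regions, `[[`, integer(1), "id"),
    label = vapply(x$regions, `[[`, character(1), "label"),
    cx = vapply(x$regions, function(r) r$centroid[1], numeric(1)),
    cy = vapply(x$regions, function(r) r$centroid[2], numeric(1)),
    area = vapply(x$regions, `[[`, numeric(1), "area")
  )
}

#' AOI labels of a world model, in id order
#' @param model A [world_model()].
#' @return Character vector of length `model$m`.
#' @export
aoi_labels <- function(model) {
  stopifnot(inherits(model, "world_model"))
  vapply(model$regions, `[[`, character(1), "label")
}

#' Load a world model from a JSON configuration
#'
#' The schema is a JSON object with a `units` string and a `regions` array;
#' each region has `id`, `label`, and either `rect` (`[xmin, ymin, xmax,
#' ymax]`) or `polygon` (array of `[x, y]` vertices). See
#' `system.file("extdata", "default_world_model.json", package = "aoiscan")`
#' for a complete example.
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A [world_model()].
#' @export
load_world_model <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$regions) || length(cfg$regions) < 2L)
    stop_input("world-model configuration must list at least 2 regions")
  regions <- lapply(cfg$regions, function(r) {
    if (is.null(r$id) || is.null(r$label))
      stop_input("every region needs an 'id' and a 'label'")
    if (!is.null(r$rect)) {
      aoi_region(r$id, r$label, rect = unlist(r$rect))
    } else if (!is.null(r$polygon)) {
      aoi_region(r$id, r$label,
                 polygon = do.call(rbind, lapply(r$polygon, unlist)))
    } else {
      stop_input("region ", r$id, " has neither 'rect' nor 'polygon'")
    }
  })
  world_model(regions, units = cfg$units %||% "unit")
}

#' Serialize a world model to its JSON configuration
#' @param model A [world_model()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_world_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "world_model"))
  regions <- lapply(model$regions, function(r) {
    base <- list(id = r$id, label = r$label)
    if (r$shape$type == "rect") base$rect <- r$shape$rect
    else base$polygon <- apply(r$shape$vertices, 1, identity, simplify = FALSE)
    base
  })
  json <- jsonlite::toJSON(list(units = model$units, regions = regions),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' The bundled 10-AOI cockpit world model
#'
#' A schematic planar layout of the ten cockpit AOIs used throughout the
#' package: the five primary-flight-display sub-regions (ATT, SPD, VS, FMA,
#' HDG) clustered together, the navigation display (ND) with its distance
#' read-out zone (NDz) beside them, the flight control unit (FCU) above the
#' displays, the ECAM to the right, and the out-the-window view (OTW)
#' spanning the top. Coordinates are in centimetres on a schematic panel;
#' only relative geometry matters, since every metric except the
#' amplitude-based coefficient K is geometry-free.
#'
#' @return A [world_model()] with `m = 10`.
#' @export
default_world_model <- function() {
  path <- system.file("extdata", "default_world_model.json",
                      package = "aoiscan", mustWork = TRUE)
  load_world_model(path)
}

region_by_id <- function(model, id) {
  if (!is_count(id) || id < 1 || id > model$m)
    stop_input("unknown AOI id: ", id)
  model$regions[[id]]
}

#' Distance between two AOI centroids
#'
#' Euclidean distance, in the model's declared units, between the centroids
#' of AOIs `i` and `j`; used as the transition amplitude when per-dwell gaze
#' positions are unavailable.
#'
#' @param model A [world_model()].
#' @param i,j AOI ids.
#' @return Non-negative length; zero iff `i == j`.
#' @export
aoi_distance <- function(model, i, j) {
  stopifnot(inherits(model, "world_model"))
  ci <- region_by_id(model, i)$centroid
  cj <- region_by_id(model, j)$centroid
  sqrt(sum((ci - cj)^2))
}

#' Full pairwise AOI centroid distance matrix
#' @param model A [world_model()].
#' @return Symmetric `m x m` matrix with zero diagonal, labelled by AOI.
#' @export
aoi_distance_matrix <- function(model) {
  stopifnot(inherits(model, "world_model"))
  cc <- cbind(
    vapply(model$regions, function(r) r$centroid[1], numeric(1)),
    vapply(model$regions, function(r) r$centroid[2], numeric(1))
  )
  d <- as.matrix(stats::dist(cc))
  dimnames(d) <- list(aoi_labels(model), aoi_labels(model))
  d
}

#' Resolve gaze positions to AOI ids
#'
#' Maps planar gaze coordinates to the id of the first region (in id order)
#' containing the point, or 0 when the point falls in no region. Rectangle
#' boundaries are inclusive; polygon membership uses even-odd ray casting.
#'
#' @param model A [world_model()].
#' @param x,y Numeric coordinate vectors of equal length.
#' @return Integer vector of AOI ids (0 = outside); non-finite coordinates
#'   resolve to 0.
#' @export
resolve_aoi <- function(model, x, y) {
  stopifnot(inherits(model, "world_model"), length(x) == length(y))
  out <- integer(length(x))
  for (r in model$regions) {
    unassigned <- out == 0L
    if (!any(unassigned)) break
    inside <- if (r$shape$type == "rect") {
      rc <- r$shape$rect
      x >= rc[1] & x <= rc[3] & y >= rc[2] & y <= rc[4]
    } else {
      point_in_polygon(x, y, r$shape$vertices)
    }
    inside[!is.finite(x) | !is.finite(y)] <- FALSE
    out[unassigned & inside] <- r$id
  }
  out
}

point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & is.finite(px))
    j <- i
  }
  inside
}
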