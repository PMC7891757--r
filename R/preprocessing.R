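# Raw gaze streams -> cleaned dwell sequences -> transition records.
# Pipeline order: segment maximal same-AOI runs, drop sub-threshold and
# off-AOI dwells, merge adjacent same-AOI dwells, then derive transitions.

#' Construct a gaze sample stream
#'
#' @param aoi Integer vector of per-sample AOI ids (0 = outside all AOIs).
#' @param time Optional strictly increasing sample times (s); defaults to a
#'   regular grid at `rate`.
#' @param x,y Optional per-sample gaze coordinates in world-model units.
#' @param rate Nominal sampling rate in Hz (default 60).
#' @param source_id Optional recording identifier carried into downstream
#'   objects.
#' @return A list of class `"gaze_stream"`.
#' @export
gaze_stream <- function(aoi, time = NULL, x = NULL, y = NULL, rate = 60,
                        source_id = NULL) {
  n <- length(aoi)
  if (n == 0L) stop_input("empty gaze stream")
  aoi <- as.integer(aoi)
  if (anyNA(aoi) || any(aoi < 0L)) stop_input("AOI ids must be >= 0 (0 = outside)")
  if (is.null(time)) time <- (seq_len(n) - 1L) / rate
  if (length(time) != n) stop_input("'time' and 'aoi' lengths differ")
  if (any(diff(time) <= 0)) stop_input("timestamps must be strictly increasing")
  for (v in list(x, y)) {
    if (!is.null(v) && length(v) != n)
      stop_input("position vectors must match the number of samples")
  }
  structure(
    list(time = as.numeric(time), aoi = aoi,
         x = if (is.null(x)) NULL else as.numeric(x),
         y = if (is.null(y)) NULL else as.numeric(y),
         rate = rate, source_id = source_id),
    class = "gaze_stream"
  )
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat("Gaze stream:", length(x$aoi), "samples at", x$rate, "Hz (",
      round(length(x$aoi) / x$rate, 1), "s );",
      sum(x$aoi == 0L), "off-AOI samples\n")
  invisible(x)
}

#' Read a gaze log from delimited text
#'
#' Expects a header with either an `aoi` column (pre-resolved ids) or `x`/`y`
#' columns to be resolved against a world model, plus an optional `time`
#' column.
#'
#' @param path Path to a CSV/TSV file.
#' @param model A [world_model()]; required when only positions are logged.
#' @param rate Sampling rate in Hz.
#' @param sep Field separator (default `","`).
#' @return A [gaze_stream()].
#' @export
read_gaze_log <- function(path, model = NULL, rate = 60, sep = ",") {
  df <- utils::read.csv(path, sep = sep)
  time <- if ("time" %in% names(df)) df$time else NULL
  if ("aoi" %in% names(df)) {
    gaze_stream(df$aoi, time = time,
                x = if ("x" %in% names(df)) df$x else NULL,
                y = if ("y" %in% names(df)) df$y else NULL,
                rate = rate, source_id = basename(path))
  } else if (all(c("x", "y") %in% names(df))) {
    if (is.null(model))
      stop_input("gaze log has no 'aoi' column; a world model is required ",
                 "to resolve positions")
    aoi <- resolve_aoi(model, df$x, df$y)
    gaze_stream(aoi, time = time, x = df$x, y = df$y, rate = rate,
                source_id = basename(path))
  } else {
    stop_input("gaze log must contain an 'aoi' column or 'x' and 'y' columns")
  }
}

#' Keep only the final portion of a stream
#'
#' Recordings of a scenario differ slightly in length, so analyses use a
#' common duration by cutting the beginning and keeping exactly the final
#' `n_frames` samples.
#'
#' @param stream A [gaze_stream()].
#' @param n_frames Number of trailing samples to retain.
#' @return The trimmed [gaze_stream()].
#' @export
trim_to_duration <- function(stream, n_frames) {
  stopifnot(inherits(stream, "gaze_stream"))
  n <- length(stream$aoi)
  if (!is_count(n_frames) || n_frames < 1) stop_input("'n_frames' must be a positive count")
  if (n < n_frames)
    stop_input("stream has ", n, " frames, fewer than the requested ", n_frames)
  keep <- seq.int(n - n_frames + 1L, n)
  out <- stream
  out$time <- stream$time[keep]
  out$aoi <- stream$aoi[keep]
  if (!is.null(stream$x)) out$x <- stream$x[keep]
  if (!is.null(stream$y)) out$y <- stream$y[keep]
  out
}

#' Number of whole slower-rate frames spanning a gaze recording
#'
#' Companion traces (e.g. flight parameters at 1 Hz) are aligned to a gaze
#' recording by taking the number of whole slow-rate frames its duration
#' spans: `floor(n_gaze_frames / gaze_rate * slow_rate)`. At the defaults
#' (14,000 gaze frames at 60 Hz, 1 Hz traces) this is 233 frames.
#'
#' @param n_gaze_frames Gaze sample count.
#' @param gaze_rate Gaze sampling rate (Hz).
#' @param slow_rate Companion trace rate (Hz).
#' @return Integer frame count.
#' @export
companion_frames <- function(n_gaze_frames, gaze_rate = 60, slow_rate = 1) {
  stopifnot(is_count(n_gaze_frames), n_gaze_frames >= 0)
  as.integer(floor(n_gaze_frames / gaze_rate * slow_rate))
}

new_dwell_sequence <- function(df, source_id = NULL, rate = NULL,
                               stream_duration = NULL) {
  rownames(df) <- NULL
  structure(df,
            source_id = source_id, rate = rate,
            stream_duration = stream_duration,
            class = c("dwell_sequence", "data.frame"))
}

#' @export
print.dwell_sequence <- function(x, ...) {
  cat("Dwell sequence:", nrow(x), "dwells")
  if (!is.null(attr(x, "source_id"))) cat(" [", attr(x, "source_id"), "]")
  cat("\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Segment a gaze stream into raw dwells
#'
#' Run-length encodes the per-sample AOI ids: every maximal run of identical
#' ids becomes one dwell with `duration = run length / rate`. Off-AOI runs
#' are kept as id-0 dwells at this stage (they are removed by
#' [clean_sequence()]). Mean gaze position per dwell is recorded when the
#' stream carries positions.
#'
#' @param stream A [gaze_stream()].
#' @return A `dwell_sequence`: a data frame with columns `aoi`, `onset`,
#'   `duration` (and `x`, `y` when available), carrying the stream duration
#'   and rate as attributes.
#' @export
segment_dwells <- function(stream) {
  stopifnot(inherits(stream, "gaze_stream"))
  r <- rle(stream$aoi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(
    aoi = r$values,
    onset = stream$time[starts],
    duration = r$lengths / stream$rate
  )
  if (!is.null(stream$x)) {
    df$x <- vapply(seq_along(starts), function(k)
      mean(stream$x[starts[k]:ends[k]]), numeric(1))
    df$y <- vapply(seq_along(starts), function(k)
      mean(stream$y[starts[k]:ends[k]]), numeric(1))
  }
  new_dwell_sequence(df, source_id = stream$source_id, rate = stream$rate,
                     stream_duration = length(stream$aoi) / stream$rate)
}

#' Clean a dwell sequence
#'
#' Applies the two-step cleaning rule: (1) discard dwells shorter than
#' `min_dwell` (default 200 ms) and all off-AOI (id 0) dwells; (2) merge
#' adjacent dwells that now share an AOI, summing their durations (so e.g.
#' the label sequence 1,1,4,4,5,5,5,6 reduces to 1,4,5,6). The result has no
#' two consecutive dwells in the same AOI. Filtering precedes merging;
#' reversing the order yields different sequences. The operation is
#' idempotent.
#'
#' @param seq A `dwell_sequence` from [segment_dwells()].
#' @param min_dwell Minimum retained dwell duration in seconds.
#' @return The cleaned `dwell_sequence`; empty (with a warning) when nothing
#'   survives.
#' @export
clean_sequence <- function(seq, min_dwell = 0.2) {
  stopifnot(inherits(seq, "dwell_sequence"))
  df <- as.data.frame(seq)
  df <- df[df$aoi >= 1L & df$duration >= min_dwell, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no dwells survive cleaning; returning an empty sequence")
    return(new_dwell_sequence(df, source_id = attr(seq, "source_id"),
                              rate = attr(seq, "rate"),
                              stream_duration = attr(seq, "stream_duration")))
  }
  grp <- cumsum(c(1L, diff(df$aoi) != 0L))
  has_pos <- all(c("x", "y") %in% names(df))
  merged <- data.frame(
    aoi = df$aoi[!duplicated(grp)],
    onset = df$onset[!duplicated(grp)],
    duration = as.numeric(tapply(df$duration, grp, sum))
  )
  if (has_pos) {
    w <- df$duration
    merged$x <- as.numeric(tapply(df$x * w, grp, sum) / tapply(w, grp, sum))
    merged$y <- as.numeric(tapply(df$y * w, grp, sum) / tapply(w, grp, sum))
  }
  new_dwell_sequence(merged, source_id = attr(seq, "source_id"),
                     rate = attr(seq, "rate"),
                     stream_duration = attr(seq, "stream_duration"))
}

#' Derive transition records from a cleaned dwell sequence
#'
#' One record per consecutive dwell pair: `from`/`to` AOI ids and the
#' transition amplitude — the distance between the two dwells' mean gaze
#' positions when the sequence carries positions, otherwise the centroid
#' distance of the two AOIs in the world model.
#'
#' @param seq A cleaned `dwell_sequence` (no consecutive same-AOI dwells).
#' @param model A [world_model()]; required when the sequence has no
#'   positions.
#' @return Data frame with columns `from`, `to`, `amplitude`; `nrow ==
#'   nrow(seq) - 1`.
#' @export
build_transitions <- function(seq, model = NULL) {
  stopifnot(inherits(seq, "dwell_sequence"))
  n <- nrow(seq)
  if (n >= 2L && any(seq$aoi[-1] == seq$aoi[-n]))
    stop_input("sequence has consecutive same-AOI dwells; run clean_sequence() first")
  if (n < 2L)
    return(data.frame(from = integer(0), to = integer(0), amplitude = numeric(0)))
  from <- seq$aoi[-n]; to <- seq$aoi[-1]
  if (all(c("x", "y") %in% names(seq))) {
    amplitude <- sqrt(diff(seq$x)^2 + diff(seq$y)^2)
  } else {
    if (is.null(model))
      stop_input("sequence has no positions; a world model is required for amplitudes")
    d <- aoi_distance_matrix(model)
    amplitude <- d[cbind(from, to)]
  }
  data.frame(from = from, to = to, amplitude = as.numeric(amplitude))
}

#' Write a dwell table to CSV
#' @param seq A `dwell_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dwells <- function(seq, path) {
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE)
  invisible(path)
}
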