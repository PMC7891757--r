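# Flight-performance scoring: RMSE of parameter traces against instructed
# point or band targets, and dual-task callout omission counting.

#' Specify an instructed flight-parameter target
#'
#' @param kind `"point"` (a single instructed value, e.g. 130 kt) or
#'   `"band"` (a tolerated range, e.g. vertical speed between -800 and +500
#'   ft/min).
#' @param value Target value (point targets).
#' @param low,high Band bounds, `low < high` (band targets).
#' @param units Parameter units label (kt, ft/min, deg, ...).
#' @return A list of class `"target_spec"`.
#' @export
target_spec <- function(kind = c("point", "band"), value = NULL,
                        low = NULL, high = NULL, units = "") {
  kind <- match.arg(kind)
  if (kind == "point") {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
      stop_input("point target needs a single finite 'value'")
    spec <- list(kind = kind, value = value, units = units)
  } else {
    if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
        length(high) != 1L || !(low < high))
      stop_input("band target needs finite bounds with low < high")
    spec <- list(kind = kind, low = low, high = high, units = units)
  }
  structure(spec, class = "target_spec")
}

#' RMSE of a parameter trace against its target
#'
#' Root mean square of per-sample errors
#' \deqn{RMSE = \sqrt{\tfrac{1}{n}\sum_i (O_i - P_i)^2}}
#' where for a point target the error is the signed deviation from the
#' instructed value, and for a band target the error is zero inside
#' `[low, high]` and the distance to the nearest bound outside it. The
#' result is in the parameter's own units and invariant to sample
#' reordering.
#'
#' @param values Observed parameter samples (numeric vector), or a list with
#'   a `values` element (a parameter trace).
#' @param target A [target_spec()].
#' @return The RMSE (non-negative scalar).
#' @export
rmse_deviation <- function(values, target) {
  if (is.list(values) && !is.null(values$values)) values <- values$values
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) stop_input("empty or NA trace")
  stopifnot(inherits(target, "target_spec"))
  err <- if (target$kind == "point") {
    values - target$value
  } else {
    pmax(0, target$low - values) + pmax(0, values - target$high)
  }
  sqrt(mean(err^2))
}

#' Read a flight-parameter trace log
#'
#' Delimited text with a `time` column plus one column per parameter
#' (e.g. `speed`, `vertical_speed`, `heading`).
#'
#' @param path CSV path.
#' @param sep Field separator.
#' @return Named list of traces, each `list(time, values)`.
#' @export
read_flight_log <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep)
  if (!"time" %in% names(df)) stop_input("flight log needs a 'time' column")
  params <- setdiff(names(df), "time")
  if (length(params) == 0L) stop_input("flight log has no parameter columns")
  stats::setNames(
    lapply(params, function(p) list(time = df$time, values = df[[p]])),
    params
  )
}

#' Count omitted distance callouts
#'
#' Matches produced callout distances to the expected marks of the dual
#' task (e.g. every 0.5 Nm from 5.0 Nm on approach): each call can satisfy
#' at most one mark, pairs are formed greedily by increasing distance
#' between call and mark, and only pairs within `tolerance` count. The
#' omissions are the expected marks left unmatched.
#'
#' @param expected_marks Strictly decreasing distances (Nm) at which a
#'   callout was required.
#' @param produced_calls Distances (Nm) at which callouts were actually
#'   made; may be empty.
#' @param tolerance Maximum |call - mark| for a match, in Nm (default 0.1).
#' @return Integer omission count in `[0, length(expected_marks)]`.
#' @export
count_omissions <- function(expected_marks, produced_calls, tolerance = 0.1) {
  expected_marks <- as.numeric(expected_marks)
  if (length(expected_marks) == 0L) return(0L)
  if (any(diff(expected_marks) >= 0))
    stop_input("'expected_marks' must be strictly decreasing (approach order)")
  produced_calls <- as.numeric(produced_calls)
  if (length(produced_calls) == 0L) return(length(expected_marks))
  pairs <- expand.grid(mark = seq_along(expected_marks),
                       call = seq_along(produced_calls))
  pairs$gap <- abs(expected_marks[pairs$mark] - produced_calls[pairs$call])
  pairs <- pairs[pairs$gap <= tolerance, , drop = FALSE]
  pairs <- pairs[order(pairs$gap), , drop = FALSE]
  matched_mark <- logical(length(expected_marks))
  matched_call <- logical(length(produced_calls))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$mark[r]; j <- pairs$call[r]
    if (!matched_mark[i] && !matched_call[j]) {
      matched_mark[i] <- TRUE
      matched_call[j] <- TRUE
    }
  }
  sum(!matched_mark)
}

#' Expected callout marks for a dual-task approach
#'
#' @param from First mark distance in Nm (default 5.0).
#' @param step Mark spacing in Nm (0.5 for the easy task, 0.2 for the hard
#'   one).
#' @param to Last mark distance (default `step`, i.e. marks run down to one
#'   step from the threshold).
#' @return Strictly decreasing numeric vector of mark distances.
#' @export
callout_marks <- function(from = 5.0, step = 0.5, to = step) {
  if (step <= 0 || from < to) stop_input("need step > 0 and from >= to")
  marks <- seq(from, to, by = -step)
  round(marks, 10)
}
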