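# Ambient/focal coefficient K: per dwell-transition pair, the difference
# between the standardized dwell duration and the standardized amplitude of
# the following transition. K > 0 marks focal attention (long dwells, short
# transitions), K < 0 ambient attention.

#' Ambient/focal coefficient K
#'
#' For each recording, pairs the i-th dwell duration `d_i` with the
#' amplitude `a_{i+1}` of the transition that follows it and computes
#' \deqn{\kappa_i = \frac{d_i - \mu_d}{\rho_d} - \frac{a_{i+1} - \mu_a}{\rho_a}}
#' with K the mean of the `kappa_i`. The means and standard deviations are
#' taken either over each recording separately (`scope = "per-recording"`)
#' or over all recordings of the dataset concatenated (`scope = "pooled"`,
#' the default). All dwell durations — including the final dwell, which has
#' no following transition — enter `mu_d`/`rho_d`, and all amplitudes enter
#' `mu_a`/`rho_a`.
#'
#' Per-recording standardization forces each recording's K to
#' `-z(d_last)/n_pairs` (the z-scores sum to zero), so group contrasts in K
#' require the pooled scope; the per-recording mode is retained for
#' windowed, within-recording use.
#'
#' @param recordings A single recording — a list with numeric `durations`
#'   (length `n`) and `amplitudes` (length `n - 1`) — or a list of such
#'   recordings.
#' @param scope `"pooled"` or `"per-recording"` standardization.
#' @param sd_denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return A list of class `"k_result_set"`: one element per recording, each
#'   with `k_series`, `k_mean`, `n_pairs`, and the standardization metadata.
#' @export
coefficient_k <- function(recordings,
                          scope = c("pooled", "per-recording"),
                          sd_denominator = c("sample", "population")) {
  scope <- match.arg(scope)
  sd_denominator <- match.arg(sd_denominator)
  if (is.list(recordings) && !is.null(recordings$durations))
    recordings <- list(recordings)
  if (!is.list(recordings) || length(recordings) == 0L)
    stop_input("'recordings' must be one recording or a non-empty list of them")
  for (k in seq_along(recordings)) {
    r <- recordings[[k]]
    if (is.null(r$durations) || is.null(r$amplitudes))
      stop_input("recording ", k, " lacks 'durations' or 'amplitudes'")
    if (length(r$durations) < 2L || length(r$amplitudes) != length(r$durations) - 1L)
      stop_input("recording ", k, ": need >= 2 dwells and exactly ",
                 "length(durations) - 1 amplitudes")
    if (scope == "per-recording" && length(r$amplitudes) < 2L)
      stop_input("recording ", k, ": per-recording standardization needs ",
                 ">= 2 dwell-transition pairs")
  }
  sdev <- function(x) {
    s <- stats::sd(x)
    if (sd_denominator == "population")
      s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  check_spread <- function(s, channel) {
    if (!is.finite(s) || s == 0)
      stop_input("zero variance in the ", channel,
                 " channel; K is undefined (no z-score exists)")
    s
  }
  if (scope == "pooled") {
    all_d <- unlist(lapply(recordings, `[[`, "durations"))
    all_a <- unlist(lapply(recordings, `[[`, "amplitudes"))
    if (length(all_a) < 2L)
      stop_input("pooled standardization needs >= 2 amplitudes overall")
    mu_d <- mean(all_d); rho_d <- check_spread(sdev(all_d), "dwell-duration")
    mu_a <- mean(all_a); rho_a <- check_spread(sdev(all_a), "amplitude")
  }
  out <- lapply(recordings, function(r) {
    d <- as.numeric(r$durations); a <- as.numeric(r$amplitudes)
    if (scope == "per-recording") {
      mu_d <- mean(d); rho_d <- check_spread(sdev(d), "dwell-duration")
      mu_a <- mean(a); rho_a <- check_spread(sdev(a), "amplitude")
    }
    n_pairs <- length(a)
    kappa <- (d[seq_len(n_pairs)] - mu_d) / rho_d - (a - mu_a) / rho_a
    list(k_series = kappa, k_mean = mean(kappa), n_pairs = n_pairs,
         standardization_scope = scope, sd_denominator = sd_denominator)
  })
  structure(out, class = "k_result_set")
}

#' @export
print.k_result_set <- function(x, ...) {
  km <- vapply(x, `[[`, numeric(1), "k_mean")
  cat("Coefficient K (", x[[1]]$standardization_scope, " scope): ",
      length(x), " recording(s), mean K = ",
      paste(round(km, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.k_result_set <- function(x, ...) {
  data.frame(
    recording = seq_along(x),
    k_mean = vapply(x, `[[`, numeric(1), "k_mean"),
    n_pairs = vapply(x, `[[`, numeric(1), "n_pairs"),
    standardization_scope = vapply(x, `[[`, character(1),
                                   "standardization_scope")
  )
}

#' Dwell-amplitude pairs of a cleaned recording
#'
#' Convenience bridge from the preprocessing output to [coefficient_k()]:
#' extracts the dwell durations and following-transition amplitudes.
#'
#' @param seq A cleaned `dwell_sequence`.
#' @param model A [world_model()] for centroid amplitudes when the sequence
#'   has no positions.
#' @return List with `durations` and `amplitudes`, suitable as one
#'   recording for [coefficient_k()].
#' @export
k_input <- function(seq, model = NULL) {
  tr <- build_transitions(seq, model)
  list(durations = seq$duration, amplitudes = tr$amplitude)
}
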