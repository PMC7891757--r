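# First-order Markov statistics of the AOI transition vector: count and
# row-normalized probability matrices, matrix density, stationary
# distributions, gaze transition entropy, and basic dwell statistics.

#' Build a first-order transition matrix
#'
#' Tallies `from -> to` AOI moves into an `m x m` count matrix (rows = from,
#' columns = to, in world-model AOI order) and row-normalizes it into
#' conditional probabilities `p(j|i)`; rows with no outgoing transitions stay
#' all-zero. Cleaned sequences have no self-transitions, so the diagonal is
#' zero.
#'
#' @param transitions Data frame with integer columns `from` and `to` (as
#'   produced by [build_transitions()]), or a cleaned `dwell_sequence` whose
#'   consecutive labels are used directly.
#' @param m AOI count (matrix dimension).
#' @param labels Optional AOI labels for dimnames.
#' @return A list of class `"transition_matrix"` with elements `counts`,
#'   `probabilities`, `m` and `n_transitions`.
#' @export
transition_matrix <- function(transitions, m, labels = NULL) {
  if (inherits(transitions, "dwell_sequence")) {
    lab <- transitions$aoi
    n <- length(lab)
    if (n >= 2L && any(lab[-1] == lab[-n]))
      stop_input("dwell sequence has consecutive repeats; clean it first")
    transitions <- if (n >= 2L)
      data.frame(from = lab[-n], to = lab[-1]) else
      data.frame(from = integer(0), to = integer(0))
  }
  if (!is_count(m) || m < 1) stop_input("'m' must be a positive count")
  from <- as.integer(transitions$from); to <- as.integer(transitions$to)
  if (length(from) && (any(from < 1L | from > m) || any(to < 1L | to > m)))
    stop_input("AOI ids outside 1..", m)
  counts <- matrix(0L, m, m)
  if (length(from)) {
    tab <- table(factor(from, levels = seq_len(m)),
                 factor(to, levels = seq_len(m)))
    counts <- matrix(as.integer(tab), m, m)
  }
  if (is.null(labels)) labels <- as.character(seq_len(m))
  dimnames(counts) <- list(from = labels, to = labels)
  rs <- rowSums(counts)
  probabilities <- counts / ifelse(rs > 0, rs, 1)
  structure(
    list(counts = counts, probabilities = probabilities, m = m,
         n_transitions = sum(counts)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix:", x$m, "AOIs,", x$n_transitions, "transitions,",
      "density", round(matrix_density(x), 3), "\n")
  invisible(x)
}

#' Transition matrix density
#'
#' Fraction of matrix cells holding at least one transition, out of all
#' `m^2` cells (diagonal included in the denominator, so cleaned sequences
#' are capped at `m(m-1)/m^2`). High density reflects dispersed, wandering
#' scanning; low density a concentrated scan.
#'
#' @param tm A [transition_matrix()].
#' @return Fraction in `[0, 1]`; 0 for an empty matrix.
#' @export
matrix_density <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  sum(tm$counts >= 1L) / tm$m^2
}

#' Stationary AOI distribution
#'
#' The weight vector `p(i)` over source AOIs used by
#' [gaze_transition_entropy()]. Two estimates are available:
#' `"dwell-proportion"` (default) — the observed share of dwells per AOI;
#' `"eigenvector"` — the left stationary vector of the transition
#' probability matrix, defined only when the chain restricted to visited
#' AOIs is irreducible.
#'
#' @param x A `dwell_sequence` (either mode) or a [transition_matrix()]
#'   (eigenvector mode only).
#' @param m AOI count; taken from `x` when it is a transition matrix.
#' @param mode `"dwell-proportion"` or `"eigenvector"`.
#' @return Probability vector of length `m` summing to 1; AOIs never visited
#'   get weight 0.
#' @export
stationary_distribution <- function(x, m = NULL,
                                    mode = c("dwell-proportion", "eigenvector")) {
  mode <- match.arg(mode)
  if (mode == "dwell-proportion") {
    if (!inherits(x, "dwell_sequence"))
      stop_input("dwell-proportion mode needs a dwell sequence")
    if (nrow(x) == 0L) stop_input("empty dwell sequence")
    if (is.null(m)) m <- max(x$aoi)
    tab <- tabulate(x$aoi, nbins = m)
    return(tab / sum(tab))
  }
  tm <- if (inherits(x, "transition_matrix")) x else {
    if (is.null(m)) m <- max(x$aoi)
    transition_matrix(x, m)
  }
  m <- tm$m
  active <- rowSums(tm$counts) > 0 | colSums(tm$counts) > 0
  if (!any(active)) stop_input("empty transition matrix")
  idx <- which(active)
  P <- tm$probabilities[idx, idx, drop = FALSE]
  reach <- strongly_connected(tm$counts[idx, idx, drop = FALSE] > 0)
  if (!reach$connected) {
    labs <- rownames(tm$counts)[idx][reach$stranded]
    stop_input("transition chain is reducible; unreachable AOI(s): ",
               paste(labs, collapse = ", "))
  }
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, k]))
  p <- numeric(m)
  p[idx] <- v / sum(v)
  p
}

# Strong connectivity of a boolean adjacency matrix via transitive closure.
strongly_connected <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n))
    reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  ok <- all(reach & t(reach))
  stranded <- if (ok) integer(0) else
    which(apply(!(reach & t(reach)), 1, any))
  list(connected = ok, stranded = stranded)
}

#' Gaze transition entropy (GTE)
#'
#' Stationary-weighted Shannon entropy of the transition conditionals:
#' \deqn{H_t = - \sum_i p(i) \sum_{j \ne i} p(j|i) \log_2 p(j|i)}
#' in bits, with the convention `0 log 0 = 0` and all-zero rows skipped.
#' Higher values mean less predictable AOI switching; the maximum over `m`
#' AOIs is `log2(m - 1)` (uniform conditionals and uniform weights, the
#' diagonal being structurally empty after cleaning).
#'
#' @param tm A [transition_matrix()].
#' @param p Stationary weight vector of length `m` (see
#'   [stationary_distribution()]).
#' @return Entropy in bits, in `[0, log2(m - 1)]`.
#' @export
gaze_transition_entropy <- function(tm, p) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (length(p) != tm$m)
    stop_input("'p' must have length m = ", tm$m)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_input("'p' must be a probability vector summing to 1")
  H <- 0
  for (i in seq_len(tm$m)) {
    if (p[i] <= 0) next
    row <- tm$probabilities[i, -i]
    row <- row[row > 0]
    if (length(row) == 0L) next
    H <- H - p[i] * sum(row * log2(row))
  }
  H
}

#' Basic scanning statistics of a cleaned dwell sequence
#'
#' @param seq A cleaned `dwell_sequence`.
#' @param m AOI count for the per-AOI share vector.
#' @param stream_duration Total recording duration in seconds; taken from
#'   the sequence's attribute when omitted. When unknown, shares are of
#'   total dwell time and `outside_share` is `NA`.
#' @return A list of class `"scanning_statistics"`: `n_dwells`,
#'   `mean_dwell_time` (s), `aoi_share` (length-`m` fractions of recording
#'   time), and `outside_share` (fraction of recording time in no retained
#'   AOI dwell).
#' @export
scanning_statistics <- function(seq, m = NULL, stream_duration = NULL) {
  stopifnot(inherits(seq, "dwell_sequence"))
  stream_duration <- stream_duration %||% attr(seq, "stream_duration")
  if (is.null(m)) m <- if (nrow(seq)) max(seq$aoi) else 1L
  total_dwell <- sum(seq$duration)
  denom <- stream_duration %||% total_dwell
  aoi_time <- vapply(seq_len(m), function(i)
    sum(seq$duration[seq$aoi == i]), numeric(1))
  structure(
    list(
      n_dwells = nrow(seq),
      mean_dwell_time = if (nrow(seq)) mean(seq$duration) else NA_real_,
      aoi_share = if (denom > 0) aoi_time / denom else aoi_time,
      outside_share = if (is.null(stream_duration)) NA_real_ else
        max(0, 1 - total_dwell / stream_duration)
    ),
    class = "scanning_statistics"
  )
}

#' @export
print.scanning_statistics <- function(x, ...) {
  cat("Scanning statistics:", x$n_dwells, "dwells, mean dwell",
      round(x$mean_dwell_time, 3), "s, outside share",
      if (is.na(x$outside_share)) "NA" else round(x$outside_share, 3), "\n")
  invisible(x)
}

#' Write a transition matrix to CSV
#' @param tm A [transition_matrix()].
#' @param path Output path.
#' @param what `"counts"` or `"probabilities"`.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tm, path,
                                    what = c("probabilities", "counts")) {
  what <- match.arg(what)
  utils::write.csv(as.data.frame(tm[[what]]), path, row.names = TRUE)
  invisible(path)
}

#' Read a transition matrix written by [write_transition_matrix()]
#' @param path CSV path (row and column names are AOI labels).
#' @param what Whether the file holds `"probabilities"` or `"counts"`.
#' @return A [transition_matrix()]; when probabilities are read, counts are
#'   unavailable and set to `NA`.
#' @export
read_transition_matrix <- function(path, what = c("probabilities", "counts")) {
  what <- match.arg(what)
  mat <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  m <- nrow(mat)
  if (what == "counts") {
    df <- which(mat >= 1, arr.ind = TRUE)
    trans <- data.frame(from = rep(df[, 1], mat[df]), to = rep(df[, 2], mat[df]))
    return(transition_matrix(trans, m, labels = rownames(mat)))
  }
  structure(
    list(counts = matrix(NA_integer_, m, m, dimnames = dimnames(mat)),
         probabilities = mat, m = m, n_transitions = NA_integer_),
    class = "transition_matrix"
  )
}
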