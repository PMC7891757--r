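# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately share no code with the package implementations.

# Build a dwell_sequence directly from labels/durations (bypasses the
# stream segmentation path so metric tests are independent of it).
as_dwell_seq <- function(labels, durations = rep(0.5, length(labels)),
                         stream_duration = NULL) {
  df <- data.frame(aoi = as.integer(labels),
                   onset = cumsum(c(0, head(durations, -1))),
                   duration = as.numeric(durations))
  structure(df, stream_duration = stream_duration,
            class = c("dwell_sequence", "data.frame"))
}

# Gaze stream from per-dwell (label, n_frames) pairs.
stream_from_runs <- function(labels, frames, rate = 60) {
  gaze_stream(rep(as.integer(labels), frames), rate = rate)
}

# Independent GTE: direct double loop over the label sequence.
gte_oracle <- function(labels, m) {
  n <- length(labels)
  p <- sapply(seq_len(m), function(i) sum(labels == i)) / n
  H <- 0
  for (i in seq_len(m)) {
    if (p[i] == 0) next
    from_i <- which(labels[-n] == i)
    if (length(from_i) == 0) next
    dests <- labels[from_i + 1]
    for (j in seq_len(m)) {
      if (j == i) next
      pij <- sum(dests == j) / length(dests)
      if (pij > 0) H <- H - p[i] * pij * log2(pij)
    }
  }
  H
}

# Independent matrix density: enumerate ordered pairs seen at least once.
density_oracle <- function(labels, m) {
  n <- length(labels)
  if (n < 2) return(0)
  pairs <- unique(paste(labels[-n], labels[-1]))
  length(pairs) / m^2
}

# Independent n-gram counts: explicit window enumeration into a list.
ngram_oracle <- function(labels, n) {
  L <- length(labels)
  if (L < n) return(integer(0))
  out <- list()
  for (i in 1:(L - n + 1)) {
    key <- paste(labels[i:(i + n - 1)], collapse = ">")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  unlist(out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent coefficient K for one recording under per-recording scope.
k_oracle_single <- function(d, a) {
  zd <- (d - mean(d)) / sd(d)
  za <- (a - mean(a)) / sd(a)
  kappa <- zd[seq_along(a)] - za
  list(k_series = kappa, k_mean = mean(kappa))
}

# Independent Lempel-Ziv phrase counter: rebuilds phrases with a character
# vector dictionary and explicit prefix search.
lzc_oracle <- function(symbols) {
  s <- as.character(symbols)
  seen <- character(0)
  phrases <- 0L
  cur <- character(0)
  for (ch in s) {
    cur <- c(cur, ch)
    key <- paste(cur, collapse = " ")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      phrases <- phrases + 1L
      cur <- character(0)
    }
  }
  if (length(cur) > 0) phrases <- phrases + 1L
  phrases
}

# Power-iteration stationary vector of a row-stochastic matrix.
stationary_oracle <- function(P, iters = 2000) {
  p <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) p <- as.numeric(p %*% P)
  p / sum(p)
}

# Two-region toy world model with centroids (0.5, 0.5) and (10.5, 0.5).
toy_model <- function() {
  world_model(list(
    aoi_region(1, "A", rect = c(0, 0, 1, 1)),
    aoi_region(2, "B", rect = c(10, 0, 11, 1))
  ), units = "cm")
}
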