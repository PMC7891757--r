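# Seeded synthetic cohorts: gaze sample streams drawn from group-specific
# first-order Markov profiles (with sub-threshold flicker and off-AOI
# dropout noise), plus flight-parameter traces and callout events, so the
# whole pipeline is testable without recorded data.

#' Build a generative group profile
#'
#' A profile bundles everything needed to simulate one population's
#' recordings: a zero-diagonal AOI transition matrix, a log-normal dwell
#' duration distribution (parameterized by target mean and SD in seconds),
#' noise rates (sub-threshold flicker dwells and off-AOI dropouts),
#' flight-trace deviation scales, and a callout omission rate.
#'
#' Presets encode the two study populations: `"expert-like"` spreads
#' transition mass over all AOIs (extra weight on the out-the-window view
#' and attitude indicator, as experienced pilots cross-check widely) with a
#' mean dwell of 1.1 s; `"novice-like"` concentrates at least 70% of each
#' row's mass on the five primary-flight-display AOIs (ids 1-5) with a mean
#' dwell of 1.51 s. Any field can be overridden.
#'
#' @param preset `"expert-like"` or `"novice-like"`.
#' @param m AOI count (default 10; presets assume the bundled layout).
#' @param overrides Named list of fields to replace (`transition_matrix`,
#'   `dwell_mean`, `dwell_sd`, `flicker_prob`, `dropout_prob`,
#'   `flight_sd`, `omission_rate`, `motif`, `motif_rate`, `name`).
#' @return A list of class `"group_profile"`.
#' @export
make_profile <- function(preset = c("expert-like", "novice-like"), m = 10,
                         overrides = list()) {
  preset <- match.arg(preset)
  if (!is_count(m) || m < 2) stop_input("'m' must be an integer >= 2")
  base_weights <- function(i) {
    if (preset == "expert-like") {
      w <- rep(1, m)
      if (m >= 10) { w[10] <- 3; w[1] <- 2 }
    } else {
      w <- rep(1, m)
      w[seq_len(min(5L, m - 1L))] <- 5
    }
    w[i] <- 0
    w
  }
  P <- t(vapply(seq_len(m), function(i) {
    w <- base_weights(i)
    w / sum(w)
  }, numeric(m)))
  defaults <- list(
    name = preset,
    transition_matrix = P,
    dwell_mean = if (preset == "expert-like") 1.1 else 1.51,
    dwell_sd = if (preset == "expert-like") 0.5 else 0.65,
    flicker_prob = 0.05,
    dropout_prob = if (preset == "expert-like") 0.13 else 0.20,
    flight_sd = if (preset == "expert-like")
      c(speed = 2.7, vertical_speed = 180, heading = 3.3) else
      c(speed = 5.5, vertical_speed = 380, heading = 3.5),
    omission_rate = if (preset == "expert-like") 0.07 else 0.27,
    motif = NULL,
    motif_rate = 0
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_input("unknown profile field(s): ", paste(unknown, collapse = ", "))
  prof <- utils::modifyList(defaults, overrides)
  prof$transition_matrix <- normalize_profile_matrix(prof$transition_matrix, m)
  if (!is.numeric(prof$dwell_mean) || prof$dwell_mean <= 0)
    stop_input("'dwell_mean' must be > 0")
  if (!is.numeric(prof$dwell_sd) || prof$dwell_sd <= 0)
    stop_input("'dwell_sd' must be > 0")
  for (f in c("flicker_prob", "dropout_prob", "omission_rate")) {
    v <- prof[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_input("'", f, "' must lie in [0, 1]")
  }
  if (!is.null(prof$motif)) {
    motif <- as.integer(prof$motif)
    if (length(motif) < 2L || any(motif < 1L | motif > m) ||
        any(motif[-1] == motif[-length(motif)]))
      stop_input("'motif' must be AOI ids in 1..m with no consecutive repeats")
    prof$motif <- motif
  }
  structure(prof, class = "group_profile")
}

normalize_profile_matrix <- function(P, m) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(m, m)) || any(!is.finite(P)) || any(P < 0))
    stop_input("transition matrix must be a non-negative ", m, "x", m, " matrix")
  diag(P) <- 0
  rs <- rowSums(P)
  if (any(rs <= 0))
    stop_input("transition matrix row(s) ",
               paste(which(rs <= 0), collapse = ", "),
               " have no off-diagonal mass and cannot be normalized")
  P / rs
}

#' @export
print.group_profile <- function(x, ...) {
  cat("Group profile '", x$name, "': ", nrow(x$transition_matrix),
      " AOIs, dwell ", x$dwell_mean, " +/- ", x$dwell_sd, " s, flicker ",
      x$flicker_prob, ", dropout ", x$dropout_prob, "\n", sep = "")
  invisible(x)
}

#' Sample an AOI sequence from a first-order Markov chain
#'
#' Draws `n_dwells` states from the row-stochastic matrix `P` (zero
#' diagonal, so no consecutive repeats). When a motif is given, it is
#' spliced into the sequence after a step with probability `motif_rate`,
#' giving the n-gram analyses a known embedded ground-truth pattern.
#' Randomness comes from the current RNG state; callers that need
#' reproducibility seed beforehand (as [simulate_recording()] does).
#'
#' @param P Row-stochastic `m x m` matrix with zero diagonal.
#' @param n_dwells Number of states to draw.
#' @param init Initial state (default: uniform draw).
#' @param motif Optional AOI id vector to embed.
#' @param motif_rate Per-step splice probability.
#' @return Integer state vector of length `n_dwells`.
#' @export
simulate_markov_sequence <- function(P, n_dwells, init = NULL, motif = NULL,
                                     motif_rate = 0) {
  m <- nrow(P)
  if (!is_count(n_dwells) || n_dwells < 1)
    stop_input("'n_dwells' must be a positive count")
  out <- integer(n_dwells + length(motif) + 1L)
  out[1L] <- if (is.null(init)) sample.int(m, 1) else as.integer(init)
  len <- 1L
  while (len < n_dwells) {
    if (!is.null(motif) && motif_rate > 0 && stats::runif(1) < motif_rate) {
      mo <- motif
      if (mo[1] == out[len]) mo <- mo[-1]
      out[len + seq_along(mo)] <- mo
      len <- len + length(mo)
    } else {
      out[len + 1L] <- sample.int(m, 1, prob = P[out[len], ])
      len <- len + 1L
    }
  }
  out[seq_len(n_dwells)]
}

#' Simulate one synthetic gaze recording
#'
#' Draws an AOI dwell chain from the profile's Markov matrix with log-normal
#' dwell durations (parameters solved from the profile's target mean/SD),
#' renders it as a sample stream at `rate` Hz truncated to exactly
#' `n_frames`, then perturbs it: after each dwell, with probability
#' `flicker_prob` a sub-threshold dwell (< 200 ms) in another AOI is
#' inserted, and with probability `dropout_prob` an off-AOI (id 0) run;
#' the perturbed stream is cut back to its final `n_frames` samples. The
#' unperturbed, pipeline-cleaned sequence is kept as `truth`, so with both
#' noise rates at zero the cleaned pipeline output equals `truth` exactly.
#'
#' Flight traces (speed, vertical speed, heading) are AR(1) noise around
#' the instructed targets (130 kt, -650 ft/min, 143 deg), scaled by the
#' profile's `flight_sd`, at 1 Hz for [companion_frames()] seconds.
#' Callouts are produced at 0.5 Nm marks from 5 Nm, each omitted with
#' probability `omission_rate`.
#'
#' @param profile A [make_profile()] result.
#' @param n_frames Gaze samples to produce (default 14,000).
#' @param seed Integer seed; identical `(profile, n_frames, seed)` give
#'   bit-identical recordings.
#' @param rate Sampling rate in Hz (default 60).
#' @return A list of class `"synthetic_recording"`: `stream`
#'   ([gaze_stream()]), `truth` (cleaned `dwell_sequence`), `traces` (named
#'   list of 1 Hz parameter traces), `calls`, `marks`, `profile_name`,
#'   `seed`.
#' @export
simulate_recording <- function(profile, n_frames = 14000, seed = 1,
                               rate = 60) {
  stopifnot(inherits(profile, "group_profile"))
  if (!is_count(n_frames) || n_frames < rate * 3)
    stop_input("'n_frames' must allow at least a few dwells")
  m <- nrow(profile$transition_matrix)
  cv2 <- (profile$dwell_sd / profile$dwell_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(profile$dwell_mean) - sdlog^2 / 2
  min_frames <- max(1L, as.integer(ceiling(0.2 * rate)))
  with_seed(seed, {
    # enough dwells to cover the frame budget, topped up if needed
    draw_n <- ceiling(n_frames / (profile$dwell_mean * rate) * 1.4) + 20
    states <- simulate_markov_sequence(profile$transition_matrix, draw_n,
                                       motif = profile$motif,
                                       motif_rate = profile$motif_rate)
    frames <- pmax(1L, as.integer(round(
      stats::rlnorm(length(states), meanlog, sdlog) * rate)))
    while (sum(frames) < n_frames) {
      extra <- simulate_markov_sequence(profile$transition_matrix, draw_n,
                                        init = states[length(states)],
                                        motif = profile$motif,
                                        motif_rate = profile$motif_rate)[-1]
      states <- c(states, extra)
      frames <- c(frames, pmax(1L, as.integer(round(
        stats::rlnorm(length(extra), meanlog, sdlog) * rate))))
    }
    cut <- which(cumsum(frames) >= n_frames)[1]
    states <- states[seq_len(cut)]
    frames <- frames[seq_len(cut)]
    frames[cut] <- frames[cut] - (sum(frames) - n_frames)
    if (frames[cut] == 0L) { states <- states[-cut]; frames <- frames[-cut] }

    truth_stream <- gaze_stream(rep(states, frames), rate = rate,
                                source_id = paste0(profile$name, "-truth"))
    truth <- suppressWarnings(clean_sequence(segment_dwells(truth_stream)))

    # noise injection: flicker and dropout segments appended after dwells
    seg_states <- list()
    seg_frames <- list()
    for (k in seq_along(states)) {
      seg_states[[length(seg_states) + 1L]] <- states[k]
      seg_frames[[length(seg_frames) + 1L]] <- frames[k]
      if (profile$flicker_prob > 0 && stats::runif(1) < profile$flicker_prob) {
        other <- setdiff(seq_len(m), states[k])
        seg_states[[length(seg_states) + 1L]] <- sample(other, 1)
        seg_frames[[length(seg_frames) + 1L]] <-
          sample.int(max(1L, min_frames - 1L), 1)
      }
      if (profile$dropout_prob > 0 && stats::runif(1) < profile$dropout_prob) {
        seg_states[[length(seg_states) + 1L]] <- 0L
        seg_frames[[length(seg_frames) + 1L]] <- sample(3:45, 1)
      }
    }
    noisy <- rep(unlist(seg_states), unlist(seg_frames))
    if (length(noisy) > n_frames)
      noisy <- noisy[seq.int(length(noisy) - n_frames + 1L, length(noisy))]
    stream <- gaze_stream(noisy, rate = rate,
                          source_id = paste0(profile$name, "-", seed))

    n_sec <- companion_frames(n_frames, gaze_rate = rate, slow_rate = 1)
    targets <- c(speed = 130, vertical_speed = -650, heading = 143)
    phi <- 0.9
    traces <- lapply(names(targets), function(p) {
      s <- profile$flight_sd[[p]]
      e <- numeric(n_sec)
      e[1] <- stats::rnorm(1, 0, s)
      for (t in seq_len(n_sec - 1L))
        e[t + 1L] <- phi * e[t] + stats::rnorm(1, 0, s * sqrt(1 - phi^2))
      list(time = seq_len(n_sec) - 1, values = targets[[p]] + e)
    })
    names(traces) <- names(targets)

    marks <- callout_marks(5, 0.5)
    produced <- marks[stats::runif(length(marks)) >= profile$omission_rate]
    calls <- produced + stats::rnorm(length(produced), 0, 0.02)

    structure(
      list(stream = stream, truth = truth, traces = traces,
           calls = calls, marks = marks,
           profile_name = profile$name, seed = as.integer(seed)),
      class = "synthetic_recording"
    )
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("Synthetic recording [", x$profile_name, ", seed ", x$seed, "]: ",
      length(x$stream$aoi), " frames, ", nrow(x$truth),
      " truth dwells\n", sep = "")
  invisible(x)
}

#' Simulate a seeded cohort of recordings
#'
#' @param profiles A [make_profile()] result or list of them.
#' @param n_per_group Recordings per profile (default 16, i.e. a 16+16
#'   cohort for two profiles).
#' @param n_frames Gaze samples per recording (default 14,000).
#' @param seed Master seed; per-recording seeds are derived from it and
#'   listed in the manifest.
#' @return A list of class `"synthetic_cohort"`: `recordings` (list of
#'   [simulate_recording()] results) and `manifest` (data frame with
#'   `recording`, `profile`, `seed`).
#' @export
simulate_cohort <- function(profiles, n_per_group = 16, n_frames = 14000,
                            seed = 1) {
  if (inherits(profiles, "group_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || length(profiles) < 1L ||
      !all(vapply(profiles, inherits, logical(1), "group_profile")))
    stop_input("'profiles' must be one or more group_profile objects")
  if (!is_count(n_per_group) || n_per_group < 0)
    stop_input("'n_per_group' must be a non-negative count")
  recs <- list()
  manifest <- data.frame(recording = integer(0), profile = character(0),
                         seed = integer(0))
  idx <- 0L
  for (g in seq_along(profiles)) {
    for (r in seq_len(n_per_group)) {
      idx <- idx + 1L
      s <- derive_seed(seed, idx)
      recs[[idx]] <- simulate_recording(profiles[[g]], n_frames = n_frames,
                                        seed = s)
      manifest <- rbind(manifest, data.frame(
        recording = idx, profile = profiles[[g]]$name, seed = s))
    }
  }
  structure(list(recordings = recs, manifest = manifest),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "recordings (",
      paste(table(x$manifest$profile), collapse = " + "), ")\n")
  invisible(x)
}

#' Write a cohort's gaze logs, flight logs and manifest to a directory
#'
#' Emits the same delimited formats the readers consume: one gaze CSV and
#' one flight CSV per recording, plus `manifest.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    utils::write.csv(
      data.frame(time = rec$stream$time, aoi = rec$stream$aoi),
      file.path(dir, sprintf("gaze_%03d.csv", i)), row.names = FALSE)
    fl <- data.frame(time = rec$traces[[1]]$time)
    for (p in names(rec$traces)) fl[[p]] <- rec$traces[[p]]$values
    utils::write.csv(fl, file.path(dir, sprintf("flight_%03d.csv", i)),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
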