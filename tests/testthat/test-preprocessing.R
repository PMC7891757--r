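test_that("segmentation run-length encodes AOI hits", {
  s <- stream_from_runs(1, 12)
  seg <- segment_dwells(s)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$aoi, 1L)
  expect_equal(seg$duration, 0.2)   # 12 samples at 60 Hz

  seg2 <- segment_dwells(gaze_stream(c(1, 1, 2, 2, 2), rate = 60))
  expect_equal(seg2$aoi, c(1L, 2L))
  expect_equal(seg2$duration, c(2, 3) / 60)

  seg3 <- segment_dwells(gaze_stream(c(1, 2, 1, 2), rate = 60))
  expect_equal(nrow(seg3), 4)
  expect_true(all(seg3$duration == 1 / 60))
})

test_that("cleaning drops short and off-AOI dwells then merges", {
  # the canonical label collapse: 1,1,4,4,5,5,5,6 -> 1,4,5,6
  seq <- as_dwell_seq(c(1, 1, 4, 4, 5, 5, 5, 6), rep(0.3, 8))
  expect_equal(clean_sequence(seq)$aoi, c(1L, 4L, 5L, 6L))
  expect_equal(clean_sequence(seq)$duration, c(0.6, 0.6, 0.9, 0.3))

  # a sub-threshold interruption is removed and the flanks merge
  seq2 <- as_dwell_seq(c(1, 2, 1), c(0.5, 0.15, 0.5))
  out <- clean_sequence(seq2)
  expect_equal(out$aoi, 1L)
  expect_equal(out$duration, 1.0)

  # off-AOI runs split dwells; after removal same-AOI flanks merge
  seq3 <- as_dwell_seq(c(3, 0, 3), c(0.4, 0.3, 0.4))
  expect_equal(clean_sequence(seq3)$aoi, 3L)
  expect_equal(clean_sequence(seq3)$duration, 0.8)

  expect_warning(out_empty <- clean_sequence(as_dwell_seq(1, 0.1)),
                 "no dwells survive")
  expect_equal(nrow(out_empty), 0)
})

test_that("cleaning is idempotent and respects the no-repeat invariant", {
  set.seed(11)
  for (rep in 1:25) {
    labels <- sample(0:5, 40, replace = TRUE)
    durs <- runif(40, 0.05, 0.8)
    once <- clean_sequence(as_dwell_seq(labels, durs))
    if (nrow(once) == 0) next
    twice <- clean_sequence(once)
    expect_equal(as.data.frame(twice), as.data.frame(once))
    if (nrow(once) > 1)
      expect_true(all(once$aoi[-1] != once$aoi[-nrow(once)]))
  }
})

test_that("retained dwell time never exceeds stream duration", {
  set.seed(12)
  for (rep in 1:10) {
    aoi <- sample(0:4, 600, replace = TRUE)
    st <- gaze_stream(aoi, rate = 60)
    cleaned <- suppressWarnings(clean_sequence(segment_dwells(st)))
    expect_lte(sum(cleaned$duration), length(aoi) / 60 + 1e-12)
  }
})

test_that("trimming keeps exactly the final n frames", {
  st <- gaze_stream(rep(1:5, each = 3000), rate = 60)
  tr <- trim_to_duration(st, 14000)
  expect_equal(length(tr$aoi), 14000)
  expect_equal(tr$aoi, tail(st$aoi, 14000))
  expect_equal(tr$time, tail(st$time, 14000))

  same <- trim_to_duration(st, length(st$aoi))
  expect_equal(same$aoi, st$aoi)
  expect_error(trim_to_duration(gaze_stream(rep(1, 10)), 20), "fewer")
})

test_that("transitions pair consecutive dwells with amplitudes", {
  m <- default_world_model()
  seq <- as_dwell_seq(c(1, 4, 5, 6), rep(0.5, 4))
  tr <- build_transitions(seq, m)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$from, c(1L, 4L, 5L))
  expect_equal(tr$to, c(4L, 5L, 6L))
  expect_equal(tr$amplitude,
               c(aoi_distance(m, 1, 4), aoi_distance(m, 4, 5),
                 aoi_distance(m, 5, 6)))

  expect_equal(nrow(build_transitions(as_dwell_seq(3, 0.5), m)), 0)
  expect_error(build_transitions(as_dwell_seq(c(1, 1, 2), rep(0.5, 3)), m),
               "consecutive")

  # 3-4-5 amplitude from the toy geometry via sample mean positions
  seq2 <- as_dwell_seq(c(1, 2), c(0.5, 0.5))
  seq2$x <- c(0, 3); seq2$y <- c(0, 4)
  expect_equal(build_transitions(seq2)$amplitude, 5)
})

test_that("transition count equals dwell count minus one on random input", {
  m <- default_world_model()
  set.seed(13)
  for (rep in 1:20) {
    labels <- sample(0:10, 60, replace = TRUE)
    frames <- sample(3:40, 60, replace = TRUE)
    st <- stream_from_runs(labels, frames)
    cleaned <- suppressWarnings(clean_sequence(segment_dwells(st)))
    expect_equal(nrow(build_transitions(cleaned, m)),
                 max(0, nrow(cleaned) - 1))
  }
})

test_that("gaze logs round-trip through CSV with aoi or x/y columns", {
  m <- default_world_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time = (0:9) / 60, aoi = rep(c(1, 10), each = 5)),
            path, row.names = FALSE)
  st <- read_gaze_log(path, rate = 60)
  expect_equal(st$aoi, rep(c(1L, 10L), each = 5))

  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time = (0:3) / 60,
                       x = c(11, 11, 30, -5), y = c(15, 15, 40, -5)),
            path2, row.names = FALSE)
  st2 <- read_gaze_log(path2, model = m, rate = 60)
  expect_equal(st2$aoi, c(1L, 1L, 10L, 0L))
  expect_error(read_gaze_log(path2, rate = 60), "world model")
})

test_that("whole slower-rate frame count matches the rate ratio", {
  expect_identical(companion_frames(14000, 60, 1), 233L)
  expect_identical(companion_frames(60, 60, 1), 1L)
  expect_identical(companion_frames(59, 60, 1), 0L)
})
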