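test_that("transition matrices tally and normalize correctly", {
  tm <- transition_matrix(data.frame(from = c(1, 4, 5), to = c(4, 5, 6)),
                          m = 10)
  expect_equal(sum(tm$counts), 3)
  expect_equal(tm$counts[1, 4], 1L)
  expect_equal(tm$counts[4, 5], 1L)
  expect_equal(tm$counts[5, 6], 1L)

  tm2 <- transition_matrix(data.frame(from = c(1, 1, 1), to = c(2, 2, 3)),
                           m = 4)
  expect_equal(tm2$probabilities[1, ], c(`1` = 0, `2` = 2/3, `3` = 1/3,
                                         `4` = 0))
  expect_equal(rowSums(tm2$probabilities)[1], c(`1` = 1))

  tm3 <- transition_matrix(data.frame(from = integer(0), to = integer(0)),
                           m = 3)
  expect_true(all(tm3$counts == 0))
  expect_error(transition_matrix(data.frame(from = 1, to = 11), m = 10),
               "outside")
})

test_that("count conservation: sum of matrix = dwells - 1", {
  set.seed(21)
  for (rep in 1:25) {
    labels <- simulate_markov_sequence(
      make_profile("expert-like")$transition_matrix,
      sample(2:60, 1))
    seq <- as_dwell_seq(labels)
    tm <- transition_matrix(seq, m = 10)
    expect_equal(sum(tm$counts), length(labels) - 1)
    expect_true(all(diag(tm$counts) == 0))
  }
})

test_that("matrix density counts active cells over all m^2 cells", {
  expect_equal(matrix_density(transition_matrix(as_dwell_seq(c(1, 2, 1)),
                                                m = 10)), 0.02)
  all_pairs <- expand.grid(from = 1:10, to = 1:10)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  expect_equal(matrix_density(transition_matrix(all_pairs, m = 10)), 0.9)
  empty <- transition_matrix(data.frame(from = integer(0), to = integer(0)),
                             m = 5)
  expect_equal(matrix_density(empty), 0)
})

test_that("stationary distribution: dwell proportions and eigenvector agree with oracles", {
  seq <- as_dwell_seq(c(1, 2, 1, 3, 1, 2, 1, 3))
  expect_equal(stationary_distribution(seq, m = 3), c(0.5, 0.25, 0.25))

  # deterministic alternation: symmetric stationary vector
  alt <- transition_matrix(as_dwell_seq(rep(c(1, 2), 10)), m = 2)
  expect_equal(stationary_distribution(alt, mode = "eigenvector"),
               c(0.5, 0.5))

  # uniform chain over 10 AOIs vs power-iteration oracle
  P <- matrix(1 / 9, 10, 10); diag(P) <- 0
  all_pairs <- expand.grid(from = 1:10, to = 1:10)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  tm <- transition_matrix(all_pairs, m = 10)
  p <- stationary_distribution(tm, mode = "eigenvector")
  expect_equal(p, rep(0.1, 10), tolerance = 1e-10)
  expect_equal(p, stationary_oracle(P), tolerance = 1e-8)

  # reducible chain names the stranded AOIs
  red <- transition_matrix(data.frame(from = c(1, 2, 3), to = c(2, 1, 4)),
                           m = 4)
  expect_error(stationary_distribution(red, mode = "eigenvector"),
               "reducible")
})

test_that("gaze transition entropy matches hand and closed-form values", {
  # deterministic alternation: zero uncertainty
  alt_seq <- as_dwell_seq(rep(c(1, 2), 8))
  tm <- transition_matrix(alt_seq, m = 2)
  expect_equal(gaze_transition_entropy(
    tm, stationary_distribution(alt_seq, m = 2)), 0)

  # hand evaluation: only source 1 is uncertain (H = 1 bit, weight 0.5)
  seq <- as_dwell_seq(c(1, 2, 1, 3, 1, 2, 1, 3))
  tm2 <- transition_matrix(seq, m = 3)
  expect_equal(gaze_transition_entropy(
    tm2, stationary_distribution(seq, m = 3)), 0.5)

  # uniform chain over m = 10: log2(9) bits
  all_pairs <- expand.grid(from = 1:10, to = 1:10)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  tm3 <- transition_matrix(all_pairs, m = 10)
  expect_equal(gaze_transition_entropy(tm3, rep(0.1, 10)), log2(9))

  expect_error(gaze_transition_entropy(tm3, rep(0.25, 4)), "length")
})

test_that("GTE equals the brute-force oracle and is bounded by log2(m-1)", {
  set.seed(22)
  P <- make_profile("novice-like")$transition_matrix
  for (rep in 1:20) {
    labels <- simulate_markov_sequence(P, sample(4:8, 1))
    seq <- as_dwell_seq(labels)
    tm <- transition_matrix(seq, m = 10)
    gte <- gaze_transition_entropy(tm, stationary_distribution(seq, m = 10))
    expect_equal(gte, gte_oracle(labels, 10), tolerance = 1e-12)
    expect_gte(gte, 0)
    expect_lte(gte, log2(9) + 1e-12)
  }
})

test_that("scanning statistics summarize dwell structure", {
  seq <- as_dwell_seq(c(1, 2), c(1, 2), stream_duration = 4)
  st <- scanning_statistics(seq, m = 3)
  expect_equal(st$n_dwells, 2)
  expect_equal(st$mean_dwell_time, 1.5)
  expect_equal(st$aoi_share, c(0.25, 0.5, 0))
  expect_equal(st$outside_share, 0.25)

  full <- scanning_statistics(as_dwell_seq(1, 2, stream_duration = 2), m = 1)
  expect_equal(full$outside_share, 0)
})

test_that("transition matrix CSV writer round-trips counts", {
  seq <- as_dwell_seq(c(1, 2, 3, 1, 2))
  tm <- transition_matrix(seq, m = 3, labels = c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_matrix(tm, path, what = "counts")
  back <- read_transition_matrix(path, what = "counts")
  expect_equal(back$counts, tm$counts)
  expect_equal(back$probabilities, tm$probabilities)
})
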