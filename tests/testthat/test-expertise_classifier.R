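make_tms <- function(n, profile, n_dwells = 200, seed = 1) {
  lapply(seq_len(n), function(i) {
    set.seed(seed * 1000 + i)
    labels <- simulate_markov_sequence(profile$transition_matrix, n_dwells)
    transition_matrix(as_dwell_seq(labels), m = 10)
  })
}

test_that("feature table flattens m x m probabilities row-major", {
  exp_prof <- make_profile("expert-like")
  nov_prof <- make_profile("novice-like")
  tms <- c(make_tms(16, exp_prof, seed = 1), make_tms(16, nov_prof, seed = 2))
  ft <- build_feature_table(tms, rep(c("expert", "novice"), each = 16))
  expect_equal(dim(ft$features), c(32, 100))
  expect_true(all(ft$features >= 0 & ft$features <= 1))
  # row-major: feature 1..10 is source AOI 1's outgoing row
  expect_equal(unname(ft$features[1, 1:10]),
               unname(tms[[1]]$probabilities[1, ]))

  # alternation 1<->2 gives exactly two unit entries
  alt <- transition_matrix(as_dwell_seq(rep(c(1, 2), 10)), m = 10)
  ft2 <- build_feature_table(list(alt, alt), c("a", "b"))
  expect_equal(sum(ft2$features[1, ] == 1), 2)

  expect_error(build_feature_table(list(), character(0)), "non-empty")
  expect_error(build_feature_table(
    list(alt, transition_matrix(as_dwell_seq(c(1, 2)), m = 5)),
    c("a", "b")), "mixed")
})

test_that("PCA reduction caps at feasible rank and orders variance", {
  exp_prof <- make_profile("expert-like")
  tms <- make_tms(32, exp_prof, seed = 3)
  ft <- build_feature_table(tms, rep(c("a", "b"), 16))
  expect_warning(red <- reduce_dimensions(ft, 35), "feasible rank")
  expect_lte(ncol(red$features), 31)
  ev <- attr(red, "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))

  # one varying feature: first component carries all the variance
  ft1 <- ft
  ft1$features <- matrix(0, 10, 5)
  ft1$features[, 3] <- 1:10
  red1 <- reduce_dimensions(ft1, 2)
  ev1 <- attr(red1, "explained_variance")
  expect_gt(ev1[1] / sum(ev1), 1 - 1e-12)

  expect_error(reduce_dimensions(ft, 0), "positive")
  expect_error(reduce_dimensions(ft, 101), "exceeds the number of features")
})

test_that("exact binomial chance level matches tail enumeration", {
  expect_equal(binomial_chance_level(32, 2, 0.05), 22 / 32)
  # direct check of the defining property at the returned k
  k <- 22
  expect_lt(sum(dbinom(k:32, 32, 0.5)), 0.05)
  expect_gte(sum(dbinom((k - 1):32, 32, 0.5)), 0.05)

  expect_equal(binomial_chance_level(1, 2), 1)
  # at alpha = 0.5 the level sits just above the null median, i.e. ~ 1/2
  expect_equal(binomial_chance_level(1000, 2, alpha = 0.5), 0.5,
               tolerance = 0.01)
  # relaxing alpha can only lower the level
  expect_lte(binomial_chance_level(32, 2, alpha = 0.2),
             binomial_chance_level(32, 2, alpha = 0.05))
  expect_error(binomial_chance_level(32, 2, alpha = 1.2), "alpha")
  expect_error(binomial_chance_level(32, 1), "n_classes")
})

test_that("cosine KNN cross-validation is reproducible and accounts correctly", {
  exp_prof <- make_profile("expert-like")
  nov_prof <- make_profile("novice-like")
  tms <- c(make_tms(16, exp_prof, seed = 4), make_tms(16, nov_prof, seed = 5))
  labels <- rep(c("expert", "novice"), each = 16)
  ft <- build_feature_table(tms, labels)

  r1 <- crossvalidated_knn(ft, seed = 99, n_components = 35)
  r2 <- crossvalidated_knn(ft, seed = 99, n_components = 35)
  expect_equal(r1$predictions, r2$predictions)
  expect_equal(r1$overall_accuracy, r2$overall_accuracy)

  # confusion accounting
  expect_equal(unname(rowSums(r1$confusion)), c(16, 16))
  expect_equal(sum(diag(r1$confusion)) / sum(r1$confusion),
               r1$overall_accuracy)
  expect_equal(r1$chance_level, 22 / 32)

  # well-separated generating matrices classify above chance
  expect_gte(r1$overall_accuracy, r1$chance_level)

  expect_error(crossvalidated_knn(ft, k_folds = 20), "k_folds")
  one_class <- build_feature_table(tms[1:16], rep("expert", 16))
  expect_error(crossvalidated_knn(one_class), "2 classes")
})

test_that("cosine distance is invariant to positive row rescaling", {
  exp_prof <- make_profile("expert-like")
  tms <- make_tms(10, exp_prof, seed = 6)
  ft <- build_feature_table(tms, rep(c("a", "b"), 5))
  ft_scaled <- ft
  ft_scaled$features <- ft$features * runif(10, 0.5, 20)
  r1 <- crossvalidated_knn(ft, seed = 7, neighbors = 3, k_folds = 2)
  r2 <- crossvalidated_knn(ft_scaled, seed = 7, neighbors = 3, k_folds = 2)
  expect_equal(r1$predictions, r2$predictions)
})

test_that("KNN prediction agrees with a brute-force cosine ranking oracle", {
  set.seed(61)
  train <- matrix(runif(40 * 6), 40, 6)
  test <- matrix(runif(8 * 6), 8, 6)
  y <- factor(rep(c("p", "q"), each = 20))
  ft <- structure(list(features = rbind(train, test),
                       labels = factor(c(as.character(y), rep("p", 8))),
                       m = 6), class = "feature_table")
  # oracle: rank by explicit 1 - cos similarity loops, majority of 5
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  pred_oracle <- sapply(seq_len(nrow(test)), function(i) {
    d <- sapply(seq_len(nrow(train)), function(j) cosd(test[i, ], train[j, ]))
    nn <- order(d)[1:5]
    names(which.max(table(y[nn])))
  })
  pred_pkg <- aoiscan:::knn_predict(train, y, test, neighbors = 5)
  expect_equal(as.character(pred_pkg), pred_oracle)
})

test_that("identical generating matrices yield near-chance accuracy", {
  prof <- make_profile("expert-like")
  tms <- c(make_tms(16, prof, seed = 8), make_tms(16, prof, seed = 9))
  ft <- build_feature_table(tms, rep(c("g1", "g2"), each = 16))
  accs <- sapply(1:5, function(s)
    crossvalidated_knn(ft, seed = s, n_components = 20)$overall_accuracy)
  # 95% binomial null interval around 0.5 for n = 32 is [10/32, 22/32]
  expect_gte(mean(accs), qbinom(0.025, 32, 0.5) / 32)
  expect_lte(mean(accs), qbinom(0.975, 32, 0.5) / 32)
})
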