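test_that("Lempel-Ziv parser reproduces the canonical binary decomposition", {
  # 1|0|10|01|010|0101|11 -> 7 phrases
  expect_identical(lempel_ziv_complexity("101001010010111"), 7L)
  expect_identical(
    lempel_ziv_complexity(c(1, 0, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1, 1, 1)),
    7L)
})

test_that("Lempel-Ziv handles degenerate sequences", {
  expect_identical(lempel_ziv_complexity("a"), 1L)
  expect_identical(lempel_ziv_complexity(c(1, 4, 5, 6)), 4L)
  expect_identical(lempel_ziv_complexity(c(7, 7)), 2L)
  for (L in 2:12)
    expect_identical(lempel_ziv_complexity(rep("a", L)), lzc_oracle(rep("a", L)))
  expect_error(lempel_ziv_complexity(character(0)), "empty")
})

test_that("Lempel-Ziv matches the independent parser and is monotone in prefixes", {
  set.seed(31)
  for (rep in 1:30) {
    s <- sample(1:10, sample(5:60, 1), replace = TRUE)
    expect_identical(lempel_ziv_complexity(s), lzc_oracle(s))
    prefix <- s[seq_len(sample(seq_along(s), 1))]
    expect_lte(lempel_ziv_complexity(prefix), lempel_ziv_complexity(s))
  }
})

test_that("n-gram counting matches exhaustive window enumeration", {
  tab <- ngram_counts(c(1, 4, 5, 1, 4, 5, 1), 3)
  expect_identical(tab[["1>4>5"]], 2L)
  expect_identical(tab[["4>5>1"]], 2L)
  expect_identical(tab[["5>1>4"]], 1L)
  expect_equal(sum(tab), 5)   # 7 - 3 + 1

  expect_warning(empty <- ngram_counts(c(1, 2), 3), "no 3-grams")
  expect_length(empty, 0)

  # bigram totals equal transition count
  s <- c(2, 5, 2, 9, 2, 5)
  expect_equal(sum(ngram_counts(s, 2)), length(s) - 1)

  set.seed(32)
  for (rep in 1:20) {
    s <- sample(1:6, sample(6:40, 1), replace = TRUE)
    n <- sample(2:5, 1)
    if (length(s) < n) next
    got <- ngram_counts(s, n)
    want <- ngram_oracle(s, n)
    expect_equal(sum(got), length(s) - n + 1)
    expect_equal(as.integer(got[names(want)]), as.integer(want))
    expect_equal(length(got), length(want))
  }
})

test_that("common n-grams implement supported set intersection", {
  a <- ngram_counts(c(1, 2, 3, 1, 2, 3, 1, 2), 3)   # has 1>2>3, 2>3>1, 3>1>2
  b <- ngram_counts(c(3, 1, 2, 3), 3)               # has 3>1>2, 1>2>3
  res <- common_ngrams(list(a, b))
  expect_setequal(res$ngrams, c("1>2>3", "3>1>2"))
  expect_equal(res$count, 2)

  # identical members: common set is the member's distinct grams
  res2 <- common_ngrams(list(a, a, a))
  expect_equal(res2$count, length(a))

  # disjoint members share nothing
  d1 <- ngram_counts(c(1, 2, 1, 2), 2)
  d2 <- ngram_counts(c(3, 4, 3, 4), 2)
  expect_equal(common_ngrams(list(d1, d2))$count, 0)

  # majority support admits grams missing from a minority
  c3 <- ngram_counts(c(1, 2, 3), 3)
  res3 <- common_ngrams(list(a, b, c3), support = 2 / 3)
  expect_true("1>2>3" %in% res3$ngrams)

  expect_error(common_ngrams(list(a, ngram_counts(c(1, 2, 3), 2))), "mixed")
  expect_error(common_ngrams(list(a)), "at least 2")
})

test_that("common n-grams are invariant to member order", {
  set.seed(33)
  tabs <- lapply(1:5, function(i)
    ngram_counts(sample(1:4, 30, replace = TRUE), 3))
  base <- common_ngrams(tabs)
  for (rep in 1:5) {
    perm <- sample(seq_along(tabs))
    expect_equal(common_ngrams(tabs[perm]), base)
  }
})

test_that("unique-AOI filter keeps only pairwise-distinct grams", {
  tab <- ngram_counts(c(10, 3, 10, 3, 10, 3, 1), 3)
  filt <- unique_aoi_ngrams(tab)
  expect_setequal(names(filt), "10>3>1")  # the only gram with distinct AOIs
  expect_identical(filt[["10>3>1"]], 1L)

  all_rep <- ngram_counts(c(1, 2, 1, 2, 1), 3)
  expect_length(unique_aoi_ngrams(all_rep), 0)

  uniq <- ngram_counts(c(1, 2, 3, 4), 3)
  expect_equal(unique_aoi_ngrams(uniq), uniq)
})

test_that("ranked n-gram report aggregates occurrences and support", {
  a <- ngram_counts(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3)
  b <- ngram_counts(c(1, 2, 3), 3)
  df <- write_ngram_report(list(a, b))
  expect_equal(df$mean_occurrences_per_member[df$ngram == "1>2>3"],
               (3 + 1) / 2)
  expect_equal(df$member_support[df$ngram == "2>3>1"], 0.5)
  expect_equal(df$mean_occurrences_per_member, sort(df$mean_occurrences_per_member, decreasing = TRUE))
})

test_that("embedded motifs surface as frequent n-grams", {
  prof <- make_profile("expert-like",
                       overrides = list(motif = c(10, 3, 1), motif_rate = 0.3))
  set.seed(34)
  s <- simulate_markov_sequence(prof$transition_matrix, 400,
                                motif = prof$motif, motif_rate = prof$motif_rate)
  tab <- ngram_counts(s, 3)
  expect_gte(tab[["10>3>1"]], 10)
  expect_equal(unname(which(names(tab) == "10>3>1")), 1L)  # most frequent
})
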