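# Sequence-pattern analyses of the AOI symbol sequence: Lempel-Ziv
# complexity, overlapping n-gram counting, group-common n-grams, and the
# unique-AOI n-gram filter.

#' Lempel-Ziv complexity of a symbol sequence
#'
#' Counts the number of distinct phrases found when the sequence is scanned
#' once from left to right, each phrase being the shortest prefix of the
#' remaining input not yet in the phrase dictionary (incremental
#' dictionary parsing in the Lempel-Ziv family). A final phrase left
#' incomplete at the end of the sequence counts as a phrase. For the binary
#' string `101001010010111` the parsing is `1|0|10|01|010|0101|11`, giving
#' complexity 7. Applied to AOI dwell sequences, higher values indicate a
#' larger variety of scanning patterns.
#'
#' @param symbols Atomic vector of symbols (AOI ids, characters, ...); a
#'   single string is split into characters.
#' @return Integer phrase count.
#' @export
lempel_ziv_complexity <- function(symbols) {
  if (is.character(symbols) && length(symbols) == 1L && nchar(symbols) > 1L)
    symbols <- strsplit(symbols, "")[[1]]
  s <- as.character(symbols)
  n <- length(s)
  if (n == 0L || anyNA(s)) stop_input("empty or NA symbol sequence")
  dict <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    key <- s[i]
    while (exists(key, envir = dict, inherits = FALSE) && j < n) {
      j <- j + 1L
      key <- paste(s[i:j], collapse = "\x1f")
    }
    count <- count + 1L
    assign(key, TRUE, envir = dict)
    i <- j + 1L
  }
  count
}

new_ngram_table <- function(counts, n) {
  structure(counts, n = as.integer(n), class = "ngram_table")
}

#' Count overlapping n-grams of a symbol sequence
#'
#' Slides a window of length `n` with stride 1 over the sequence and counts
#' every distinct n-gram. For a sequence of length `L >= n` the counts sum
#' to `L - n + 1`.
#'
#' @param symbols Atomic vector of symbols (e.g. cleaned AOI labels).
#' @param n Gram length, `>= 2`.
#' @param sep Separator used in the printed n-gram keys (default `">"`).
#' @return An `ngram_table`: a named integer vector of counts (names are the
#'   n-grams joined by `sep`), with the gram length as attribute `n`. Empty,
#'   with a warning, when the sequence is shorter than `n`.
#' @export
ngram_counts <- function(symbols, n, sep = ">") {
  if (!is_count(n) || n < 2) stop_input("'n' must be an integer >= 2")
  s <- as.character(symbols)
  L <- length(s)
  if (L < n) {
    warning("sequence of length ", L, " has no ", n, "-grams")
    return(new_ngram_table(structure(integer(0), names = character(0)), n))
  }
  windows <- vapply(seq_len(L - n + 1L), function(i)
    paste(s[i:(i + n - 1L)], collapse = sep), character(1))
  tab <- table(windows)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  new_ngram_table(sort(counts, decreasing = TRUE), n)
}

#' @export
print.ngram_table <- function(x, top = 10L, ...) {
  cat(attr(x, "n"), "-gram table: ", length(x), " distinct grams, ",
      sum(x), " occurrences\n", sep = "")
  if (length(x)) print(utils::head(unclass(x), top))
  invisible(x)
}

#' @export
as.data.frame.ngram_table <- function(x, ...) {
  data.frame(ngram = names(x), count = as.integer(x),
             stringsAsFactors = FALSE)
}

#' N-grams common to a group of recordings
#'
#' Returns the n-grams present (count >= 1) in at least
#' `ceiling(support * group size)` members' tables. The default `support =
#' 1` is the strict intersection: patterns every member of the group
#' produced. The number of such shared patterns is a measure of within-group
#' scanning consistency.
#'
#' @param tables List (>= 2) of `ngram_table`s with identical gram length.
#' @param support Required member fraction in `(0, 1]`.
#' @return List with `ngrams` (character vector of shared grams, sorted) and
#'   `count` (its length).
#' @export
common_ngrams <- function(tables, support = 1.0) {
  if (!is.list(tables) || length(tables) < 2L)
    stop_input("need at least 2 n-gram tables")
  if (!all(vapply(tables, inherits, logical(1), "ngram_table")))
    stop_input("'tables' must be a list of ngram_table objects")
  ns <- vapply(tables, attr, integer(1), "n")
  if (length(unique(ns)) != 1L)
    stop_input("mixed gram lengths: ", paste(unique(ns), collapse = ", "))
  if (!is.numeric(support) || support <= 0 || support > 1)
    stop_input("'support' must be in (0, 1]")
  need <- ceiling(support * length(tables))
  all_grams <- unlist(lapply(tables, names), use.names = FALSE)
  presence <- table(all_grams)
  shared <- sort(names(presence)[presence >= need])
  list(ngrams = shared, count = length(shared))
}

#' Keep only n-grams whose AOIs are pairwise distinct
#'
#' Most frequent gaze n-grams revisit an AOI (e.g. back-and-forth
#' OTW>VS>OTW); this filter retains only patterns visiting `n` different
#' AOIs, which single out the more elaborate scanning routines.
#'
#' @param table An `ngram_table`.
#' @param sep Separator used in the table's keys.
#' @return The filtered `ngram_table`.
#' @export
unique_aoi_ngrams <- function(table, sep = ">") {
  stopifnot(inherits(table, "ngram_table"))
  if (length(table) == 0L) return(table)
  keep <- vapply(strsplit(names(table), sep, fixed = TRUE),
                 function(g) !anyDuplicated(g), logical(1))
  new_ngram_table(table[keep], attr(table, "n"))
}

#' Write a ranked group n-gram report
#'
#' One row per n-gram seen in any member, ranked by mean occurrences per
#' member, with the fraction of members producing it.
#'
#' @param tables List of `ngram_table`s (one per group member).
#' @param path Output CSV path, or `NULL` to return the data frame.
#' @return The report data frame (columns `ngram`,
#'   `mean_occurrences_per_member`, `member_support`), invisibly when
#'   written.
#' @export
write_ngram_report <- function(tables, path = NULL) {
  if (!is.list(tables) || length(tables) < 1L)
    stop_input("need at least one n-gram table")
  grams <- sort(unique(unlist(lapply(tables, names), use.names = FALSE)))
  occ <- vapply(grams, function(g)
    mean(vapply(tables, function(t) if (g %in% names(t)) t[[g]] else 0L,
                numeric(1))), numeric(1))
  supp <- vapply(grams, function(g)
    mean(vapply(tables, function(t) g %in% names(t), logical(1))), numeric(1))
  df <- data.frame(ngram = grams,
                   mean_occurrences_per_member = occ,
                   member_support = supp,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$mean_occurrences_per_member, df$ngram), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
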