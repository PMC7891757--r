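# Expertise classification from flattened transition-probability matrices:
# feature construction, PCA reduction, cosine-distance KNN with stratified
# k-fold cross-validation, and the exact binomial chance level.

#' Flatten transition matrices into a feature table
#'
#' Each recording's `m x m` transition-probability matrix becomes one row of
#' `m^2` features, flattened row-major (all destinations of source AOI 1,
#' then of AOI 2, ...). For the default 10-AOI world model this yields 100
#' features per recording.
#'
#' @param matrices List of [transition_matrix()] objects sharing `m`.
#' @param labels Group identifier per matrix (coerced to factor).
#' @return A list of class `"feature_table"` with `features` (numeric
#'   matrix, rows = recordings), `labels` (factor) and `m`.
#' @export
build_feature_table <- function(matrices, labels) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop_input("'matrices' must be a non-empty list of transition matrices")
  if (!all(vapply(matrices, inherits, logical(1), "transition_matrix")))
    stop_input("'matrices' must contain transition_matrix objects")
  ms <- vapply(matrices, `[[`, numeric(1), "m")
  if (length(unique(ms)) != 1L)
    stop_input("matrices have mixed AOI counts: ",
               paste(unique(ms), collapse = ", "))
  if (length(labels) != length(matrices))
    stop_input("'labels' must align with 'matrices'")
  m <- matrices[[1]]$m
  feats <- t(vapply(matrices, function(tm) as.numeric(t(tm$probabilities)),
                    numeric(m * m)))
  aoi <- colnames(matrices[[1]]$probabilities)
  colnames(feats) <- paste0("from_", rep(aoi, each = m), "_to_",
                            rep(aoi, times = m))
  structure(list(features = feats, labels = factor(labels), m = m),
            class = "feature_table")
}

#' Project a feature table onto its principal components
#'
#' Mean-centred PCA (no scaling) of the feature rows; components are
#' ordered by decreasing explained variance. A request beyond the feasible
#' rank of the centred table (`min(rows - 1, features)`) is capped with a
#' warning — e.g. 35 components requested from 32 recordings yields at most
#' 31.
#'
#' @param table A [build_feature_table()] result.
#' @param n_components Number of components to retain (default 35).
#' @return A `feature_table` whose `features` are the component scores;
#'   loadings, centre and explained variance are attached as attributes.
#' @export
reduce_dimensions <- function(table, n_components = 35) {
  stopifnot(inherits(table, "feature_table"))
  if (!is_count(n_components) || n_components < 1)
    stop_input("'n_components' must be a positive count")
  p <- ncol(table$features)
  if (n_components > p)
    stop_input("'n_components' exceeds the number of features (max ", p, ")")
  feasible <- min(nrow(table$features) - 1L, p)
  if (n_components > feasible) {
    warning("n_components = ", n_components, " exceeds the feasible rank ",
            feasible, "; capping")
    n_components <- feasible
  }
  pc <- stats::prcomp(table$features, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  out <- table
  out$features <- pc$x[, seq_len(k), drop = FALSE]
  attr(out, "rotation") <- pc$rotation[, seq_len(k), drop = FALSE]
  attr(out, "center") <- pc$center
  attr(out, "explained_variance") <- pc$sdev[seq_len(k)]^2
  out
}

cosine_distance_matrix <- function(test, train) {
  # 1 - cosine similarity; zero-norm rows are maximally distant (1).
  nt <- sqrt(rowSums(test^2)); nr <- sqrt(rowSums(train^2))
  sim <- tcrossprod(test, train)
  denom <- outer(nt, nr)
  sim <- ifelse(denom > 0, sim / denom, 0)
  1 - sim
}

knn_predict <- function(train_x, train_y, test_x, neighbors) {
  d <- cosine_distance_matrix(test_x, train_x)
  lvls <- levels(train_y)
  k <- min(neighbors, nrow(train_x))
  apply_row <- function(row) {
    ord <- order(row, as.integer(train_y))   # distance, then class id
    nn <- ord[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      # tie-break: smallest summed distance among tied classes, then lowest id
      sums <- vapply(top, function(cl)
        sum(row[nn][train_y[nn] == cl]), numeric(1))
      top <- top[order(sums, match(top, lvls))][1]
    }
    top
  }
  factor(apply(d, 1, apply_row), levels = lvls)
}

#' Cross-validated cosine-KNN classification
#'
#' Stratified k-fold cross-validation of a k-nearest-neighbour classifier
#' under cosine distance (`1 - cosine similarity`) with majority voting;
#' vote ties break deterministically by smallest summed neighbour distance,
#' then lowest class id. When `n_components` is given, PCA is fitted inside
#' each training fold and test rows are projected onto it (no information
#' leaks from the held-out fold); set `pca_within_fold = FALSE` to fit the
#' PCA once on the full table instead.
#'
#' @param table A [build_feature_table()] result (raw features).
#' @param k_folds Number of folds (default 5).
#' @param neighbors Neighbourhood size (default 10).
#' @param n_components Optional PCA dimensionality (e.g. 35); `NULL`
#'   disables reduction.
#' @param seed Integer seed controlling the fold assignment.
#' @param pca_within_fold Fit the PCA per training fold (default `TRUE`).
#' @return A list of class `"classification_report"`: `fold_accuracies`,
#'   `overall_accuracy`, `confusion` (true x predicted counts),
#'   `chance_level` (exact binomial at alpha = 0.05), `n_components`, and
#'   metadata (`seed`, `neighbors`, `k_folds`, `pca_within_fold`,
#'   `predictions`).
#' @export
crossvalidated_knn <- function(table, k_folds = 5, neighbors = 10,
                               n_components = NULL, seed = 1,
                               pca_within_fold = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  x <- table$features
  n <- nrow(x)
  if (nlevels(y) < 2L) stop_input("need at least 2 classes")
  class_sizes <- table(y)
  if (any(class_sizes < k_folds))
    stop_input("every class needs >= k_folds members (smallest has ",
               min(class_sizes), ", k_folds = ", k_folds, ")")
  folds <- integer(n)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  if (!is.null(n_components) && !pca_within_fold) {
    x <- reduce_dimensions(table, n_components)$features
    n_components_used <- ncol(x)
  } else {
    n_components_used <- n_components
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    tr_x <- x[!test, , drop = FALSE]; te_x <- x[test, , drop = FALSE]
    if (!is.null(n_components) && pca_within_fold) {
      sub <- structure(list(features = tr_x, labels = y[!test],
                            m = table$m), class = "feature_table")
      red <- suppressWarnings(reduce_dimensions(sub, n_components))
      rot <- attr(red, "rotation"); ctr <- attr(red, "center")
      tr_x <- red$features
      te_x <- sweep(te_x, 2, ctr) %*% rot
      n_components_used <- ncol(tr_x)
    }
    pred[test] <- knn_predict(tr_x, y[!test], te_x, neighbors)
    fold_acc[f] <- mean(pred[test] == y[test])
  }
  confusion <- table(true = y, predicted = pred)
  structure(
    list(
      fold_accuracies = fold_acc,
      overall_accuracy = mean(pred == y),
      confusion = confusion,
      chance_level = binomial_chance_level(n, nlevels(y)),
      n_components = n_components_used,
      neighbors = neighbors, k_folds = k_folds, seed = seed,
      pca_within_fold = pca_within_fold,
      predictions = pred
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Cosine-KNN cross-validation:", x$k_folds, "folds,",
      x$neighbors, "neighbours",
      if (!is.null(x$n_components)) paste0(", ", x$n_components, " components"),
      "\n  overall accuracy ", round(100 * x$overall_accuracy, 1),
      "% (chance level ", round(100 * x$chance_level, 1), "%)\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Exact binomial chance level for classification accuracy
#'
#' The smallest accuracy `k/n` whose upper-tail probability under random
#' guessing — `Binomial(n, 1/n_classes)` — falls below `alpha`, computed by
#' exact tail summation. An observed cross-validated accuracy at or above
#' this level is better than chance at the given significance. For `n = 32`
#' recordings and two classes at `alpha = 0.05` the level is 22/32 = 68.75%.
#'
#' @param n Number of classified samples.
#' @param n_classes Number of classes (guessing probability `1/n_classes`).
#' @param alpha Significance level in `(0, 1)`.
#' @return The chance-level accuracy as a fraction in `(0, 1]`.
#' @export
binomial_chance_level <- function(n, n_classes, alpha = 0.05) {
  if (!is_count(n) || n < 1) stop_input("'n' must be a positive count")
  if (!is_count(n_classes) || n_classes < 2)
    stop_input("'n_classes' must be an integer >= 2")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_input("'alpha' must lie in (0, 1)")
  p <- 1 / n_classes
  # P(X >= k) = pbinom(k - 1, n, p, lower.tail = FALSE)
  for (k in 0:n) {
    if (stats::pbinom(k - 1, n, p, lower.tail = FALSE) < alpha)
      return(k / n)
  }
  1
}
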