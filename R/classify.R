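# Exact k-NN predictor: Euclidean distances, majority vote, voting ties
# broken by the label of the single nearest neighbour. Deterministic, so
# fixed folds give byte-identical reports.
knn_predict <- function(train, test, labels, k) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  labels <- as.character(labels)
  apply(test, 1L, function(row) {
    d <- sqrt(colSums((t(train) - row)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else labels[nn[1L]]
  })
}

# Stratified fold assignment: within each class, indices are shuffled under
# the seed and dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(factor(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < folds) {
        stop(sprintf("class '%s' has %d members, fewer than %d folds; use fewer folds",
                     cl, length(idx), folds))
      }
      fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' k-nearest-neighbour cross-validated classification
#'
#' Stratified k-fold cross-validation of a k-NN classifier (default k = 3,
#' 10 folds) on an entropy feature table. Features are z-scored with means
#' and SDs fitted on the training folds only (toggleable); rows containing
#' undefined (`NA`) feature values are dropped with a message. Voting ties
#' are broken by the nearest single neighbour, so a fixed seed gives
#' identical folds and accuracies.
#'
#' @param features `data.frame` or matrix of numeric features
#'   (segments x features).
#' @param labels Class labels, one per row; >= 2 classes.
#' @param k Number of neighbours. @param folds Number of CV folds.
#' @param seed Integer seed driving the fold assignment.
#' @param standardize z-score features on the training folds?
#' @return Object of class `knn_result`: list with `features`, `k`,
#'   `folds`, `fold_accuracy`, `mean_accuracy` (mean over folds),
#'   `pooled_accuracy` (accuracy over all pooled test predictions),
#'   `seed`, `n_used`, `n_dropped`.
#' @export
knn_cross_validate <- function(features, labels, k = 3, folds = 10,
                               seed = 1, standardize = TRUE) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  ok <- stats::complete.cases(features)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " row(s) with undefined feature values")
    features <- features[ok, , drop = FALSE]
    labels <- labels[ok]
  }
  fold <- stratified_folds(labels, folds, seed)
  fold_acc <- numeric(folds)
  pooled_correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    X_tr <- as.matrix(features[tr, , drop = FALSE])
    X_te <- as.matrix(features[!tr, , drop = FALSE])
    if (standardize) {
      mu <- colMeans(X_tr)
      sg <- apply(X_tr, 2L, stats::sd)
      sg[sg == 0] <- 1
      X_tr <- sweep(sweep(X_tr, 2L, mu), 2L, sg, "/")
      X_te <- sweep(sweep(X_te, 2L, mu), 2L, sg, "/")
    }
    pred <- knn_predict(X_tr, X_te, labels[tr], k)
    hits <- pred == labels[!tr]
    fold_acc[f] <- mean(hits)
    pooled_correct <- pooled_correct + sum(hits)
  }
  structure(list(features = names(features), k = k, folds = folds,
                 fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = pooled_correct / nrow(features),
                 seed = seed, n_used = nrow(features),
                 n_dropped = sum(!ok)),
            class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf("<knn_result> {%s}: mean accuracy %.3f (pooled %.3f), k = %d, %d folds\n",
              paste(x$features, collapse = ", "), x$mean_accuracy,
              x$pooled_accuracy, x$k, x$folds))
  invisible(x)
}

#' Exhaustive entropy-feature combination search
#'
#' Evaluates [knn_cross_validate()] on every feature set of size 1 to
#' `max_size` subject to the family-exclusion rule: no set may contain two
#' configurations of the same algorithm family (so five features means one
#' per family). Results are ranked by mean accuracy, ties broken by
#' smaller set then lexicographic column order.
#'
#' @inheritParams knn_cross_validate
#' @param families Named character vector mapping feature column names to
#'   algorithm families; defaults to the `"family"` attribute of
#'   `features` (set by [batch_entropy()]).
#' @param max_size Largest feature-set size, 1-5.
#' @return `data.frame` ranked by mean accuracy, with columns `size`,
#'   `features` (comma-separated), `mean_accuracy`, `pooled_accuracy`, and
#'   the full `knn_result` list in attribute `results` (same order).
#' @export
feature_combination_search <- function(features, labels,
                                       families = attr(features, "family"),
                                       max_size = 2, k = 3, folds = 10,
                                       seed = 1) {
  stopifnot(max_size >= 1L, max_size <= 5L)
  features <- as.data.frame(features)
  if (is.null(families)) stop("feature columns must carry family tags")
  stopifnot(all(names(features) %in% names(families)))
  sets <- list()
  for (size in seq_len(min(max_size, ncol(features)))) {
    cand <- utils::combn(names(features), size, simplify = FALSE)
    keep <- vapply(cand, function(cols) !anyDuplicated(families[cols]), TRUE)
    sets <- c(sets, cand[keep])
  }
  results <- lapply(sets, function(cols) {
    knn_cross_validate(features[, cols, drop = FALSE], labels,
                       k = k, folds = folds, seed = seed)
  })
  tab <- data.frame(
    size = lengths(sets),
    features = vapply(sets, paste, "", collapse = ", "),
    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"),
    pooled_accuracy = vapply(results, `[[`, 0, "pooled_accuracy"),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$mean_accuracy, tab$size, tab$features)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}

#' Assemble a machine- and human-readable study report
#'
#' Tabulates group-test results and classification results: per-comparison
#' statistics and significance flags, and the best accuracy per
#' feature-set size. Written as JSON when `path` is given (deterministic
#' content, so fixed-seed runs are byte-identical).
#'
#' @param test_results Named list of `group_test` objects (may be empty).
#' @param classification Ranked `data.frame` from
#'   [feature_combination_search()], or `NULL`.
#' @param path Optional JSON output path.
#' @return List with elements `tests` (`data.frame`) and `best_by_size`
#'   (`data.frame`, absent rows when no classification input), invisibly.
#' @export
study_report <- function(test_results = list(), classification = NULL,
                         path = NULL) {
  tests <- if (length(test_results)) {
    data.frame(
      comparison = names(test_results),
      test = vapply(test_results, `[[`, "", "test"),
      statistic = vapply(test_results, `[[`, 0, "statistic"),
      p_value = vapply(test_results, `[[`, 0, "p_value"),
      significant = vapply(test_results, `[[`, TRUE, "significant"),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(comparison = character(0), test = character(0),
               statistic = numeric(0), p_value = numeric(0),
               significant = logical(0))
  }
  best_by_size <- if (!is.null(classification) && nrow(classification)) {
    do.call(rbind, lapply(split(classification, classification$size),
                          function(d) d[which.max(d$mean_accuracy), ]))
  } else {
    data.frame(size = integer(0), features = character(0),
               mean_accuracy = numeric(0), pooled_accuracy = numeric(0))
  }
  rownames(best_by_size) <- NULL
  report <- list(tests = tests, best_by_size = best_by_size)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
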