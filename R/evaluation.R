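# stratified fold assignment: within each class, shuffle then deal out folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      abort(sprintf(
        "Class '%s' has %d members, fewer than %d folds; use fewer folds.",
        cl, length(idx), k), class = "ckalign_parameter_error")
    }
    idx <- sample(idx)
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# z-score by training statistics only (leakage-safe); constant columns -> 1
scale_train_test <- function(Xtr, Xte) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  scl[scl < .Machine$double.eps] <- 1
  list(train = sweep(sweep(Xtr, 2L, ctr, "-"), 2L, scl, "/"),
       test = sweep(sweep(Xte, 2L, ctr, "-"), 2L, scl, "/"))
}

knn_accuracy <- function(Xtr, ltr, Xte, lte, k) {
  pred <- class::knn(Xtr, Xte, factor(ltr), k = k)
  mean(as.character(pred) == as.character(lte))
}

#' k-NN accuracy under nested stratified cross-validation
#'
#' Outer stratified folds estimate generalization; within each outer
#' training portion, inner stratified folds pick the neighbour count `k`
#' from `k_grid` by mean inner accuracy (ties go to the smallest `k`). The
#' winning `k` is refit on the full outer-training set and scored on the
#' held-out fold. Features are z-scored with training-fold statistics only,
#' and the distance is Euclidean. Deterministic given `seed`.
#'
#' @param data data frame of numeric features plus a label column.
#' @param labels label column name (default `"class"`).
#' @param k_grid candidate neighbour counts (default `c(1, 3, 5, 7, 9, 11)`).
#' @param outer_folds,inner_folds fold counts (default 10 and 10).
#' @param seed integer seed driving fold assignment (and k-NN vote
#'   tie-breaks).
#' @return object of class `cv_result`: `accuracy_mean` and `accuracy_sd`
#'   (percent), `chosen_k` per outer fold, `fold_accuracy`, and the settings.
#' @export
knn_nested_cv <- function(data, labels = "class",
                          k_grid = c(1, 3, 5, 7, 9, 11),
                          outer_folds = 10, inner_folds = 10, seed = 1) {
  parts <- split_features_labels(data, labels)
  X <- parts$X
  l <- parts$labels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  fold <- stratified_folds(l, outer_folds)
  fold_acc <- numeric(outer_folds)
  chosen_k <- integer(outer_folds)
  for (fo in seq_len(outer_folds)) {
    tr <- which(fold != fo)
    te <- which(fold == fo)
    inner_fold <- stratified_folds(l[tr], inner_folds)
    inner_acc <- matrix(0, inner_folds, length(k_grid))
    for (fi in seq_len(inner_folds)) {
      itr <- tr[inner_fold != fi]
      ite <- tr[inner_fold == fi]
      sc <- scale_train_test(X[itr, , drop = FALSE], X[ite, , drop = FALSE])
      for (ki in seq_along(k_grid)) {
        inner_acc[fi, ki] <- knn_accuracy(sc$train, l[itr], sc$test, l[ite],
                                          k_grid[ki])
      }
    }
    best <- which.max(colMeans(inner_acc))   # first max -> smallest k wins
    chosen_k[fo] <- k_grid[best]
    sc <- scale_train_test(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fold_acc[fo] <- knn_accuracy(sc$train, l[tr], sc$test, l[te], k_grid[best])
  }
  structure(
    list(accuracy_mean = 100 * mean(fold_acc),
         accuracy_sd = 100 * stats::sd(fold_acc),
         chosen_k = chosen_k, fold_accuracy = 100 * fold_acc,
         k_grid = k_grid, outer_folds = outer_folds,
         inner_folds = inner_folds, seed = seed,
         stratified = TRUE, scaling = "train-fold z-score"),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result>  accuracy %.2f%% +/- %.2f%% (%d outer folds)\n",
              x$accuracy_mean, x$accuracy_sd, x$outer_folds))
  cat("  chosen k per fold:", paste(x$chosen_k, collapse = " "), "\n")
  invisible(x)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(accuracy_mean = x$accuracy_mean,
                 accuracy_sd = x$accuracy_sd,
                 outer_folds = x$outer_folds, inner_folds = x$inner_folds,
                 seed = x$seed)
}

# evaluation schedule for the accuracy-vs-rank curve: every size up to
# `dense_until`, then geometric steps, always ending at P
curve_schedule <- function(P, dense_until = 50, ratio = 1.25) {
  if (P <= dense_until) return(seq_len(P))
  js <- seq_len(dense_until)
  j <- dense_until
  while (j < P) {
    j <- min(P, ceiling(j * ratio))
    js <- c(js, j)
  }
  unique(js)
}

#' Accuracy as features are added in relevance order
#'
#' Evaluates [knn_nested_cv()] on the top-`j` ranked features for growing
#' `j`, yielding the accuracy-versus-ranked-features curve. The selected-set
#' size is the smallest `j` attaining the curve maximum. For large feature
#' counts a stride schedule (every size up to 50, then geometric steps) keeps
#' the cost manageable; `full_resolution = TRUE` evaluates every size.
#'
#' @inheritParams knn_nested_cv
#' @param ranking feature names (or column indices) in decreasing relevance
#'   order; a permutation of the feature columns.
#' @param full_resolution evaluate every prefix size?
#' @return object of class `cv_curve`: tibble `curve` with columns
#'   `n_features`, `accuracy_mean`, `accuracy_sd`, plus `n_selected` and
#'   `max_accuracy`.
#' @export
accuracy_rank_curve <- function(data, ranking, labels = "class",
                                k_grid = c(1, 3, 5, 7, 9, 11),
                                outer_folds = 10, inner_folds = 10,
                                seed = 1, full_resolution = FALSE) {
  feat_names <- setdiff(names(data), labels)
  if (is.numeric(ranking)) ranking <- feat_names[ranking]
  if (!setequal(ranking, feat_names) || length(ranking) != length(feat_names)) {
    abort("`ranking` must be a permutation of the feature columns.",
          class = "ckalign_validation_error")
  }
  P <- length(ranking)
  sizes <- if (full_resolution) seq_len(P) else curve_schedule(P)
  rows <- purrr::map(sizes, function(j) {
    cv <- knn_nested_cv(data[c(ranking[seq_len(j)], labels)], labels = labels,
                        k_grid = k_grid, outer_folds = outer_folds,
                        inner_folds = inner_folds, seed = seed)
    tibble::tibble(n_features = j, accuracy_mean = cv$accuracy_mean,
                   accuracy_sd = cv$accuracy_sd)
  })
  curve <- dplyr::bind_rows(rows)
  best <- max(curve$accuracy_mean)
  n_sel <- curve$n_features[which(curve$accuracy_mean >= best - 1e-12)[1L]]
  structure(list(curve = curve, n_selected = n_sel, max_accuracy = best,
                 seed = seed),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve>  max accuracy %.2f%% at %d features\n",
              x$max_accuracy, x$n_selected))
  invisible(x)
}

#' @export
tidy.cv_curve <- function(x, ...) x$curve

#' Accuracy-vs-ranked-features plot
#'
#' @param object a `cv_curve`.
#' @param ... unused.
#' @return a ggplot with a ribbon of +/- one standard deviation and a marker
#'   at the selected-set size.
#' @export
autoplot.cv_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features,
                                   y = .data$accuracy_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$accuracy_mean - .data$accuracy_sd,
      ymax = .data$accuracy_mean + .data$accuracy_sd), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$n_selected, linetype = 2) +
    ggplot2::labs(x = "ranked features included", y = "accuracy (%)",
                  title = "Accuracy vs. ranked features")
}

#' Dimension-reduction factor
#'
#' Total feature count divided by the number of selected features.
#'
#' @param p total number of features.
#' @param n_selected selected count (must be in \[1, p\]).
#' @return numeric factor `p / n_selected`.
#' @examples
#' dimension_reduction_factor(1593, 275)   # ~5.79
#' @export
dimension_reduction_factor <- function(p, n_selected) {
  if (n_selected < 1 || n_selected > p) {
    abort("`n_selected` must be in [1, p].", class = "ckalign_parameter_error")
  }
  p / n_selected
}

#' Relevance marginals by channel and extraction principle
#'
#' Groups a relevance table by the channel and by the extraction principle
#' encoded in the feature names (`channel.principle.quantity.statistic`, as
#' produced by [eeg_feature_bank()]), returning each group's mean and
#' standard deviation of relevance — the numeric substrate of per-region
#' relevance maps.
#'
#' @param rel relevance table with columns `feature`, `rho`.
#' @param feature_info optional tibble mapping features to `channel` and
#'   `principle` (the `"feature_info"` attribute of [eeg_feature_bank()]
#'   output); parsed from the names when absent.
#' @return list of two tibbles, `by_channel` and `by_principle`, each with
#'   group, `rho_mean`, `rho_sd`, `n`.
#' @export
relevance_by_group <- function(rel, feature_info = NULL) {
  stopifnot(is.data.frame(rel), all(c("feature", "rho") %in% names(rel)))
  if (is.null(feature_info)) {
    parts <- strsplit(rel$feature, ".", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) {
      abort(sprintf(
        "Cannot parse feature name '%s' (expected channel.principle.quantity.statistic).",
        rel$feature[bad[1L]]), class = "ckalign_validation_error")
    }
    feature_info <- tibble::tibble(
      feature = rel$feature,
      channel = vapply(parts, `[`, "", 1L),
      principle = vapply(parts, `[`, "", 2L))
  }
  df <- dplyr::left_join(rel, feature_info, by = "feature")
  summarize_by <- function(df, col) {
    df |>
      dplyr::group_by(.data[[col]]) |>
      dplyr::summarise(rho_mean = mean(.data$rho),
                       rho_sd = stats::sd(.data$rho),
                       n = dplyr::n(), .groups = "drop")
  }
  list(by_channel = summarize_by(df, "channel"),
       by_principle = summarize_by(df, "principle"))
}
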