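# internal validation helpers shared across modules

check_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg), class = "ckalign_shape_error")
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg), class = "ckalign_validation_error")
  }
  invisible(x)
}

check_square <- function(x, arg = deparse(substitute(x))) {
  check_matrix(x, arg)
  if (nrow(x) != ncol(x)) {
    abort(sprintf("`%s` must be square (got %d x %d).", arg, nrow(x), ncol(x)),
          class = "ckalign_shape_error")
  }
  invisible(x)
}

check_scalar_positive <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", arg),
          class = "ckalign_parameter_error")
  }
  invisible(x)
}

# Split a data frame into a numeric feature matrix and a label vector.
# `labels` names the label column; all remaining columns must be numeric.
split_features_labels <- function(data, labels = "class") {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "ckalign_validation_error")
  }
  if (!labels %in% names(data)) {
    abort(sprintf("Label column '%s' not found in `data`.", labels),
          class = "ckalign_validation_error")
  }
  l <- data[[labels]]
  feat <- data[setdiff(names(data), labels)]
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Non-numeric feature column(s): %s.", paste(bad, collapse = ", ")),
          class = "ckalign_validation_error")
  }
  X <- as.matrix(feat)
  check_matrix(X, "data (features)")
  if (nrow(X) < 2L) {
    abort("Need at least 2 samples.", class = "ckalign_validation_error")
  }
  list(X = X, labels = l, feature_names = colnames(X))
}

# column z-scoring with a zero-variance guard (constant columns get scale 1)
standardize_columns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}
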