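# ranks with deterministic index-order tie-break, largest value = rank 1
rank_decreasing <- function(rho) {
  ord <- order(-rho, seq_along(rho))
  rk <- integer(length(rho))
  rk[ord] <- seq_along(rho)
  rk
}

#' Feature relevance index from a projection matrix
#'
#' The relevance of feature \eqn{p} is the mean absolute value of row
#' \eqn{p} of the learned projection,
#' \eqn{\varrho_p = \mathrm{E}_m\{|a_{pm}|\}}: features whose rows carry
#' more weight contribute more to the class-discriminative metric.
#'
#' @param A numeric projection matrix (features in rows).
#' @return nonnegative numeric vector of length `nrow(A)`.
#' @export
relevance_vector <- function(A) {
  check_matrix(A)
  if (nrow(A) < 1L || ncol(A) < 1L) {
    abort("`A` must be non-empty.", class = "ckalign_validation_error")
  }
  rowMeans(abs(A))
}

#' Relevance table of a fitted model
#'
#' Convenience wrapper around [tidy.cka_fit()]: per-feature relevance and
#' rank as a tibble, ready for [select_features()].
#'
#' @param fit a `cka_fit`.
#' @return tibble with columns `feature`, `rho`, `rank`.
#' @export
relevance <- function(fit) {
  stopifnot(inherits(fit, "cka_fit"))
  tidy(fit)
}

# low-level selection on a plain numeric relevance vector -> integer indices
select_indices <- function(rho, rule = c("variance_explained",
                                         "mean_threshold", "top_k"),
                           param = 0.95) {
  rule <- match.arg(rule)
  P <- length(rho)
  ord <- order(-rho, seq_len(P))
  idx <- switch(rule,
    mean_threshold = which(rho > mean(rho)),
    variance_explained = {
      cs <- cumsum(rho[ord])
      m <- if (sum(rho) <= 0) 0L else which(cs >= param * sum(rho))[1L]
      ord[seq_len(m)]
    },
    top_k = {
      k <- as.integer(param)
      if (is.na(k) || k < 1L || k > P) {
        abort(sprintf("`param` (k) must be in [1, %d] for top_k.", P),
              class = "ckalign_parameter_error")
      }
      ord[seq_len(k)]
    })
  if (length(idx) == 0L) {
    warn("Selection rule kept no feature; falling back to the top-1 feature.")
    idx <- ord[1L]
  }
  # return in decreasing-relevance order
  idx[order(rank_decreasing(rho)[idx])]
}

#' Select features by relevance
#'
#' Applies a selection rule to a relevance table:
#' \describe{
#'   \item{`variance_explained`}{keep the shortest ranked prefix holding at
#'     least `param` (default 0.95) of the total relevance mass;}
#'   \item{`mean_threshold`}{keep features with \eqn{\varrho_p} strictly above
#'     the mean relevance;}
#'   \item{`top_k`}{keep the `param` highest-ranked features.}
#' }
#' An empty selection (possible under the strict mean threshold when all
#' relevances tie) falls back to the single top-ranked feature with a warning.
#'
#' @param rel relevance table with columns `feature`, `rho` (from
#'   [relevance()] or [vra_relevance()]).
#' @param rule selection rule.
#' @param param rule parameter: mass fraction for `variance_explained`,
#'   ignored for `mean_threshold`, `k` for `top_k`.
#' @return the table with an added logical `selected` column, ordered as the
#'   input; attribute `"selected"` carries the kept feature names in
#'   decreasing-relevance order.
#' @export
select_features <- function(rel, rule = c("variance_explained",
                                          "mean_threshold", "top_k"),
                            param = 0.95) {
  stopifnot(is.data.frame(rel), all(c("feature", "rho") %in% names(rel)))
  idx <- select_indices(rel$rho, rule, param)
  out <- rel
  out$selected <- seq_len(nrow(rel)) %in% idx
  attr(out, "selected") <- rel$feature[idx]
  out
}

#' Supervised relevance-based feature selection
#'
#' Stage one of the pipeline: fit the alignment-maximizing projection
#' ([cka_fit()]), score each feature by its mean absolute projection weight,
#' and keep features by the chosen rule. Deterministic given the input (the
#' fit itself has no random component once the data are fixed).
#'
#' @inheritParams cka_fit
#' @inheritParams select_features
#' @return object of class `cka_selection`: the inner `fit`, the relevance
#'   table (`relevance`, with `selected` flags), the kept feature names
#'   (`selected`), and `data_selected` (kept columns plus the label column).
#' @examples
#' sim <- simulate_tabular(n_samples = 60, n_features = 10, n_informative = 2,
#'                         seed = 7)
#' sel <- cka_select(sim$data, control = cka_control(max_iterations = 30))
#' glance(sel)
#' @export
cka_select <- function(data, labels = "class",
                       rule = c("variance_explained", "mean_threshold",
                                "top_k"),
                       param = 0.95, n_dim = NULL, var_explained = 0.95,
                       control = cka_control()) {
  rule <- match.arg(rule)
  fit <- cka_fit(data, labels = labels, n_dim = n_dim,
                 var_explained = var_explained, control = control)
  rel <- select_features(relevance(fit), rule = rule, param = param)
  sel_names <- attr(rel, "selected")
  structure(
    list(fit = fit, relevance = rel, selected = sel_names,
         rule = rule, param = param,
         data_selected = data[c(sel_names, labels)]),
    class = "cka_selection")
}

#' @export
print.cka_selection <- function(x, ...) {
  cat(sprintf("<cka_selection>  kept %d of %d features (rule %s)\n",
              length(x$selected), nrow(x$relevance), x$rule))
  cat("  top features:", paste(head(x$selected, 8), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cka_selection <- function(x, ...) x$relevance

#' @export
glance.cka_selection <- function(x, ...) {
  P <- nrow(x$relevance)
  tibble::tibble(
    n_features = P, n_selected = length(x$selected),
    reduction_factor = dimension_reduction_factor(P, length(x$selected)),
    rule = x$rule, cka = x$fit$cka, converged = x$fit$converged)
}

#' Relevance-selected discriminative embedding
#'
#' Stage two: after relevance-based selection ([cka_select()]), a second
#' alignment-maximizing projection is learned on the selected columns alone,
#' and the samples are mapped through it, \eqn{Y = X' A'}. The embedding
#' dimension is chosen by the variance-explained rule on the selected
#' features and never exceeds the number of selected features.
#'
#' @inheritParams cka_select
#' @param embed_var_explained variance fraction fixing the embedding
#'   dimension (default 0.95).
#' @return object of class `cka_embedding`: the stage-one `selection`, the
#'   stage-two `fit`, the projection `A_prime`, and the embedded coordinates
#'   `Y` (tibble with the label column attached).
#' @export
cka_embed <- function(data, labels = "class",
                      rule = c("variance_explained", "mean_threshold",
                               "top_k"),
                      param = 0.95, n_dim = NULL, var_explained = 0.95,
                      embed_var_explained = 0.95, control = cka_control()) {
  rule <- match.arg(rule)
  selection <- cka_select(data, labels = labels, rule = rule, param = param,
                          n_dim = n_dim, var_explained = var_explained,
                          control = control)
  fit2 <- cka_fit(selection$data_selected, labels = labels,
                  var_explained = embed_var_explained, control = control)
  Y <- predict(fit2, selection$data_selected)
  structure(
    list(selection = selection, fit = fit2, A_prime = fit2$A, Y = Y,
         n_selected = length(selection$selected), n_embedded = fit2$n_dim),
    class = "cka_embedding")
}

#' @export
print.cka_embedding <- function(x, ...) {
  cat(sprintf("<cka_embedding>  %d features -> %d selected -> %d dims\n",
              nrow(x$selection$relevance), x$n_selected, x$n_embedded))
  invisible(x)
}

#' @export
glance.cka_embedding <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$selection$relevance),
    n_selected = x$n_selected, n_embedded = x$n_embedded,
    cka_stage1 = x$selection$fit$cka, cka_stage2 = x$fit$cka)
}

#' Variance-based relevance (unsupervised baseline)
#'
#' PCA baseline that ignores labels: after column centering, feature
#' relevance is the eigenvalue-weighted sum of absolute loadings over the
#' components retaining `var_fraction` of the total variance,
#' \eqn{\varrho_p = \sum_m \lambda_m |v_{pm}|}. The decomposition is
#' deliberately variance-preserving (columns are centered but not rescaled):
#' being driven by raw variability — and therefore misleadable by
#' high-variance nuisance features — is exactly the behaviour this baseline
#' exists to expose. Zero-variance features get zero relevance.
#'
#' @param data data frame with numeric feature columns (a label column, if
#'   named via `labels`, is dropped before the decomposition).
#' @param labels optional label column name to exclude (default `"class"` if
#'   present, ignored otherwise).
#' @param var_fraction variance fraction determining how many components are
#'   aggregated (default 0.95).
#' @return tibble with columns `feature`, `rho`, `rank`.
#' @export
vra_relevance <- function(data, labels = "class", var_fraction = 0.95) {
  stopifnot(is.data.frame(data))
  feat <- data[setdiff(names(data), labels)]
  X <- as.matrix(feat)
  check_matrix(X, "data (features)")
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > .Machine$double.eps
  if (!any(keep)) {
    abort("All features constant: variance-based relevance undefined.",
          class = "ckalign_degenerate_error")
  }
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  m <- which(cumsum(ev) / sum(ev) >= var_fraction)[1L]
  lam <- ev[seq_len(m)]
  V <- abs(pc$rotation[, seq_len(m), drop = FALSE])
  rho <- rep(0, ncol(X))
  rho[keep] <- as.numeric(V %*% lam)
  tibble::tibble(feature = colnames(X), rho = rho,
                 rank = rank_decreasing(rho))
}

#' Relevance profile plot
#'
#' Bar plot of per-feature relevance in rank order, colored by selection
#' status when a `selected` column is present.
#'
#' @param rel relevance table (optionally with a `selected` column).
#' @return a ggplot.
#' @export
plot_relevance <- function(rel) {
  stopifnot(is.data.frame(rel), all(c("feature", "rho", "rank") %in% names(rel)))
  df <- rel[order(rel$rank), ]
  df$feature <- factor(df$feature, levels = df$feature)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$rho))
  p <- if ("selected" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$selected))
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = "relevance", title = "Feature relevance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
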