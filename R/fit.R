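#' Optimizer settings for the alignment learner
#'
#' @param tolerance stop when the absolute change in the log-alignment
#'   objective between accepted iterates falls below this (default `1e-6`).
#' @param max_iterations cap on ascent iterations (default 300).
#' @param learn_sigma jointly optimize the kernel bandwidth (log-parameterized
#'   so it stays positive) alongside the projection? Default `TRUE`; when
#'   `FALSE` the bandwidth stays at its median-distance initialization.
#' @param step_rule `"backtracking"` (Armijo line search, guarantees a
#'   nondecreasing objective trace) or `"fixed"`.
#' @param initial_step initial step size for either rule.
#' @param armijo_c sufficient-increase constant for backtracking.
#' @param shrink step shrink factor for backtracking.
#' @return a list of class `cka_control`.
#' @export
cka_control <- function(tolerance = 1e-6, max_iterations = 300,
                        learn_sigma = TRUE,
                        step_rule = c("backtracking", "fixed"),
                        initial_step = 1, armijo_c = 1e-4, shrink = 0.5) {
  check_scalar_positive(tolerance, "tolerance")
  if (!is.numeric(max_iterations) || length(max_iterations) != 1L ||
      max_iterations < 1 || max_iterations != round(max_iterations)) {
    abort("`max_iterations` must be a positive integer.",
          class = "ckalign_parameter_error")
  }
  check_scalar_positive(initial_step, "initial_step")
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         learn_sigma = isTRUE(learn_sigma), step_rule = match.arg(step_rule),
         initial_step = initial_step, armijo_c = armijo_c, shrink = shrink),
    class = "cka_control")
}

#' PCA initialization of the projection matrix
#'
#' Columns of the start value are the top-`M` principal directions of the
#' column-standardized data, with the sign convention that each column's
#' largest-magnitude loading is positive (deterministic across platforms).
#'
#' @param X numeric matrix, samples in rows.
#' @param M number of projection columns, `1 <= M <= min(N - 1, P)`.
#' @return P x M matrix.
#' @export
init_projection <- function(X, M) {
  check_matrix(X)
  max_m <- min(nrow(X) - 1L, ncol(X))
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M > max_m) {
    abort(sprintf("`M` must be in [1, %d].", max_m),
          class = "ckalign_parameter_error")
  }
  Xs <- standardize_columns(X)$X
  rot <- prcomp(Xs, center = FALSE, scale. = FALSE)$rotation[, seq_len(M), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(rot, 2L, flip, "*")
}

#' Median-distance bandwidth initialization
#'
#' The bandwidth start value is the median of the off-diagonal pairwise
#' Euclidean distances of the projected samples \eqn{XA} — the standard
#' median heuristic.
#'
#' @inheritParams init_projection
#' @param A projection matrix (P x M).
#' @return positive scalar.
#' @export
init_sigma <- function(X, A) {
  check_matrix(X)
  d <- sqrt(pairwise_sqdist(X, A))
  s <- median(d[upper.tri(d)])
  if (!is.finite(s) || s <= 0) {
    abort("All projected samples coincide; bandwidth undefined.",
          class = "ckalign_degenerate_error")
  }
  s
}

#' Log-alignment objective
#'
#' \eqn{\log \hat\rho(K_X(A,\sigma), K_l)} for the Gaussian kernel on the
#' projected features. Always `<= 0` since \eqn{\hat\rho \le 1}.
#'
#' @param X numeric matrix, samples in rows (not standardized here; callers
#'   choose the scaling).
#' @param labels class label vector (length `nrow(X)`).
#' @param A projection matrix P x M.
#' @param sigma positive kernel bandwidth.
#' @return scalar log-alignment.
#' @export
cka_objective <- function(X, labels, A, sigma) {
  Klc <- center_kernel(label_kernel(labels))
  obj_parts(X, Klc, A, sigma)$f
}

# shared plumbing: returns objective plus the pieces the gradient reuses
obj_parts <- function(X, Klc, A, sigma) {
  D2 <- pairwise_sqdist(X, A)
  K <- exp(-D2 / (2 * sigma^2))
  Kc <- center_kernel(K)
  den_x <- sum(Kc * Kc)
  den_l <- sum(Klc * Klc)
  if (den_x < 1e-300 || den_l < 1e-300) {
    abort("Degenerate alignment: centered kernel identically zero.",
          class = "ckalign_degenerate_error")
  }
  num <- sum(Kc * Klc)
  f <- if (num <= 0) -Inf else log(num) - 0.5 * log(den_x) - 0.5 * log(den_l)
  list(f = f, D2 = D2, K = K, Kc = Kc, num = num, den_x = den_x)
}

#' Analytic gradient of the log-alignment objective
#'
#' Chain rule through the Gaussian kernel and the projected-distance form.
#' With \eqn{G = \bar K_l / \langle \bar K_X, \bar K_l\rangle -
#' \bar K_X / \langle \bar K_X, \bar K_X\rangle} and elementwise
#' \eqn{W = -(G \circ K)/(2\sigma^2)}, the gradient with respect to `A` is
#' \eqn{4\, X^\top (\mathrm{diag}(W 1) - W) X A} and the gradient with respect
#' to \eqn{\log\sigma} is \eqn{\sum_{nn'} G_{nn'} K_{nn'} d^2_{nn'} / \sigma^2}.
#'
#' @inheritParams cka_objective
#' @return list with `A` (P x M matrix) and `log_sigma` (scalar).
#' @export
cka_gradient <- function(X, labels, A, sigma) {
  Klc <- center_kernel(label_kernel(labels))
  parts <- obj_parts(X, Klc, A, sigma)
  grad_parts(X, Klc, A, sigma, parts)
}

grad_parts <- function(X, Klc, A, sigma, parts) {
  if (!is.finite(parts$f)) {
    abort("Objective not finite at the evaluation point.",
          class = "ckalign_divergence_error")
  }
  G <- Klc / parts$num - parts$Kc / parts$den_x
  W <- -(G * parts$K) / (2 * sigma^2)
  L <- diag(rowSums(W)) - W
  gA <- 4 * crossprod(X, L %*% X) %*% A
  g_ls <- sum(G * parts$K * parts$D2) / sigma^2
  list(A = gA, log_sigma = g_ls)
}

#' Fit the alignment-maximizing projection
#'
#' Gradient ascent on \eqn{\log \hat\rho(K_X(A,\sigma), K_l)} over the linear
#' projection `A` (and, by default, the kernel bandwidth). Feature columns
#' are standardized internally (center and scale are stored in the model and
#' applied by [predict.cka_fit()]); the projection is initialized from PCA of
#' the standardized features and the bandwidth from the median pairwise
#' projected distance. Iteration stops when the objective improves by less
#' than `control$tolerance` or after `control$max_iterations` steps.
#'
#' @param data data frame holding numeric feature columns and one label
#'   column.
#' @param labels name of the label column (default `"class"`).
#' @param n_dim number of projection columns `M`. Default: the number of
#'   principal components needed to retain `var_explained` of the variance of
#'   the standardized features.
#' @param var_explained variance fraction behind the default `n_dim`
#'   (default 0.95).
#' @param control optimizer settings from [cka_control()].
#' @param verbose print the objective per accepted iteration?
#' @return an object of class `cka_fit`: the learned projection `A`
#'   (rows = features), bandwidth `sigma`, the accepted objective trace, the
#'   final alignment `cka`, convergence info, and the stored column
#'   center/scale.
#' @seealso [relevance()], [cka_select()], [cka_embed()]
#' @examples
#' sim <- simulate_tabular(n_samples = 60, n_features = 8, n_informative = 2,
#'                         seed = 1)
#' fit <- cka_fit(sim$data, control = cka_control(max_iterations = 25))
#' glance(fit)
#' @export
cka_fit <- function(data, labels = "class", n_dim = NULL,
                    var_explained = 0.95, control = cka_control(),
                    verbose = FALSE) {
  parts <- split_features_labels(data, labels)
  X0 <- parts$X
  l <- parts$labels
  if (length(unique(l)) < 2L) {
    abort("All labels identical: alignment to a single class is undefined.",
          class = "ckalign_degenerate_error")
  }
  std <- standardize_columns(X0)
  X <- std$X
  if (is.null(n_dim)) {
    ev <- prcomp(X, center = FALSE)$sdev^2
    n_dim <- max(1L, which(cumsum(ev) / sum(ev) >= var_explained)[1L])
    n_dim <- min(n_dim, nrow(X) - 1L, ncol(X))
  }
  A <- init_projection(X0, n_dim)
  sigma <- init_sigma(X, A)
  Klc <- center_kernel(label_kernel(l))

  cur <- obj_parts(X, Klc, A, sigma)
  if (!is.finite(cur$f)) {
    abort("Objective not finite at initialization.",
          class = "ckalign_divergence_error")
  }
  trace <- cur$f
  converged <- FALSE
  step <- control$initial_step
  iter <- 0L
  while (iter < control$max_iterations) {
    iter <- iter + 1L
    g <- grad_parts(X, Klc, A, sigma, cur)
    gnorm2 <- sum(g$A^2) + if (control$learn_sigma) g$log_sigma^2 else 0
    if (gnorm2 == 0) { converged <- TRUE; break }

    if (control$step_rule == "backtracking") {
      alpha <- control$initial_step
      accepted <- FALSE
      for (bt in 1:40) {
        A_new <- A + alpha * g$A
        sig_new <- if (control$learn_sigma) {
          sigma * exp(alpha * g$log_sigma)
        } else sigma
        cand <- tryCatch(obj_parts(X, Klc, A_new, sig_new),
                         ckalign_degenerate_error = function(e) list(f = -Inf))
        if (is.finite(cand$f) &&
            cand$f >= cur$f + control$armijo_c * alpha * gnorm2) {
          accepted <- TRUE
          break
        }
        alpha <- alpha * control$shrink
      }
      if (!accepted) { converged <- TRUE; break }  # no ascent direction left
    } else {
      alpha <- step
      A_new <- A + alpha * g$A
      sig_new <- if (control$learn_sigma) sigma * exp(alpha * g$log_sigma) else sigma
      cand <- obj_parts(X, Klc, A_new, sig_new)
      if (!is.finite(cand$f)) {
        abort(sprintf("Objective became non-finite at iteration %d.", iter),
              class = "ckalign_divergence_error")
      }
    }
    delta <- cand$f - cur$f
    A <- A_new
    sigma <- sig_new
    cur <- cand
    trace <- c(trace, cur$f)
    if (verbose) message(sprintf("iter %3d  objective %.8f", iter, cur$f))
    if (abs(delta) < control$tolerance) { converged <- TRUE; break }
  }

  structure(
    list(A = A, sigma = sigma, center = std$center, scale = std$scale,
         feature_names = parts$feature_names, labels_col = labels,
         objective_trace = trace, objective = cur$f, cka = exp(cur$f),
         converged = converged, n_iterations = iter, n_dim = ncol(A),
         n_samples = nrow(X), control = control),
    class = "cka_fit")
}

#' Project new data with a fitted model
#'
#' Applies the stored column standardization and the learned projection,
#' returning the embedded coordinates.
#'
#' @param object a `cka_fit`.
#' @param newdata data frame containing at least the model's feature columns.
#' @param ... unused.
#' @return tibble with columns `y1 ... yM` (plus the label column if present
#'   in `newdata`).
#' @export
predict.cka_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols)) {
    abort(sprintf("`newdata` lacks feature column(s): %s.",
                  paste(head(missing_cols, 5), collapse = ", ")),
          class = "ckalign_validation_error")
  }
  X <- as.matrix(newdata[object$feature_names])
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
  Y <- Xs %*% object$A
  colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  out <- tibble::as_tibble(Y)
  if (object$labels_col %in% names(newdata)) {
    out[[object$labels_col]] <- newdata[[object$labels_col]]
  }
  out
}

#' @export
print.cka_fit <- function(x, ...) {
  cat(sprintf("<cka_fit>  %d features -> %d dims, %d samples\n",
              nrow(x$A), x$n_dim, x$n_samples))
  cat(sprintf("  alignment %.4f (log %.6f), sigma %.4g\n",
              x$cka, x$objective, x$sigma))
  cat(sprintf("  %d iterations, converged: %s\n", x$n_iterations, x$converged))
  invisible(x)
}

#' Per-feature summary of a fitted projection
#'
#' One row per input feature with its relevance index (mean absolute
#' projection weight across columns, see [relevance()]) and rank.
#'
#' @param x a `cka_fit`.
#' @param ... unused.
#' @return tibble with columns `feature`, `rho`, `rank`.
#' @export
tidy.cka_fit <- function(x, ...) {
  rho <- relevance_vector(x$A)
  tibble::tibble(
    feature = x$feature_names,
    rho = rho,
    rank = rank_decreasing(rho))
}

#' One-row fit summary
#'
#' @param x a `cka_fit`.
#' @param ... unused.
#' @return tibble with alignment, objective, dimensions, iteration count and
#'   convergence flag.
#' @export
glance.cka_fit <- function(x, ...) {
  tibble::tibble(
    cka = x$cka, objective = x$objective, sigma = x$sigma,
    n_features = nrow(x$A), n_dim = x$n_dim, n_samples = x$n_samples,
    n_iterations = x$n_iterations, converged = x$converged)
}

#' Objective trace plot
#'
#' @param object a `cka_fit`.
#' @param ... unused.
#' @return a ggplot of the accepted log-alignment objective per iteration.
#' @export
autoplot.cka_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "log alignment",
                  title = "CKA ascent trace")
}
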