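#' Pairwise squared Mahalanobis distances under a linear projection
#'
#' Computes the matrix of squared distances
#' \eqn{d^2(x_n, x_{n'}) = (x_n - x_{n'}) A A^\top (x_n - x_{n'})^\top},
#' i.e. squared Euclidean distances between the rows of \eqn{X A}. The
#' projection view and the metric view are the same quantity; the projected
#' form is used because it is cheaper and numerically symmetric.
#'
#' @param X numeric matrix, samples in rows (N x P).
#' @param A numeric projection matrix (P x M), or `NULL` for the identity
#'   metric (plain squared Euclidean distances).
#' @return symmetric N x N matrix with zero diagonal and nonnegative entries.
#' @examples
#' X <- matrix(c(0, 1, 3), ncol = 1)
#' pairwise_sqdist(X, matrix(2))
#' @export
pairwise_sqdist <- function(X, A = NULL) {
  check_matrix(X)
  Y <- if (is.null(A)) X else {
    check_matrix(A)
    if (ncol(X) != nrow(A)) {
      abort(sprintf("Non-conformable: X has %d columns, A has %d rows.",
                    ncol(X), nrow(A)), class = "ckalign_shape_error")
    }
    X %*% A
  }
  sq <- rowSums(Y * Y)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
  D2[D2 < 0] <- 0            # clamp tiny negative round-off
  D2 <- (D2 + t(D2)) / 2
  diag(D2) <- 0
  D2
}

#' Gaussian kernel from squared distances
#'
#' \eqn{K_{nn'} = \exp(-d^2_{nn'} / 2\sigma^2)}. Entries lie in (0, 1] with a
#' unit diagonal; the bandwidth \eqn{\sigma} sets the observation window of
#' the similarity.
#'
#' @param D2 symmetric nonnegative matrix of squared distances (zero diagonal).
#' @param sigma positive bandwidth, in the units of the projected-feature
#'   distance.
#' @return N x N kernel matrix with attribute `centered = FALSE`.
#' @export
gaussian_kernel <- function(D2, sigma) {
  check_square(D2)
  check_scalar_positive(sigma, "sigma")
  K <- exp(-D2 / (2 * sigma^2))
  attr(K, "centered") <- FALSE
  K
}

#' Label (target) kernel
#'
#' Delta-function similarity between class labels:
#' \eqn{K_{nn'} = 1} if \eqn{l_n = l_{n'}}, else 0. Under a label-sorted
#' permutation the matrix is block diagonal.
#'
#' @param labels vector of class labels (integer, character or factor).
#' @return N x N 0/1 kernel matrix with attribute `centered = FALSE`.
#' @export
label_kernel <- function(labels) {
  if (length(labels) < 1L || anyNA(labels)) {
    abort("`labels` must be non-empty and free of NA.",
          class = "ckalign_validation_error")
  }
  l <- as.character(labels)
  K <- outer(l, l, "==") * 1
  attr(K, "centered") <- FALSE
  K
}

#' Center a kernel matrix
#'
#' Double centering \eqn{\bar K = \tilde I K \tilde I} with
#' \eqn{\tilde I = I - 11^\top / N}, equivalent to mean-centering the implicit
#' feature map. Row and column sums of the result are zero; the operation is
#' idempotent.
#'
#' @param K square symmetric numeric matrix.
#' @return centered matrix with attribute `centered = TRUE`.
#' @export
center_kernel <- function(K) {
  check_square(K)
  rm_ <- rowMeans(K)
  cm_ <- colMeans(K)
  Kc <- K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm_) + mean(K)
  attr(Kc, "centered") <- TRUE
  Kc
}

is_centered <- function(K) isTRUE(attr(K, "centered"))

#' Empirical centered kernel alignment
#'
#' The normalized Frobenius inner product between two centered kernel
#' matrices,
#' \deqn{\hat\rho = \frac{\langle \bar K_X, \bar K_l \rangle_F}
#'   {\sqrt{\langle \bar K_X, \bar K_X\rangle_F
#'          \langle \bar K_l, \bar K_l\rangle_F}},}
#' a dependence measure in \[0, 1\] for positive semidefinite inputs. Inputs
#' are centered internally unless already flagged centered (see
#' [center_kernel()]). A kernel whose centered part vanishes (single-class
#' labels, constant features) has no defined alignment and raises an error
#' rather than returning a silent 0/0.
#'
#' @param Kx,Kl square kernel matrices of matching size.
#' @return alignment value in \[0, 1\] (up to rounding).
#' @export
cka <- function(Kx, Kl) {
  check_square(Kx)
  check_square(Kl)
  if (nrow(Kx) != nrow(Kl)) {
    abort("Kernel matrices must have matching dimensions.",
          class = "ckalign_shape_error")
  }
  Kxc <- if (is_centered(Kx)) Kx else center_kernel(Kx)
  Klc <- if (is_centered(Kl)) Kl else center_kernel(Kl)
  den_x <- sum(Kxc * Kxc)
  den_l <- sum(Klc * Klc)
  if (den_x < 1e-300 || den_l < 1e-300) {
    abort(paste("Degenerate alignment: a centered kernel is identically zero",
                "(single-class labels or constant features?)."),
          class = "ckalign_degenerate_error")
  }
  sum(Kxc * Klc) / sqrt(den_x * den_l)
}
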