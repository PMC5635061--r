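# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: double loops over sample pairs,
# naive convolution for wavelet pyramids, central finite differences for
# gradients.

# elementwise four-term centering estimator, double loop
center_kernel_loop <- function(K) {
  n <- nrow(K)
  out <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    out[a, b] <- K[a, b] - mean(K[a, ]) - mean(K[, b]) + mean(K)
  }
  out
}

# pairwise CKA estimator built entirely from scalar loops
cka_loop <- function(X, l, A, sigma) {
  n <- nrow(X)
  Y <- X %*% A
  K <- matrix(0, n, n)
  Kl <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    K[a, b] <- exp(-sum((Y[a, ] - Y[b, ])^2) / (2 * sigma^2))
    Kl[a, b] <- as.numeric(l[a] == l[b])
  }
  Kc <- center_kernel_loop(K)
  Klc <- center_kernel_loop(Kl)
  num <- 0; dx <- 0; dl <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    num <- num + Kc[a, b] * Klc[a, b]
    dx <- dx + Kc[a, b]^2
    dl <- dl + Klc[a, b]^2
  }
  num / sqrt(dx * dl)
}

# central finite differences of the log-alignment objective
fd_gradient <- function(X, l, A, sigma, h = 1e-6) {
  gA <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    Ap <- A; Ap[i, j] <- Ap[i, j] + h
    Am <- A; Am[i, j] <- Am[i, j] - h
    gA[i, j] <- (cka_objective(X, l, Ap, sigma) -
                 cka_objective(X, l, Am, sigma)) / (2 * h)
  }
  gls <- (cka_objective(X, l, A, sigma * exp(h)) -
          cka_objective(X, l, A, sigma * exp(-h))) / (2 * h)
  list(A = gA, log_sigma = gls)
}

# one-level wavelet analysis step by naive periodized convolution (scalar
# accumulation, no vector indexing tricks)
dwt_step_naive <- function(x, filt) {
  n <- length(x)
  out <- numeric(n / 2)
  for (i in seq_len(n / 2)) {
    acc <- 0
    for (t in seq_along(filt)) {
      idx <- (2 * i - t) %% n
      acc <- acc + filt[t] * x[idx + 1]
    }
    out[i] <- acc
  }
  out
}

# full pyramid energies via the naive step (independent oracle for
# dwt_relative_energy); filters are re-stated here rather than taken from
# the package internals
oracle_sym7_lo <- c(
   0.002681814568257878, -0.0010473848886829163, -0.01263630340325193,
   0.03051551316596357,   0.0678926935013727,    -0.049552834937127255,
   0.017441255086855827,  0.5361019170917628,     0.767764317003164,
   0.2886296317515146,   -0.14004724044296152,   -0.10780823770381774,
   0.004010244871533663,  0.010268176708511255)
oracle_sym7_hi <- c(
  -0.010268176708511255,  0.004010244871533663,   0.10780823770381774,
  -0.14004724044296152,  -0.2886296317515146,     0.767764317003164,
  -0.5361019170917628,    0.017441255086855827,   0.049552834937127255,
   0.0678926935013727,   -0.03051551316596357,   -0.01263630340325193,
   0.0010473848886829163, 0.002681814568257878)

dwt_energies_naive <- function(x, depth = 3) {
  n <- (length(x) %/% 2^depth) * 2^depth
  a <- x[seq_len(n)]
  energies <- numeric(depth)
  for (lev in seq_len(depth)) {
    d <- dwt_step_naive(a, oracle_sym7_hi)
    energies[lev] <- sum(d^2)
    a <- dwt_step_naive(a, oracle_sym7_lo)
  }
  list(detail = energies, approx = sum(a^2))
}

# decreasing-order ranks with first-index tie-break, written independently
rank_decreasing_oracle <- function(rho) {
  ord <- order(-rho, seq_along(rho))
  rk <- integer(length(rho))
  for (i in seq_along(ord)) rk[ord[i]] <- i
  rk
}

# small random symmetric PSD-ish kernel for property tests
random_gaussian_kernel <- function(n, p = 3) {
  X <- matrix(rnorm(n * p), n, p)
  gaussian_kernel(pairwise_sqdist(X), sigma = median(dist(X)))
}
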