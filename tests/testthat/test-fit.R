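test_that("PCA initialization is deterministic, orthonormal, and finds the dominant axis", {
  set.seed(10)
  # two strongly correlated unit-variance features: dominant axis ~ (1,1)/sqrt(2)
  z <- rnorm(100)
  X <- cbind(z + 0.1 * rnorm(100), z + 0.1 * rnorm(100))
  A <- init_projection(X, 1)
  cosine <- abs(sum(A * c(1, 1) / sqrt(2))) / sqrt(sum(A^2))
  expect_gt(cosine, 0.99)

  X <- matrix(rnorm(40 * 6), 40, 6)
  A <- init_projection(X, 6)
  expect_lt(max(abs(crossprod(A) - diag(6))), 1e-10)
  expect_identical(A, init_projection(X, 6))
  expect_error(init_projection(X, 0), class = "ckalign_parameter_error")
  expect_error(init_projection(X, 7), class = "ckalign_parameter_error")
})

test_that("bandwidth initialization is the median pairwise projected distance", {
  # single pair at distance 3
  X <- matrix(c(0, 3), ncol = 1)
  expect_equal(init_sigma(X, matrix(1)), 3)
  # three points with mutual distances 1, 2, 3 -> median 2
  X <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(init_sigma(X, matrix(1)), 2)
  # brute-force pair enumeration on a random set
  set.seed(11)
  X <- matrix(rnorm(20 * 4), 20, 4)
  A <- matrix(rnorm(8), 4, 2)
  Y <- X %*% A
  d <- c()
  for (a in 1:19) for (b in (a + 1):20) {
    d <- c(d, sqrt(sum((Y[a, ] - Y[b, ])^2)))
  }
  expect_equal(init_sigma(X, A), median(d))
  expect_error(init_sigma(matrix(c(1, 1), ncol = 1), matrix(1)),
               class = "ckalign_degenerate_error")
})

test_that("objective is log of the alignment and bounded above by zero", {
  set.seed(12)
  X <- matrix(rnorm(15 * 4), 15, 4)
  l <- rep(1:3, 5)
  A <- matrix(rnorm(8), 4, 2)
  obj <- cka_objective(X, l, A, 1.1)
  K <- gaussian_kernel(pairwise_sqdist(X, A), 1.1)
  expect_lt(abs(obj - log(cka(K, label_kernel(l)))), 1e-14)
  expect_lte(obj, 0)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    p <- sample(2:5, 1)
    m <- sample(1:min(4, p), 1)
    X <- matrix(rnorm(n * p), n, p)
    l <- sample(1:2, n, replace = TRUE)
    if (length(unique(l)) < 2) l[1] <- 3 - l[1]
    A <- matrix(rnorm(p * m, sd = 0.7), p, m)
    sig <- runif(1, 0.7, 2)
    g <- cka_gradient(X, l, A, sig)
    fd <- fd_gradient(X, l, A, sig)
    denom <- pmax(abs(fd$A), 1e-4)
    expect_lt(max(abs(g$A - fd$A) / denom), 1e-5)
    expect_lt(abs(g$log_sigma - fd$log_sigma) /
                max(abs(fd$log_sigma), 1e-4), 1e-5)
  }
})

test_that("duplicated coordinates receive identical gradient rows", {
  set.seed(14)
  X <- matrix(rnorm(12 * 3), 12, 3)
  X <- cbind(X, X[, 3])                    # duplicate feature 3 as feature 4
  l <- rep(1:2, 6)
  A <- matrix(rnorm(8), 4, 2)
  A[4, ] <- A[3, ]                         # symmetric rows for the pair
  A[3, ] <- A[3, ] / 1                     # keep identical
  g <- cka_gradient(X, l, A, 1.2)
  expect_equal(g$A[3, ], g$A[4, ], tolerance = 1e-12)
})

test_that("gradient ascent is monotone with backtracking and improves on the start", {
  set.seed(15)
  for (rep in 1:4) {
    sim <- simulate_tabular(n_samples = 40, n_features = 8, n_informative = 2,
                            seed = rep)
    fit <- cka_fit(sim$data, control = cka_control(max_iterations = 40))
    expect_true(all(diff(fit$objective_trace) >= -1e-12))
    expect_gte(fit$objective, fit$objective_trace[1])
    expect_true(is.finite(fit$objective))
  }
})

test_that("degenerate labels abort before the first iteration", {
  sim <- simulate_tabular(n_samples = 20, n_features = 5, n_informative = 2,
                          seed = 1)
  d <- sim$data
  d$class <- 1L
  expect_error(cka_fit(d), class = "ckalign_degenerate_error")
})

test_that("iteration bookkeeping follows the control settings", {
  expect_error(cka_control(max_iterations = 0), class = "ckalign_parameter_error")
  expect_error(cka_control(tolerance = -1), class = "ckalign_parameter_error")
  sim <- simulate_tabular(n_samples = 30, n_features = 6, n_informative = 2,
                          seed = 2)
  fit1 <- cka_fit(sim$data, control = cka_control(max_iterations = 1))
  expect_equal(fit1$n_iterations, 1L)
  expect_length(fit1$objective_trace, 2L)
})

test_that("objective is invariant to joint rescaling of data and bandwidth", {
  set.seed(16)
  X <- matrix(rnorm(20 * 4), 20, 4)
  l <- rep(1:2, 10)
  A <- matrix(rnorm(8), 4, 2)
  f1 <- cka_objective(X, l, A, 1.3)
  for (c_ in c(0.1, 7)) {
    f2 <- cka_objective(c_ * X, l, A, c_ * 1.3)
    expect_lt(abs(f1 - f2), 1e-10)
  }
})

test_that("informative features dominate the learned projection rows", {
  # two well-separated classes carried by 2 of 10 features
  sim <- simulate_tabular(n_samples = 60, n_features = 10, n_informative = 2,
                          seed = 3)
  fit <- cka_fit(sim$data)
  rn <- sqrt(rowSums(fit$A^2))
  expect_gt(mean(rn[sim$support]) / mean(rn[-sim$support]), 3)
})

test_that("fixed bandwidth mode keeps sigma at its initialization", {
  sim <- simulate_tabular(n_samples = 30, n_features = 6, n_informative = 2,
                          seed = 4)
  fit <- cka_fit(sim$data, control = cka_control(learn_sigma = FALSE,
                                                 max_iterations = 15))
  X <- as.matrix(sim$data[, 1:6])
  A0 <- init_projection(X, fit$n_dim)
  Xs <- scale(X)
  expect_equal(fit$sigma, init_sigma(matrix(as.numeric(Xs), nrow(X)), A0))
})

test_that("tidy and glance summarise the fit consistently", {
  sim <- simulate_tabular(n_samples = 40, n_features = 6, n_informative = 2,
                          seed = 5)
  fit <- cka_fit(sim$data, control = cka_control(max_iterations = 20))
  td <- tidy(fit)
  expect_named(td, c("feature", "rho", "rank"))
  expect_equal(nrow(td), 6)
  expect_equal(sort(td$rank), 1:6)
  expect_equal(td$rho, relevance_vector(fit$A), ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$cka, exp(gl$objective))
  expect_equal(gl$n_dim, ncol(fit$A))
  # projection of the training data reproduces standardized coordinates
  Y <- predict(fit, sim$data)
  expect_equal(ncol(Y), fit$n_dim + 1L)   # + label column
})
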