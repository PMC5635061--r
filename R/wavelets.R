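# Small spectral/wavelet primitives used by the EEG feature bank.
# Kept minimal and directly testable against brute-force oracles.

# Symlet-7 decomposition filters (standard published coefficients,
# low-pass h and high-pass g, length 14).
sym7_dec_lo <- c(
   0.002681814568257878, -0.0010473848886829163, -0.01263630340325193,
   0.03051551316596357,   0.0678926935013727,    -0.049552834937127255,
   0.017441255086855827,  0.5361019170917628,     0.767764317003164,
   0.2886296317515146,   -0.14004724044296152,   -0.10780823770381774,
   0.004010244871533663,  0.010268176708511255)
sym7_dec_hi <- c(
  -0.010268176708511255,  0.004010244871533663,   0.10780823770381774,
  -0.14004724044296152,  -0.2886296317515146,     0.767764317003164,
  -0.5361019170917628,    0.017441255086855827,   0.049552834937127255,
   0.0678926935013727,   -0.03051551316596357,   -0.01263630340325193,
   0.0010473848886829163, 0.002681814568257878)

# one analysis step with periodic (circular) extension: filter then
# downsample by 2; x must have even length
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  out <- numeric(n / 2)
  for (i in seq_len(n / 2)) {
    # coefficient i uses samples ending at 2i (periodized)
    idx <- ((2 * i - seq_len(L)) %% n) + 1L
    out[i] <- sum(filt * x[idx])
  }
  out
}

#' Discrete wavelet decomposition (Symlet-7, periodized)
#'
#' Mallat pyramid with the Symlet-7 filter pair and circular boundary
#' handling. The signal is truncated to the largest multiple of
#' \eqn{2^{levels}} if needed.
#'
#' @param x numeric signal.
#' @param levels decomposition depth (default 3).
#' @return list with `details` (list of detail-coefficient vectors, level 1
#'   first) and `approx` (final approximation coefficients).
#' @export
dwt_sym7 <- function(x, levels = 3) {
  if (length(x) < 2^levels * 2) {
    abort(sprintf("Signal too short for a %d-level decomposition.", levels),
          class = "ckalign_parameter_error")
  }
  n <- (length(x) %/% (2^levels)) * (2^levels)
  a <- x[seq_len(n)]
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    details[[lev]] <- dwt_step(a, sym7_dec_hi)
    a <- dwt_step(a, sym7_dec_lo)
  }
  list(details = details, approx = a)
}

# relative energies of detail levels: E(d_lev) / total coefficient energy
dwt_relative_energy <- function(x, levels_wanted = c(2, 3), depth = 3) {
  dec <- dwt_sym7(x, levels = depth)
  energies <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  total <- sum(energies) + sum(dec$approx^2)
  if (total <= 0) return(rep(0, length(levels_wanted)))
  energies[levels_wanted] / total
}

#' Morlet scalogram power
#'
#' Continuous wavelet transform with a complex Morlet mother wavelet
#' (center frequency parameter \eqn{\omega_0 = 6}), evaluated by FFT
#' convolution at the requested analysis frequencies. Returns power
#' \eqn{|W(f, t)|^2}.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies in Hz.
#' @return matrix `length(freqs)` x `length(x)` of scalogram power.
#' @export
morlet_power <- function(x, fs, freqs) {
  check_scalar_positive(fs, "fs")
  n <- length(x)
  xf <- fft(x)
  # angular frequencies of the DFT bins
  w <- 2 * pi * fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  w0 <- 6
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- w0 / (2 * pi * freqs[i])              # scale in seconds
    # analytic Morlet in the frequency domain (positive frequencies only)
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * s * fs) * exp(-(s * w - w0)^2 / 2)
    psi_hat[w < 0] <- 0
    W <- fft(xf * psi_hat, inverse = TRUE) / n
    out[i, ] <- Mod(W)^2
  }
  out
}

# orthonormal DCT-II of a vector (direct evaluation; only a handful of
# coefficients are ever requested)
dct2 <- function(x, n_coef = length(x)) {
  N <- length(x)
  k <- seq_len(n_coef) - 1L
  n <- seq_len(N) - 1L
  M <- cos(pi * outer(k, n + 0.5) / N)
  coef <- as.numeric(M %*% x)
  coef * sqrt(2 / N)
}

# one-sided Hamming-tapered periodogram; returns power per frequency bin
periodogram_power <- function(x, fs) {
  n <- length(x)
  w <- signal::hamming(n)
  xw <- (x - mean(x)) * w
  sp <- Mod(fft(xw))^2 / sum(w^2)
  nbin <- floor(n / 2) + 1L
  freq <- (seq_len(nbin) - 1L) * fs / n
  list(freq = freq, power = sp[seq_len(nbin)])
}
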