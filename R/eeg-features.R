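#' Feature-bank configuration
#'
#' Settings for the per-channel EEG feature extractors. Defaults follow
#' standard piecewise-stationary EEG practice: 1 s Hamming-tapered segments
#' with 50% overlap, an analysis band of 4–30 Hz, \eqn{\alpha} = 8–13 Hz and
#' \eqn{\beta} = 14–30 Hz sub-bands, Morlet scalograms, Symlet-7 wavelet
#' levels 2 and 3, the canonical rhythm bands
#' (\eqn{\delta}<4, \eqn{\theta} 4–8, \eqn{\alpha} 8–13, \eqn{\beta} 14–30 Hz)
#' and 5 cepstral coefficients per rhythm. Each short-time quantity is
#' aggregated across segments by its mean, variance and maximum.
#'
#' @param segment_length segment length in seconds (default 1).
#' @param segment_overlap overlap fraction in \[0, 1) (default 0.5).
#' @param stats aggregation statistics applied across segments.
#' @param bands named list of spectral sub-bands (Hz) for PSD/CWT features.
#' @param rhythm_bands named list of rhythm bands (Hz) for cepstral features.
#' @param dwt_levels detail levels whose relative energy is extracted.
#' @param dwt_depth decomposition depth.
#' @param n_cepstral cepstral coefficients kept per rhythm (default 5).
#' @return list of class `feature_bank_config`.
#' @export
feature_bank_config <- function(segment_length = 1, segment_overlap = 0.5,
                                stats = c("mean", "var", "max"),
                                bands = list(alpha = c(8, 13),
                                             beta = c(14, 30)),
                                rhythm_bands = list(delta = c(0.5, 4),
                                                    theta = c(4, 8),
                                                    alpha = c(8, 13),
                                                    beta = c(14, 30)),
                                dwt_levels = c(2, 3), dwt_depth = 3,
                                n_cepstral = 5) {
  check_scalar_positive(segment_length, "segment_length")
  if (segment_overlap < 0 || segment_overlap >= 1) {
    abort("`segment_overlap` must be in [0, 1).",
          class = "ckalign_parameter_error")
  }
  if (!length(stats)) {
    abort("`stats` must be non-empty.", class = "ckalign_parameter_error")
  }
  structure(
    list(segment_length = segment_length, segment_overlap = segment_overlap,
         stats = stats, bands = bands, rhythm_bands = rhythm_bands,
         dwt_levels = dwt_levels, dwt_depth = dwt_depth,
         n_cepstral = n_cepstral),
    class = "feature_bank_config")
}

#' Split a signal into overlapping segments
#'
#' Segments of `segment_length` seconds with hop
#' `segment_length * (1 - segment_overlap)`; count
#' `floor((T - L)/hop) + 1`. An optional Hamming taper is applied (the
#' spectral extractors use it; the Hjorth extractor does not, so its
#' closed-form sinusoid values hold).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param cfg a [feature_bank_config()].
#' @param taper apply a Hamming window to each segment?
#' @return matrix with one segment per column.
#' @export
segment_signal <- function(x, fs, cfg = feature_bank_config(), taper = TRUE) {
  L <- round(cfg$segment_length * fs)
  if (L > length(x)) {
    abort("Segment longer than the signal.", class = "ckalign_parameter_error")
  }
  hop <- max(1L, round(L * (1 - cfg$segment_overlap)))
  n_seg <- floor((length(x) - L) / hop) + 1L
  starts <- (seq_len(n_seg) - 1L) * hop
  segs <- vapply(starts, function(s) x[(s + 1):(s + L)], numeric(L))
  segs <- matrix(segs, nrow = L)
  if (taper) segs <- segs * signal::hamming(L)
  segs
}

stat_aggregate <- function(values, stats) {
  vapply(stats, function(s) {
    switch(s,
           mean = mean(values),
           var = stats::var(values),
           max = max(values),
           abort(sprintf("Unknown statistic '%s'.", s),
                 class = "ckalign_parameter_error"))
  }, numeric(1))
}

band_power_from_spectrum <- function(pg, band) {
  sum(pg$power[pg$freq >= band[1] & pg$freq <= band[2]])
}

#' Welch-style band-power features
#'
#' Per Hamming-tapered segment, the periodogram power summed inside each
#' configured sub-band (\eqn{\alpha}, \eqn{\beta} by default); each band's
#' per-segment series is aggregated by the configured statistics. Defaults
#' give 2 bands x 3 statistics = 6 values.
#'
#' @inheritParams segment_signal
#' @return named numeric vector (band x statistic).
#' @export
psd_features <- function(x, fs, cfg = feature_bank_config()) {
  for (b in cfg$bands) {
    if (b[2] > fs / 2) {
      abort("Band edge beyond the Nyquist frequency.",
            class = "ckalign_parameter_error")
    }
  }
  segs <- segment_signal(x, fs, cfg, taper = TRUE)
  out <- c()
  for (bn in names(cfg$bands)) {
    pw <- apply(segs, 2L, function(s) {
      band_power_from_spectrum(periodogram_power_raw(s, fs), cfg$bands[[bn]])
    })
    agg <- stat_aggregate(pw, cfg$stats)
    names(agg) <- paste("psd", bn, cfg$stats, sep = ".")
    out <- c(out, agg)
  }
  out
}

# periodogram without demeaning (segments are already tapered); zero input
# stays exactly zero
periodogram_power_raw <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n
  nbin <- floor(n / 2) + 1L
  list(freq = (seq_len(nbin) - 1L) * fs / n, power = sp[seq_len(nbin)])
}

hjorth_one <- function(x) {
  a <- stats::var(x)
  if (a < .Machine$double.eps) {
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  m <- sqrt(stats::var(d1) / a)
  md <- sqrt(stats::var(d2) / stats::var(d1))
  c(activity = a, mobility = m, complexity = md / m)
}

#' Hjorth parameters
#'
#' Per (untapered) segment: Activity (signal variance), Mobility (RMS
#' frequency proxy, \eqn{\sqrt{var(\Delta x)/var(x)}} with \eqn{\Delta} the
#' first difference) and Complexity (the mobility of the differenced signal
#' divided by the mobility of the signal; 1 for a pure sinusoid). Aggregated
#' by the configured statistics: 3 parameters x 3 statistics = 9 values.
#'
#' @inheritParams segment_signal
#' @return named numeric vector.
#' @export
hjorth_features <- function(x, fs, cfg = feature_bank_config()) {
  segs <- segment_signal(x, fs, cfg, taper = FALSE)
  if (nrow(segs) < 3L) {
    abort("Segments too short for Hjorth parameters (need >= 3 samples).",
          class = "ckalign_parameter_error")
  }
  if (any(apply(segs, 2L, stats::var) < .Machine$double.eps)) {
    warn("Zero-variance segment(s): mobility/complexity reported as 0 there.")
  }
  H <- apply(segs, 2L, hjorth_one)
  out <- c()
  for (pn in rownames(H)) {
    agg <- stat_aggregate(H[pn, ], cfg$stats)
    names(agg) <- paste("hjorth", pn, cfg$stats, sep = ".")
    out <- c(out, agg)
  }
  out
}

#' Morlet scalogram band-energy features
#'
#' Morlet scalogram of the full signal on a 1 Hz frequency grid; per
#' segment time-span, the mean scalogram power inside each configured band;
#' aggregated by the configured statistics (2 bands x 3 statistics = 6
#' values by default).
#'
#' @inheritParams segment_signal
#' @return named numeric vector.
#' @export
cwt_features <- function(x, fs, cfg = feature_bank_config()) {
  for (b in cfg$bands) {
    if (b[2] > fs / 2) {
      abort("Band edge beyond the Nyquist frequency.",
            class = "ckalign_parameter_error")
    }
  }
  L <- round(cfg$segment_length * fs)
  hop <- max(1L, round(L * (1 - cfg$segment_overlap)))
  n_seg <- floor((length(x) - L) / hop) + 1L
  out <- c()
  for (bn in names(cfg$bands)) {
    band <- cfg$bands[[bn]]
    freqs <- seq(band[1], band[2], by = 1)
    P <- morlet_power(x, fs, freqs)
    pw <- vapply(seq_len(n_seg), function(i) {
      idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + L)
      mean(P[, idx])
    }, numeric(1))
    agg <- stat_aggregate(pw, cfg$stats)
    names(agg) <- paste("cwt", bn, cfg$stats, sep = ".")
    out <- c(out, agg)
  }
  out
}

#' Symlet-7 wavelet energy features
#'
#' Per (untapered) segment, the relative energy of the detail coefficients
#' at the configured levels (2 and 3 by default, covering the mid-frequency
#' EEG content at typical sampling rates), aggregated by the configured
#' statistics: 2 levels x 3 statistics = 6 values.
#'
#' @inheritParams segment_signal
#' @return named numeric vector.
#' @export
dwt_features <- function(x, fs, cfg = feature_bank_config()) {
  segs <- segment_signal(x, fs, cfg, taper = FALSE)
  E <- apply(segs, 2L, dwt_relative_energy,
             levels_wanted = cfg$dwt_levels, depth = cfg$dwt_depth)
  E <- matrix(E, nrow = length(cfg$dwt_levels))
  out <- c()
  for (i in seq_along(cfg$dwt_levels)) {
    agg <- stat_aggregate(E[i, ], cfg$stats)
    names(agg) <- paste("dwt", paste0("d", cfg$dwt_levels[i]), cfg$stats,
                        sep = ".")
    out <- c(out, agg)
  }
  out
}

# zero-phase Butterworth band filter; delta-like bands with a near-zero
# lower edge become low-pass
rhythm_filter <- function(x, fs, band, order = 4) {
  nyq <- fs / 2
  if (band[1] <= 0.5) {
    flt <- signal::butter(order, band[2] / nyq, type = "low")
  } else {
    flt <- signal::butter(order / 2, band / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' Per-rhythm cepstral features
#'
#' For each segment and each rhythm band (\eqn{\delta, \theta, \alpha,
#' \beta}): zero-phase Butterworth band filtering, a Hamming-tapered log
#' power spectrum (floored at 1e-12 of the spectrum's full scale so silent
#' frames stay finite), DCT-II, and the first `n_cepstral` coefficients.
#' Aggregated across segments by the configured statistics:
#' 4 bands x 5 coefficients x 3 statistics = 60 values by default. Amplitude
#' scaling of the input shifts only the 0th coefficient (log-homogeneity).
#'
#' @inheritParams segment_signal
#' @return named numeric vector.
#' @export
rhythm_cepstral_features <- function(x, fs, cfg = feature_bank_config()) {
  for (b in cfg$rhythm_bands) {
    if (b[2] > fs / 2) {
      abort("Rhythm band beyond the Nyquist frequency.",
            class = "ckalign_parameter_error")
    }
  }
  segs <- segment_signal(x, fs, cfg, taper = FALSE)
  n_seg <- ncol(segs)
  out <- c()
  for (bn in names(cfg$rhythm_bands)) {
    band <- cfg$rhythm_bands[[bn]]
    xf <- rhythm_filter(x, fs, band)
    segs_f <- segment_signal(xf, fs, cfg, taper = TRUE)
    C <- vapply(seq_len(n_seg), function(i) {
      p <- periodogram_power_raw(segs_f[, i], fs)$power
      floor_ <- 1e-12 * max(p, 1e-300)
      dct2(log(pmax(p, floor_)), n_coef = cfg$n_cepstral)
    }, numeric(cfg$n_cepstral))
    C <- matrix(C, nrow = cfg$n_cepstral)
    for (k in seq_len(cfg$n_cepstral)) {
      agg <- stat_aggregate(C[k, ], cfg$stats)
      names(agg) <- paste("cep", paste0(bn, k - 1L), cfg$stats, sep = ".")
      out <- c(out, agg)
    }
  }
  out
}

#' Build the trial feature table
#'
#' Applies the per-channel extractors to every trial and channel and
#' concatenates the results into one row per trial. In `"mi"` mode the bank
#' is band power + Hjorth + scalogram + wavelet energies (27 features per
#' channel); in `"rhythm"` mode it is the per-rhythm cepstral set (60 per
#' channel with the defaults). Column names follow
#' `channel.principle.quantity.statistic`.
#'
#' @param trials an `eeg_trials` object (see [simulate_eeg()]).
#' @param mode feature bank: `"mi"` or `"rhythm"`.
#' @param cfg a [feature_bank_config()].
#' @return tibble with one row per trial, feature columns plus `class`;
#'   attribute `"feature_info"` holds a tibble mapping each feature to its
#'   channel, principle, quantity and statistic.
#' @export
eeg_feature_bank <- function(trials, mode = c("mi", "rhythm"),
                             cfg = feature_bank_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(trials, "eeg_trials"))
  d <- dim(trials$data)
  extract_one <- function(x) {
    if (mode == "mi") {
      c(psd_features(x, trials$fs, cfg), hjorth_features(x, trials$fs, cfg),
        cwt_features(x, trials$fs, cfg), dwt_features(x, trials$fs, cfg))
    } else {
      rhythm_cepstral_features(x, trials$fs, cfg)
    }
  }
  rows <- lapply(seq_len(d[1]), function(n) {
    per_ch <- lapply(seq_len(d[2]), function(ch) {
      v <- tryCatch(extract_one(trials$data[n, ch, ]),
        error = function(e) {
          abort(sprintf("Feature extraction failed at trial %d, channel %s: %s",
                        n, trials$channel_names[ch], conditionMessage(e)),
                class = "ckalign_extraction_error")
        })
      names(v) <- paste(trials$channel_names[ch], names(v), sep = ".")
      v
    })
    unlist(per_ch)
  })
  M <- do.call(rbind, rows)
  info <- do.call(rbind, strsplit(colnames(M), ".", fixed = TRUE))
  feature_info <- tibble::tibble(
    feature = colnames(M), channel = info[, 1], principle = info[, 2],
    quantity = info[, 3], statistic = info[, 4])
  out <- tibble::as_tibble(as.data.frame(M))
  out$class <- trials$labels
  attr(out, "feature_info") <- feature_info
  out
}
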