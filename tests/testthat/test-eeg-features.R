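fs <- 160
cfg <- feature_bank_config()

test_that("segmentation yields the contracted count and shape", {
  x <- seq_len(400)
  cfg100 <- feature_bank_config(segment_length = 1, segment_overlap = 0.5)
  segs <- segment_signal(x, fs = 100, cfg100, taper = FALSE)
  expect_equal(dim(segs), c(100, 7))        # hop 50: floor((400-100)/50)+1
  segs0 <- segment_signal(x, fs = 100,
                          feature_bank_config(segment_overlap = 0),
                          taper = FALSE)
  expect_equal(ncol(segs0), 4)              # disjoint tiling floor(400/100)
  expect_equal(as.numeric(segs0), x[1:400]) # exact partition
  # constant signal -> identical segments
  segc <- segment_signal(rep(2, 300), fs = 100, cfg100, taper = FALSE)
  expect_true(all(segc == 2))
  expect_error(segment_signal(seq_len(50), fs = 100, cfg100),
               class = "ckalign_parameter_error")
})

test_that("band power concentrates at the tone frequency", {
  tt <- seq_len(640) / fs
  x <- sin(2 * pi * 10 * tt)
  p <- psd_features(x, fs, cfg)
  expect_gt(p[["psd.alpha.mean"]] / (p[["psd.beta.mean"]] + 1e-300), 100)
  expect_equal(unname(psd_features(rep(0, 640), fs, cfg)), rep(0, 6))
  # quadratic amplitude homogeneity
  p3 <- psd_features(3 * x, fs, cfg)
  expect_equal(unname(p3[c(1, 3)]), unname(9 * p[c(1, 3)]), tolerance = 1e-10)
  expect_error(psd_features(x, fs,
                            feature_bank_config(bands = list(hi = c(70, 100)))),
               class = "ckalign_parameter_error")
})

test_that("Hjorth parameters match sinusoid closed forms", {
  tt <- seq_len(640) / fs
  for (f0 in c(5, 10)) {
    x <- sin(2 * pi * f0 * tt)
    h <- hjorth_features(x, fs, cfg)
    expect_equal(h[["hjorth.activity.mean"]], 0.5, tolerance = 0.02)
    expect_equal(h[["hjorth.complexity.mean"]], 1, tolerance = 0.02)
    expect_equal(h[["hjorth.mobility.mean"]], 2 * sin(pi * f0 / fs),
                 tolerance = 0.02)
  }
  expect_warning(h0 <- hjorth_features(rep(1, 640), fs, cfg), "Zero-variance")
  expect_equal(unname(h0[c("hjorth.activity.mean", "hjorth.mobility.mean",
                           "hjorth.complexity.mean")]), c(0, 0, 0))
})

test_that("scalogram energies localize the tone and scale quadratically", {
  tt <- seq_len(640) / fs
  x <- sin(2 * pi * 10 * tt)
  cw <- cwt_features(x, fs, cfg)
  expect_gt(cw[["cwt.alpha.mean"]] / cw[["cwt.beta.mean"]], 50)
  expect_equal(unname(cwt_features(rep(0, 640), fs, cfg)), rep(0, 6))
  cw2 <- cwt_features(2 * x, fs, cfg)
  expect_equal(unname(cw2[c(1, 3)]), unname(4 * cw[c(1, 3)]),
               tolerance = 1e-10)
})

test_that("wavelet level energies match the naive filter-bank oracle", {
  set.seed(30)
  x <- rnorm(160)
  dec <- dwt_sym7(x, levels = 3)
  oracle <- dwt_energies_naive(x, depth = 3)
  pkg_detail <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  expect_lt(max(abs(pkg_detail - oracle$detail)), 1e-8)
  expect_lt(abs(sum(dec$approx^2) - oracle$approx), 1e-8)
  expect_equal(unname(dwt_features(rep(0, 640), fs, cfg)), rep(0, 6))
  expect_error(dwt_sym7(rnorm(8), levels = 3),
               class = "ckalign_parameter_error")
})

test_that("a tone in the level-2 passband dominates level 3", {
  # at fs = 160 the level-2 detail band is ~20-40 Hz, level 3 ~10-20 Hz
  tt <- seq_len(640) / fs
  x <- sin(2 * pi * 30 * tt)
  d <- dwt_features(x, fs, cfg)
  expect_gt(d[["dwt.d2.mean"]], d[["dwt.d3.mean"]])
  x3 <- sin(2 * pi * 12 * tt)
  d3 <- dwt_features(x3, fs, cfg)
  expect_gt(d3[["dwt.d3.mean"]], d3[["dwt.d2.mean"]])
})

test_that("cepstral coefficients shift only their 0th term under scaling", {
  set.seed(31)
  x <- rnorm(640)
  c1 <- rhythm_cepstral_features(x, fs, cfg)
  c2 <- rhythm_cepstral_features(5 * x, fs, cfg)
  is_c0 <- grepl("cep[.](delta|theta|alpha|beta)0[.]", names(c1))
  expect_lt(max(abs((c1 - c2)[!is_c0])), 1e-6)
  expect_gt(min(abs((c1 - c2)[is_c0 & grepl("mean", names(c1))])), 1e-3)
  # silence stays finite at the log floor
  c0 <- rhythm_cepstral_features(rep(0, 640), fs, cfg)
  expect_true(all(is.finite(c0)))
  expect_equal(length(c1), 4 * 5 * 3)
})

test_that("rhythm-dominant signals separate in their band coefficients", {
  tt <- seq_len(2 * 640) / fs
  set.seed(32)
  alpha_sig <- sin(2 * pi * 10 * tt) + 0.1 * rnorm(length(tt))
  delta_sig <- sin(2 * pi * 2 * tt) + 0.1 * rnorm(length(tt))
  ca <- rhythm_cepstral_features(alpha_sig, fs, cfg)
  cd <- rhythm_cepstral_features(delta_sig, fs, cfg)
  expect_gt(ca[["cep.alpha0.mean"]], cd[["cep.alpha0.mean"]])
  expect_gt(cd[["cep.delta0.mean"]], ca[["cep.delta0.mean"]])
})

test_that("the trial feature bank has the contracted shape and names", {
  trials <- simulate_eeg(n_trials = 6, n_channels = 2, n_samples = 480,
                         seed = 33)
  fb <- eeg_feature_bank(trials, mode = "mi")
  expect_equal(ncol(fb) - 1L, 2 * 27)      # 27 per channel
  expect_false(anyDuplicated(names(fb)) > 0)
  info <- attr(fb, "feature_info")
  expect_equal(nrow(info), 54)
  expect_setequal(unique(info$principle), c("psd", "hjorth", "cwt", "dwt"))
  expect_equal(unname(table(info$channel)), c(27L, 27L), ignore_attr = TRUE)
  expect_equal(fb$class, trials$labels)
  # all power/energy features finite; power features nonnegative
  vals <- as.matrix(fb[setdiff(names(fb), "class")])
  expect_true(all(is.finite(vals)))
  pow <- vals[, info$principle %in% c("psd", "cwt", "dwt")]
  expect_true(all(pow >= 0))
})

test_that("channel permutation permutes feature blocks", {
  trials <- simulate_eeg(n_trials = 4, n_channels = 3, n_samples = 480,
                         seed = 34)
  fb <- eeg_feature_bank(trials)
  perm <- c(3, 1, 2)
  trials2 <- trials
  trials2$data <- trials$data[, perm, , drop = FALSE]
  trials2$channel_names <- trials$channel_names[perm]
  fb2 <- eeg_feature_bank(trials2)
  for (ch in trials$channel_names) {
    cols <- grep(paste0("^", ch, "\\."), names(fb), value = TRUE)
    expect_equal(fb2[cols], fb[cols], ignore_attr = TRUE)
  }
})

test_that("rhythm mode emits the cepstral bank", {
  trials <- simulate_eeg(n_trials = 4, n_channels = 2, n_samples = 480,
                         mode = "ictal_bursts", seed = 35)
  fb <- eeg_feature_bank(trials, mode = "rhythm")
  expect_equal(ncol(fb) - 1L, 2 * 60)
  expect_true(all(is.finite(as.matrix(fb[setdiff(names(fb), "class")]))))
})
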