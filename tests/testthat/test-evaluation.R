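test_that("nested CV is accurate on separated blobs and honest on noise", {
  sim <- simulate_tabular(n_samples = 200, n_features = 10, n_informative = 4,
                          seed = 40)
  cv <- knn_nested_cv(sim$data, seed = 1)
  expect_gte(cv$accuracy_mean, 99)
  expect_true(all(cv$chosen_k %in% c(1, 3, 5, 7, 9, 11)))
  expect_length(cv$chosen_k, 10)

  # label shuffles: mean accuracy at chance level within a binomial band
  # (averaged over shuffles; a single permutation draw can genuinely sit
  # outside the band when it happens to anticorrelate with the clusters)
  accs <- vapply(1:5, function(s) {
    d <- sim$data
    set.seed(s)
    d$class <- sample(d$class)
    knn_nested_cv(d, seed = s)$accuracy_mean
  }, numeric(1))
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("nested CV is deterministic given its seed", {
  sim <- simulate_tabular(n_samples = 60, n_features = 6, n_informative = 2,
                          seed = 42)
  cv1 <- knn_nested_cv(sim$data, seed = 7)
  cv2 <- knn_nested_cv(sim$data, seed = 7)
  expect_identical(cv1[c("accuracy_mean", "accuracy_sd", "chosen_k",
                         "fold_accuracy")],
                   cv2[c("accuracy_mean", "accuracy_sd", "chosen_k",
                         "fold_accuracy")])
})

test_that("stratification failures are reported with advice", {
  d <- tibble::tibble(f1 = rnorm(12), class = c(rep(1, 9), rep(2, 3)))
  expect_error(knn_nested_cv(d, outer_folds = 10, seed = 1),
               "fewer folds", class = "ckalign_parameter_error")
})

test_that("no information leaks from test folds", {
  # a feature equal to the label leaks perfect accuracy only when included;
  # a post-hoc shuffled copy of it does not
  set.seed(43)
  n <- 100
  base <- tibble::tibble(f1 = rnorm(n), f2 = rnorm(n),
                         class = rep(1:2, n / 2))
  leak <- base
  leak$oracle_feature <- as.numeric(leak$class)
  cv_leak <- knn_nested_cv(leak, seed = 3)
  expect_equal(cv_leak$accuracy_mean, 100)

  shuffled <- base
  shuffled$shuffled_copy <- sample(as.numeric(base$class))
  cv_shuf <- knn_nested_cv(shuffled, seed = 3)
  expect_lt(cv_shuf$accuracy_mean, 75)
})

test_that("the accuracy curve finds the informative prefix", {
  sim <- simulate_tabular(n_samples = 100, n_features = 12, n_informative = 3,
                          seed = 44)
  rel <- relevance(cka_fit(sim$data))
  ranking <- rel$feature[order(rel$rank)]
  curve <- accuracy_rank_curve(sim$data, ranking, outer_folds = 5,
                               inner_folds = 5, seed = 4)
  expect_lte(curve$n_selected, 3 + 3)
  expect_true(all(curve$curve$accuracy_mean >= 0 &
                  curve$curve$accuracy_mean <= 100))
  # reversed ranking reaches its maximum later
  curve_rev <- accuracy_rank_curve(sim$data, rev(ranking), outer_folds = 5,
                                   inner_folds = 5, seed = 4)
  expect_gt(curve_rev$n_selected, curve$n_selected)
})

test_that("a single-feature curve is a single point", {
  sim <- simulate_tabular(n_samples = 60, n_features = 1, n_informative = 1,
                          seed = 45)
  curve <- accuracy_rank_curve(sim$data, "f01", outer_folds = 5,
                               inner_folds = 5, seed = 1)
  expect_equal(nrow(curve$curve), 1)
  expect_equal(curve$n_selected, 1)
})

test_that("the stride schedule is dense then geometric and always ends at P", {
  s <- ckalign:::curve_schedule(200)
  expect_equal(s[1:50], 1:50)
  expect_equal(max(s), 200)
  expect_true(all(diff(s) > 0))
  expect_identical(ckalign:::curve_schedule(30), 1:30)
})

test_that("dimension reduction factor reproduces the printed arithmetic", {
  expect_equal(dimension_reduction_factor(1593, 275), 5.79, tolerance = 0.001)
  expect_equal(dimension_reduction_factor(1593, 1410), 1.13, tolerance = 0.001)
  expect_equal(dimension_reduction_factor(10, 10), 1)
  expect_error(dimension_reduction_factor(10, 0),
               class = "ckalign_parameter_error")
})

test_that("relevance marginals match a brute-force group-by", {
  trials <- simulate_eeg(n_trials = 6, n_channels = 2, n_samples = 480,
                         seed = 46)
  fb <- eeg_feature_bank(trials)
  info <- attr(fb, "feature_info")
  set.seed(47)
  rel <- tibble::tibble(feature = info$feature,
                        rho = runif(nrow(info)),
                        rank = rank_decreasing_oracle(runif(nrow(info))))
  g <- relevance_by_group(rel)          # parses names itself
  for (ch in unique(info$channel)) {
    manual <- mean(rel$rho[info$channel == ch])
    expect_equal(g$by_channel$rho_mean[g$by_channel$channel == ch], manual)
  }
  for (pr in unique(info$principle)) {
    manual <- mean(rel$rho[info$principle == pr])
    expect_equal(g$by_principle$rho_mean[g$by_principle$principle == pr],
                 manual)
  }
  # uniform relevance -> equal group means
  relu <- rel
  relu$rho <- 1
  gu <- relevance_by_group(relu)
  expect_true(all(abs(gu$by_channel$rho_mean - 1) < 1e-12))
  # block support: relevance confined to one channel
  relb <- rel
  relb$rho <- ifelse(info$channel == "ch01", relb$rho, 0)
  gb <- relevance_by_group(relb)
  expect_equal(gb$by_channel$rho_mean[gb$by_channel$channel == "ch02"], 0)
  expect_gt(gb$by_channel$rho_mean[gb$by_channel$channel == "ch01"], 0)
  # malformed names are named in the error
  bad <- tibble::tibble(feature = c("ok.psd.alpha.mean", "broken_name"),
                        rho = c(1, 2))
  expect_error(relevance_by_group(bad), "broken_name",
               class = "ckalign_validation_error")
})
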