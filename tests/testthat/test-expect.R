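test_that("rating aggregation averages the right raters", {
  rt <- data.frame(
    subject_id = c("a", "b", "a", "b", "a", "b"),
    scene_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    category = "car",
    likelihood = c(0.2, 0.4, 0, 0.6, 0, 0),
    box_x = c(10, 30, NA, 100, NA, NA),
    box_y = c(5, 15, NA, 200, NA, NA),
    box_area = c(100, 300, NA, 500, NA, NA),
    box_aspect = c(1, 3, NA, 2, NA, NA), stringsAsFactors = FALSE)
  agg <- aggregate_ratings(rt)
  expect_equal(agg$likelihood[agg$scene_id == "s1"], 0.3)
  expect_equal(agg$x[agg$scene_id == "s1"], 20)
  ## single non-zero rater: box mean is that rater's box
  expect_equal(agg$x[agg$scene_id == "s2"], 100)
  expect_equal(agg$n_nonzero_raters[agg$scene_id == "s2"], 1)
  ## all-zero scene: likelihood 0, box aggregates absent
  expect_equal(agg$likelihood[agg$scene_id == "s3"], 0)
  expect_true(is.na(agg$x[agg$scene_id == "s3"]))
  expect_error(aggregate_ratings(rt[0, ]), "at least one rater")
})

test_that("least squares matches the normal-equations oracle", {
  expect_equal(fit_linear(matrix(1:10), 2 * (1:10))$weights,
               c(2), ignore_attr = TRUE, tolerance = 1e-10)
  f0 <- fit_linear(matrix(rnorm(20), 10), rep(3, 10))
  expect_equal(f0$intercept, 3, tolerance = 1e-10)
  expect_equal(unname(f0$weights), c(0, 0), tolerance = 1e-10)

  set.seed(8)
  X <- matrix(rnorm(150), 50, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(50)
  fit <- fit_linear(X, y)
  A <- cbind(1, X)
  b_oracle <- solve(crossprod(A), crossprod(A, y))
  expect_lt(max(abs(c(fit$intercept, fit$weights) - b_oracle)), 1e-8)

  ## rank deficiency: minimum-norm convention with a warning
  Xd <- cbind(X, X[, 1])
  expect_warning(fd <- fit_linear(Xd, y), "minimum-norm")
  expect_equal(fd$weights[1] + fd$weights[4], fit$weights[1],
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("cross-validation predicts every scene out of fold", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5)) + 5
  cv <- crossval_correlation(X, y, k = 5, seed = 3)
  expect_gte(cv$r, 0.999)  # noiseless linear response
  expect_equal(crossval_correlation(X, y, k = 5, seed = 3)$r, cv$r)
  expect_false(identical(crossval_correlation(X, y, k = 5, seed = 4)$folds,
                         cv$folds))
  expect_warning(crossval_correlation(X, rep(1, 100), k = 5, seed = 1),
                 "constant")
})

test_that("independent responses stay inside the permutation null band", {
  ss <- small_scene_set()
  y <- with_seed_test(31, rnorm(60))
  cv <- crossval_correlation(ss$channels, y, k = 5, seed = 1,
                             subset = "NC", pca_k = 4)
  nb <- permutation_null_band(ss$channels, y, subset = "NC", n_perm = 300,
                              seed = 2, pca_k = 4)
  expect_gt(cv$r, nb$band[1])
  expect_lt(cv$r, nb$band[2])
})

test_that("out-of-fold predictions cannot leak the held-out responses", {
  ss <- small_scene_set()
  y <- study_response(ss, "car")
  cv1 <- crossval_correlation(ss$channels, y, k = 5, seed = 6,
                              subset = "NC", pca_k = 4, pca_refit = TRUE)
  fold1 <- cv1$folds == 1
  y2 <- y
  y2[fold1] <- y2[fold1] + 10  # perturb only the held-out responses
  cv2 <- crossval_correlation(ss$channels, y2, k = 5, seed = 6,
                              subset = "NC", pca_k = 4, pca_refit = TRUE)
  expect_equal(cv1$predictions[fold1], cv2$predictions[fold1])
})

test_that("statistically equivalent models exceed each other half the time", {
  ## two independent pure-noise channels are exchangeable by symmetry, so
  ## the expected exceedance over replicate datasets is 1/2 (within one
  ## dataset the fraction is tilted by whichever channel happens to fit
  ## that dataset's noise better)
  set.seed(12)
  ex <- replicate(24, {
    channels <- list(T = matrix(rnorm(90 * 8), 90, 8),
                     C = matrix(rnorm(90 * 8), 90, 8))
    y <- rnorm(90)
    cmp <- compare_models(channels, y, subsets = c("T", "C"),
                          n_splits = 40, seed = sample.int(1e6, 1),
                          pca_k = 4, reference = "C")
    cmp$table$exceedance_fraction[cmp$table$subset == "T"]
  })
  expect_lt(abs(mean(ex) - 0.5), 3 * stats::sd(ex) / sqrt(length(ex)))

  ## single split: sd reported as 0
  channels <- list(T = matrix(rnorm(90 * 8), 90, 8),
                   C = matrix(rnorm(90 * 8), 90, 8))
  cmp1 <- compare_models(channels, rnorm(90), subsets = c("T", "C"),
                         n_splits = 1, seed = 5, pca_k = 4,
                         reference = "C")
  expect_true(all(cmp1$table$sd_r == 0))
})

test_that("subset truth separates channel models decisively", {
  ## response built from N and C latents only: NC dominates T
  sd <- study_data()
  cmp <- compare_models(sd$scene_set$channels, sd$y_car,
                        subsets = c("T", "NC"), n_splits = 200, seed = 8)
  expect_identical(cmp$reference, "NC")
  expect_lt(cmp$table$exceedance_fraction[cmp$table$subset == "T"], 0.001)
})

test_that("noise ceiling behaves like a reliability", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  r <- seq(0, 1, 0.1)
  expect_true(all(diff(spearman_brown(r)) > 0))   # monotone increasing
  expect_true(all(spearman_brown(r) >= r))        # >= r on [0, 1]

  ## zero subject noise: ceiling is exactly 1
  cfg <- small_config(seed = 13, subject_noise_sd = 0,
                      zero_likelihood_rate = 0)
  rt <- generate_subject_ratings(generate_scene_set(cfg))
  nc <- noise_ceiling(rt, "likelihood", "car", n_resamples = 50, seed = 1)
  expect_equal(nc$mean, 1, tolerance = 1e-12)

  one <- small_ratings()
  one <- one[one$subject_id == "subj_01", ]
  expect_error(noise_ceiling(one, "likelihood", "car"), "2 subjects")
})

test_that("nontarget weights invert exactly with the response sign", {
  ss <- small_scene_set()
  y <- study_response(ss, "car")
  m_car <- fit_expectation_model(ss$channels, y, "NC", pca_k = 4,
                                 response = "likelihood", category = "car")
  m_neg <- fit_expectation_model(ss$channels, -y, "NC", pca_k = 4,
                                 response = "likelihood",
                                 category = "person")
  nw <- nontarget_weight_correlation(m_car, m_neg)
  expect_equal(nw$r, -1, tolerance = 1e-8)
  m_c_only <- fit_expectation_model(ss$channels, y, "C", pca_k = 4)
  expect_error(nontarget_weight_correlation(m_car, m_c_only),
               "N channel")
})
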