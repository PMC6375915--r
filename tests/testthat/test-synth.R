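test_that("scene generation is bit-identical under a fixed seed", {
  cfg <- small_config(seed = 7)
  a <- generate_scene_set(cfg)
  b <- generate_scene_set(cfg)
  expect_identical(a$channels, b$channels)
  expect_identical(a$labels, b$labels)
  expect_identical(generate_subject_ratings(a), generate_subject_ratings(b))
})

test_that("vocabulary probabilities drive label occurrence", {
  vocab <- c(tree = 1.0, bench = 0.0, rock = 0.5, pole = 0.2, door = 0.4,
             sign = 0.3)
  cfg <- generator_config(n_scenes = 650, n_subjects = 2,
                          nontarget_vocabulary = vocab, coarse_dim = 20,
                          target_dim = 10, n_factors = 5,
                          true_weights = small_weights(), seed = 3)
  ss <- generate_scene_set(cfg)
  expect_true(all(ss$channels$N[, "tree"] == 1))
  expect_true(all(ss$channels$N[, "bench"] == 0))
  ## binomial sampling oracle: observed frequency within 3 SEs
  se <- sqrt(0.5 * 0.5 / 650)
  expect_lt(abs(mean(ss$channels$N[, "rock"]) - 0.5), 3 * se)
})

test_that("rating noise structure follows the configuration", {
  cfg <- small_config(seed = 5, subject_noise_sd = 0,
                      zero_likelihood_rate = 0)
  ss <- generate_scene_set(cfg)
  rt <- generate_subject_ratings(ss)
  ## no subject noise, no spontaneous zeros: all subjects agree per scene
  spread <- tapply(rt$likelihood,
                   interaction(rt$scene_id, rt$category), function(v)
                     diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("zero-likelihood ratings suppress the box; others carry one", {
  rt <- small_ratings()
  zero <- rt$likelihood == 0
  expect_true(any(zero))  # default config produces some zeros
  expect_true(all(is.na(rt$box_x[zero])))
  expect_true(all(is.na(rt$box_aspect[zero])))
  expect_false(any(is.na(rt$box_x[!zero])))
  expect_false(any(is.na(rt$box_area[!zero])))
  expect_true(all(rt$likelihood >= 0 & rt$likelihood <= 1))
})

test_that("split-half reliability matches the variance-component closed form", {
  ## Monte-Carlo oracle: with zero generating weights the shared scene
  ## component is exactly the scene noise, so the uncorrected split-half
  ## correlation of n/2-subject means has closed form ss^2/(ss^2 + 2 sn^2/n)
  ss_sd <- 0.08; sn_sd <- 0.1; n_sub <- 4
  closed <- ss_sd^2 / (ss_sd^2 + 2 * sn_sd^2 / n_sub)
  reps <- vapply(1:200, function(i) {
    cfg <- generator_config(n_scenes = 60, n_subjects = n_sub,
                            coarse_dim = 20, target_dim = 10, n_factors = 5,
                            true_weights = rapply(small_weights(),
                                                  function(v) v * 0,
                                                  how = "replace"),
                            scene_noise_sd = ss_sd,
                            subject_noise_sd = sn_sd,
                            zero_likelihood_rate = 0, seed = 1000 + i)
    rt <- generate_subject_ratings(generate_scene_set(cfg))
    rt <- rt[rt$category == "car", ]
    m <- matrix(rt$likelihood, ncol = n_sub)
    stats::cor(rowMeans(m[, 1:2]), rowMeans(m[, 3:4]))
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - closed), 3 * se)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_scenes = 0), "positive")
  expect_error(generator_config(coarse_dim = -1), "positive")
  expect_error(generator_config(
    nontarget_vocabulary = c(tree = 1.5)), "\\[0, 1\\]")
  expect_error(generator_config(zero_likelihood_rate = 2), "\\[0, 1\\]")
  expect_error(eval_config(n_pos = 0), "positive")
  expect_error(eval_config(associated_objects = c(dog = 2)), "\\[-1, 1\\]")
})

test_that("evaluation sets realize the configured separations", {
  ## no class separation: empirical AUC near 0.5
  es0 <- generate_eval_set(eval_config(n_pos = 800, n_neg = 800,
                                       score_separation = 0, seed = 9))
  auc0 <- roc_curve(es0$eval$score, es0$eval$label)$auc
  se_auc <- sqrt((800 + 800 + 1) / (12 * 800 * 800))
  expect_lt(abs(auc0 - 0.5), 3 * se_auc)

  ## uninformative prior: near-zero correlation with the label
  esu <- generate_eval_set(eval_config(n_pos = 1000, n_neg = 1000,
                                       prior_informativeness = 0,
                                       seed = 10))
  expect_lt(abs(stats::cor(esu$eval$prior_signal, esu$eval$label)),
            3 / sqrt(2000))

  ## uncoupled object: association index near zero
  esz <- generate_eval_set(eval_config(
    n_pos = 2500, n_neg = 2500,
    associated_objects = c(dog = 0, bus = 0.6), seed = 11))
  ai <- association_index(esz$presence, "dog", "car")
  expect_lt(ai, 3 * sqrt(0.25 / 2500))
  expect_gt(association_index(esz$presence, "bus", "car"), 0.1)

  ## determinism
  cfg <- eval_config(n_pos = 40, n_neg = 40, seed = 12)
  expect_identical(generate_eval_set(cfg), generate_eval_set(cfg))
})

test_that("default study conditions hit the intended regime", {
  ss <- study_data()$scene_set
  ## every scene has all three channel rows
  expect_true(all(vapply(ss$channels, nrow, 0L) == 650))
  ## 20 components capture most variance of the continuous channels
  expect_gte(fit_channel_pca(ss$channels$T, 20)$variance_captured, 0.85)
  expect_gte(fit_channel_pca(ss$channels$C, 20)$variance_captured, 0.85)
})
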