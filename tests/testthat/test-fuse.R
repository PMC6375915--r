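test_that("predicted priors reproduce in-sample fits and track the signal", {
  ss <- small_scene_set()
  y <- study_response(ss, "car")
  m <- fit_expectation_model(ss$channels, y, "C", pca_k = 4,
                             response = "likelihood", category = "car")
  ## applying the model to its training scenes gives its fitted values
  pr <- predict_priors(list(likelihood = m), ss$channels$C)
  fitted <- m$intercept +
    assemble_design("C", m$pcas, list(C = ss$channels$C)) %*% m$weights
  expect_equal(pr$prior_likelihood, as.numeric(fitted))

  ## zero-weight model predicts a constant equal to its intercept
  m0 <- fit_expectation_model(ss$channels, rep(0.4, 60), "C", pca_k = 4)
  p0 <- predict(m0, ss$channels$C)
  expect_equal(p0, rep(0.4, 60), tolerance = 1e-8)
})

test_that("ROC curve matches the concordant-pair oracle", {
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  ## perfectly separated classes
  expect_equal(roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(14)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    sc <- round(rnorm(n), 1)  # ties on purpose
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) %in% c(0, n)) next
    expect_lt(abs(roc_curve(sc, lb)$auc - pairwise_auc(sc, lb)), 1e-12)
  }
})

test_that("fused classifier honours separability, chance and determinism", {
  ## perfectly separable scores
  df <- data.frame(label = rep(c(0, 1), each = 50),
                   score = c(rnorm(50), rnorm(50) + 100))
  f <- train_fused_classifier(df, fusion_config(priors = character(0),
                                                seed = 2))
  expect_equal(f$accuracy_mean, 1)
  expect_equal(mean(f$fold_accuracy), f$accuracy_mean)

  ## permuted labels, balanced: accuracy within 3 binomial SEs of 0.5
  set.seed(15)
  dfn <- data.frame(label = rep(c(0, 1), 500), score = rnorm(1000))
  fn <- train_fused_classifier(dfn, fusion_config(priors = character(0),
                                                  seed = 3))
  expect_lt(abs(fn$accuracy_mean - 0.5), 3 * 0.5 / sqrt(1000))

  ## determinism under a fixed seed
  fn2 <- train_fused_classifier(dfn, fusion_config(priors = character(0),
                                                   seed = 3))
  expect_identical(fn$folds, fn2$folds)
  expect_identical(fn$accuracy_mean, fn2$accuracy_mean)

  expect_error(train_fused_classifier(df[c(1:5, 51:60), ],
                                      fusion_config()), "10 scenes")
})

test_that("discriminant agrees with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(16)
  n <- 200
  X <- cbind(score = rnorm(n) + rep(c(0, 1.2), each = n / 2),
             prior = rnorm(n) + rep(c(0, 0.6), each = n / 2))
  y <- rep(c(0L, 1L), each = n / 2)
  fit <- contextpriors:::lda_train(X, y)
  pred_ours <- as.integer(contextpriors:::lda_score(fit, X) > 0)
  ref <- MASS::lda(X, grouping = y)
  pred_ref <- as.integer(as.character(predict(ref, X)$class))
  expect_equal(pred_ours, pred_ref)
})

test_that("score-only results respect monotone-transform invariances", {
  set.seed(17)
  df <- data.frame(label = rep(c(0, 1), 300),
                   score = rnorm(600) + rep(c(0, 1), 300))
  f1 <- train_fused_classifier(df, fusion_config(priors = character(0),
                                                 seed = 4))
  ## positive affine map: identical accuracy and AUC (LDA equivariance)
  df2 <- df; df2$score <- 3 * df$score + 7
  f2 <- train_fused_classifier(df2, fusion_config(priors = character(0),
                                                  seed = 4))
  expect_equal(f2$accuracy_mean, f1$accuracy_mean)
  expect_equal(f2$auc, f1$auc, tolerance = 1e-10)
  ## any strictly monotone map preserves the AUC of the raw score
  expect_equal(roc_curve(exp(df$score), df$label)$auc,
               roc_curve(df$score, df$label)$auc, tolerance = 1e-12)
})

test_that("augmentation table reports deltas against the baseline", {
  es <- generate_eval_set(eval_config(n_pos = 300, n_neg = 300, seed = 18))
  ev <- es$eval
  ev$prior_ctx <- ev$prior_signal
  tab <- augmentation_table(ev, list(ctx = "prior_ctx"), seed = 5)
  expect_equal(tab$delta_points[tab$config == "baseline"], 0)
  expect_true(all(c("baseline", "ctx") %in% tab$config))
  expect_true(all(tab$accuracy_mean >= 0 & tab$accuracy_mean <= 1))
})
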