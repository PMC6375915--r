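test_that("association index equals contingency counting exactly", {
  P <- cbind(car = c(1, 1, 0, 0), bicycle = c(1, 1, 1, 0))
  expect_equal(association_index(P, "bicycle", "car"), 0.25)

  ## brute-force 2x2 contingency oracle on random tables
  set.seed(19)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    M <- cbind(anchor = rbinom(n, 1, 0.5), obj = rbinom(n, 1, 0.4))
    if (sum(M[, "anchor"]) == 0) next
    tab <- table(factor(M[, "anchor"], 0:1), factor(M[, "obj"], 0:1))
    p_cond <- tab["1", "1"] / sum(tab["1", ])
    p_marg <- sum(tab[, "1"]) / n
    expect_identical(association_index(M, "obj", "anchor"),
                     abs(p_cond - p_marg))
  }

  ## constructed: p(obj) = 0.5, p(obj | anchor) = 1 gives exactly 0.5
  Pc <- cbind(anchor = rep(c(1, 0), each = 50),
              obj = c(rep(1, 50), rep(0, 50)))
  expect_equal(association_index(Pc, "obj", "anchor"), 0.5)

  expect_error(association_index(cbind(a = c(0, 0), b = c(1, 0)),
                                 "b", "a"), "never present")
})

test_that("independent objects have near-zero association", {
  set.seed(20)
  n <- 5000
  P <- cbind(car = rbinom(n, 1, 0.5), obj = rbinom(n, 1, 0.3))
  expect_lt(association_index(P, "obj", "car"),
            3 * sqrt(0.3 * 0.7 / (n / 2)))
})

test_that("benefit correlations recover constructed relationships", {
  ## improvement exactly -baseline: r = -1
  s <- data.frame(improvement_points = -(1:10), baseline_accuracy = 1:10,
                  association = rep(0.2, 10) + (1:10) / 100)
  bc <- benefit_correlation(s)
  expect_equal(bc$vs_baseline$r, -1, tolerance = 1e-12)

  ## decreasing function of baseline: negative r recovered
  set.seed(21)
  base <- runif(12, 0.5, 0.9)
  s2 <- data.frame(improvement_points = 10 * (1 - base) + rnorm(12, 0, 0.2),
                   baseline_accuracy = base,
                   association = runif(12))
  expect_lt(benefit_correlation(s2)$vs_baseline$r, 0)

  ## permuted improvements: |r| inside the 99% permutation band
  obs <- abs(benefit_correlation(
    transform(s2, improvement_points = sample(improvement_points)))
    $vs_baseline$r)
  null_r <- replicate(500, abs(stats::cor(sample(s2$improvement_points),
                                          s2$baseline_accuracy)))
  expect_lt(obs, stats::quantile(null_r, 0.995))

  ## degenerate input
  s3 <- s2; s3$association <- 0.5
  expect_warning(bc3 <- benefit_correlation(s3), "constant")
  expect_true(is.na(bc3$vs_association$r))
  expect_error(benefit_correlation(s2[1:2, ]), "3 categories")
})

test_that("transfer experiment tabulates per-category improvements", {
  es <- generate_eval_set(eval_config(
    n_pos = 400, n_neg = 400,
    associated_objects = c(bike = 0.8, tv = 0.05), seed = 22))
  ts <- transfer_experiment(es, folds = 5, seed = 2)
  expect_setequal(ts$category, c("bike", "tv"))
  expect_true(all(ts$association >= 0 & ts$association <= 1))
  expect_equal(ts$improvement_points,
               100 * (ts$augmented_accuracy - ts$baseline_accuracy))
  ## the strongly coupled category is the more associated one
  expect_gt(ts$association[ts$category == "bike"],
            ts$association[ts$category == "tv"])
})
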