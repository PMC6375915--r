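test_that("detection thresholds partition counts as specified", {
  recs <- rbind(make_detection(score = -0.5), make_detection(score = -1.0),
                make_detection(score = -1.5))
  v <- summarize_detections(recs)
  ## direct counting oracle: one strong (> -0.7), two weak (> -1.2)
  expect_equal(unname(v["car_n_strong"]), 1)
  expect_equal(unname(v["car_false_alarms"]), 1)
  expect_equal(unname(v["car_mean_score"]), mean(c(-0.5, -1, -1.5)))
  expect_error(summarize_detections(recs, strong_threshold = -1.2,
                                    weak_threshold = -0.7), "exceed")
})

test_that("single-record geometry statistics are exact", {
  ## 100 x 50 box centred on the 640 x 480 frame centre
  rec <- make_detection(score = -0.3, box_x = 320 - 50, box_y = 240 - 25,
                        box_width = 100, box_height = 50)
  v <- summarize_detections(rec)
  expect_equal(unname(v["car_mean_area"]), 5000)
  expect_equal(unname(v[sprintf("car_ecc_%d", 1:5)]), c(1, 0, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(v["car_view_car_1"]), 1)
  expect_equal(sum(v[sprintf("car_ecc_%d", 1:5)]), nrow(rec))
})

test_that("scenes without detections yield all-zero summaries", {
  empty <- make_detection()[0, ]
  v <- summarize_detections(empty)
  expect_length(v, 62)
  expect_true(all(v == 0))
})

test_that("detection summaries are permutation-invariant over record order", {
  set.seed(4)
  recs <- do.call(rbind, lapply(1:6, function(i)
    make_detection(category = sample(c("car", "person"), 1),
                   view = sample(3, 1), score = runif(1, -1.5, 0),
                   box_x = runif(1, 0, 500), box_y = runif(1, 0, 400),
                   box_width = runif(1, 20, 120),
                   box_height = runif(1, 20, 120),
                   parts = runif(16))))
  pm <- detection_part_means(recs)
  v1 <- summarize_detections(recs, pm)
  v2 <- summarize_detections(recs[sample(nrow(recs)), ], pm)
  expect_equal(v1, v2)
  ## eccentricity histogram accounts for every detection per category
  for (cat in c("car", "person"))
    expect_equal(sum(v1[sprintf("%s_ecc_%d", cat, 1:5)]),
                 sum(recs$category == cat))
})

test_that("part-deformation statistics use dataset-wide part means", {
  ## two scenes; part 1 at x = 0.2 in scene A, x = 0.6 in scene B
  pa <- rep(0.5, 16); pa[1] <- 0.2
  pb <- rep(0.5, 16); pb[1] <- 0.6
  recs <- rbind(make_detection(scene_id = "A", parts = pa),
                make_detection(scene_id = "B", parts = pb))
  ch <- build_target_channel(recs, c("A", "B"))
  ## dataset mean of part 1 x is 0.4; displacements are -0.2 and +0.2
  expect_equal(unname(ch["A", "car_deform_p1_dx"]), -0.2)
  expect_equal(unname(ch["B", "car_deform_p1_dx"]), 0.2)
  expect_equal(unname(ch["A", "car_deform_p1_dy"]), 0)
  expect_error(build_target_channel(recs, "A"), "unknown scenes")
})

test_that("nontarget channel is an exact indicator matrix", {
  labs <- data.frame(scene_id = c("s1", "s1", "s2"),
                     label = c("tree", "bench", "tree"),
                     stringsAsFactors = FALSE)
  m <- build_nontarget_channel(labs, c("tree", "bench", "rock"),
                               scene_ids = c("s1", "s2", "s3"))
  expect_equal(m["s1", ], c(tree = 1, bench = 1, rock = 0))
  expect_equal(unname(m["s3", ]), c(0, 0, 0))  # empty label set
  expect_error(build_nontarget_channel(labs, c("tree")), "bench")

  ## counting oracle on generated scenes: column sums = label frequencies
  ss <- small_scene_set()
  m2 <- build_nontarget_channel(ss$labels,
                                names(ss$truth$config$nontarget_vocabulary),
                                scene_ids = ss$scenes$scene_id)
  expect_equal(colSums(m2), colSums(ss$channels$N))
})

test_that("channel PCA is orthonormal and accounts for variance", {
  set.seed(2)
  ## rank-1 matrix: one component captures everything
  x1 <- outer(rnorm(30), rnorm(6))
  p1 <- fit_channel_pca(x1, k = 1, standardize = FALSE)
  expect_equal(p1$variance_captured, 1)

  x <- matrix(rnorm(40 * 12), 40, 12)
  p <- fit_channel_pca(x, k = 5)
  expect_equal(crossprod(p$rotation), diag(5), tolerance = 1e-8)
  expect_error(fit_channel_pca(x, k = 13), "k must lie")

  ## zero-variance column: scale floor keeps the fit finite
  xz <- cbind(x, 0)
  expect_true(all(is.finite(fit_channel_pca(xz, k = 3)$rotation)))

  ## projecting the channel mean row gives zero scores
  mu <- matrix(colMeans(x), 1)
  expect_equal(max(abs(predict(p, mu))), 0, tolerance = 1e-10)
})

test_that("reconstruction error is non-increasing in k", {
  set.seed(6)
  x <- matrix(rnorm(50 * 10), 50, 10) + outer(rnorm(50), rnorm(10)) * 2
  errs <- vapply(1:8, function(k) {
    p <- fit_channel_pca(x, k = k, standardize = FALSE)
    sc <- predict(p, x)
    xr <- sc %*% t(p$rotation)
    xc <- sweep(x, 2, p$center)
    sum((xc - xr)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("design assembly concatenates channel projections", {
  ss <- small_scene_set()
  pcas <- lapply(ss$channels, fit_channel_pca, k = 4)
  d1 <- assemble_design("N", pcas, ss$channels)
  d3 <- assemble_design("TNC", pcas, ss$channels)
  expect_equal(ncol(d1), 4)
  expect_equal(ncol(d3), 12)
  ## nested subsets are column-submatrices of the full design
  dnc <- assemble_design(c("N", "C"), pcas, ss$channels)
  expect_equal(dnc, d3[, 5:12])
  expect_error(assemble_design(character(0), pcas, ss$channels),
               "non-empty")
  expect_error(assemble_design("X", pcas, ss$channels), "unknown")
})
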