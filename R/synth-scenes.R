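#' Generate a synthetic scene set with three feature channels
#'
#' Simulates a set of target-absent scenes together with the three per-scene
#' feature channels consumed by the expectation models:
#' \describe{
#'   \item{T}{continuous target-detector summary features (default 62 dims),}
#'   \item{N}{binary nontarget-object labels drawn from the configured
#'     vocabulary probabilities via a probit factor model (marginal label
#'     frequencies match the vocabulary exactly in expectation),}
#'   \item{C}{continuous coarse scene features (default 512 dims).}
#' }
#' Each channel is low rank by construction: `n_factors` latent components
#' with decaying strengths plus isotropic noise, so that a 20-component PCA
#' captures the bulk of the variance. The returned `truth` record stores the
#' latent factor scores, loadings, generating weights and noise parameters,
#' enabling exact parameter-recovery checks downstream.
#'
#' @param config A [generator_config()].
#' @return A list of class `scene_set` with elements
#'   \describe{
#'     \item{scenes}{data.frame of scene ids,}
#'     \item{labels}{long data.frame (scene_id, label) of nontarget labels,}
#'     \item{channels}{named list of T/N/C matrices (rows = scenes),}
#'     \item{truth}{generating record (config, factor scores `Z`, loadings,
#'       factor strengths `lambda`, probit thresholds, per-category latent
#'       response tables).}
#'   }
#' @export
#' @examples
#' ss <- generate_scene_set(generator_config(n_scenes = 30, seed = 7))
#' dim(ss$channels$C)
generate_scene_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(config$seed, c("scenes", "ratings", "eval"))
  n <- config$n_scenes
  k <- config$n_factors
  vocab <- config$nontarget_vocabulary
  dims <- c(T = config$target_dim, N = length(vocab), C = config$coarse_dim)
  if (k > min(dims))
    stop_input("n_factors exceeds the smallest channel dimension")

  with_seed(seeds[["scenes"]], {
    scene_id <- sprintf("scene_%04d", seq_len(n))

    ## latent factor scores, orthonormal-row loadings, decaying strengths
    Z <- lapply(dims, function(d) matrix(stats::rnorm(n * k), n, k))
    loadings <- lapply(dims, function(d) {
      t(qr.Q(qr(matrix(stats::rnorm(d * k), d, k))))  # k x d, rows orthonormal
    })
    lambda <- lapply(dims, function(d) {
      dec <- (k:1)
      sqrt(d * dec / sum(dec))
    })
    signal <- function(ch) Z[[ch]] %*% (lambda[[ch]] * loadings[[ch]])

    X_T <- signal("T") + matrix(stats::rnorm(n * dims["T"],
                                sd = config$channel_noise_sd[["T"]]),
                                n, dims[["T"]])
    colnames(X_T) <- sprintf("T%d", seq_len(dims[["T"]]))
    rownames(X_T) <- scene_id

    X_C <- signal("C") + matrix(stats::rnorm(n * dims["C"],
                                sd = config$channel_noise_sd[["C"]]),
                                n, dims[["C"]])
    colnames(X_C) <- sprintf("C%d", seq_len(dims[["C"]]))
    rownames(X_C) <- scene_id

    ## N channel: probit factor model preserving marginal label frequencies
    sd_u <- config$channel_noise_sd[["N"]]
    F_N <- signal("N")
    v <- colSums((lambda[["N"]] * loadings[["N"]])^2)
    thresh <- -stats::qnorm(vocab) * sqrt(v + sd_u^2)
    U <- matrix(stats::rnorm(n * dims["N"], sd = sd_u), n, dims[["N"]])
    X_N <- 1 * sweep(F_N + U, 2, thresh, ">")
    colnames(X_N) <- names(vocab)
    rownames(X_N) <- scene_id

    idx <- which(X_N == 1, arr.ind = TRUE)
    labels <- data.frame(scene_id = scene_id[idx[, 1]],
                         label = colnames(X_N)[idx[, 2]],
                         stringsAsFactors = FALSE)
    labels <- labels[order(match(labels$scene_id, scene_id)), ]
    rownames(labels) <- NULL

    ## latent responses per category x response
    latent <- list()
    for (cat in names(config$true_weights)) {
      w <- config$true_weights[[cat]]
      lat <- data.frame(scene_id = scene_id, stringsAsFactors = FALSE)
      for (resp in names(w)) {
        lat[[resp]] <- as.numeric(
          Z[["T"]] %*% w[[resp]]$T + Z[["N"]] %*% w[[resp]]$N +
          Z[["C"]] %*% w[[resp]]$C)
      }
      lat$likelihood <- 0.5 + lat$likelihood
      latent[[cat]] <- lat
    }

    truth <- list(config = config, seeds = seeds, Z = Z,
                  loadings = loadings, lambda = lambda,
                  probit_thresholds = thresh, probit_colvar = v + sd_u^2,
                  latent = latent)
    structure(list(scenes = data.frame(scene_id = scene_id,
                                       stringsAsFactors = FALSE),
                   labels = labels,
                   channels = list(T = X_T, N = X_N, C = X_C),
                   truth = truth),
              class = "scene_set")
  })
}

#' @export
print.scene_set <- function(x, ...) {
  cat("Synthetic scene set:", nrow(x$scenes), "scenes;",
      "channels T/N/C with", paste(vapply(x$channels, ncol, 0L),
                                   collapse = "/"),
      "dims;", x$truth$config$n_factors, "latent factors per channel\n")
  invisible(x)
}

## Map a latent box response value (unit scale) into pixel/area/aspect units.
latent_box <- function(latent, cat, config) {
  w <- config$image_width; h <- config$image_height
  area0 <- if (cat == "car") 15000 else 6000       # px^2
  aspect0 <- if (cat == "car") 0.5 else 2.5        # height / width
  list(x = clip_range(w / 2 + (w / 4) * latent$x, 0, w),
       y = clip_range(h / 2 + (h / 4) * latent$y, 0, h),
       area = area0 * exp(0.5 * latent$area),
       aspect = aspect0 * exp(0.3 * latent$aspect))
}

#' Generate subject-level likelihood ratings and most-likely boxes
#'
#' Simulates the behavioural rating table: for every subject x scene x
#' category, a likelihood rating in `[0, 1]` equal to the scene's latent
#' linear signal plus shared scene noise plus independent subject noise,
#' truncated to the unit interval; and, whenever the rating is non-zero, a
#' most-likely bounding box (x, y, area, aspect ratio) equal to the scene's
#' latent box plus subject jitter. With probability `zero_likelihood_rate`
#' a subject spontaneously rates a scene 0, in which case the box fields are
#' absent (`NA`), mirroring the task in which a box is only placed for
#' non-zero likelihood ratings.
#'
#' @param scene_set Output of [generate_scene_set()].
#' @param config The generator configuration; defaults to the one stored in
#'   the scene set's truth record.
#' @return A data.frame with columns subject_id, scene_id, category,
#'   likelihood, box_x, box_y, box_area, box_aspect.
#' @export
#' @examples
#' ss <- generate_scene_set(generator_config(n_scenes = 20, n_subjects = 3,
#'                                           seed = 2))
#' head(generate_subject_ratings(ss))
generate_subject_ratings <- function(scene_set,
                                     config = scene_set$truth$config) {
  stopifnot(inherits(scene_set, "scene_set"))
  if (!identical(config$n_scenes, nrow(scene_set$scenes)))
    stop_input("config does not match the scene set (n_scenes differs)")
  n <- config$n_scenes
  S <- config$n_subjects
  subj_id <- sprintf("subj_%02d", seq_len(S))

  with_seed(scene_set$truth$seeds[["ratings"]], {
    out <- vector("list", length(scene_set$truth$latent))
    ci <- 0
    for (cat in names(scene_set$truth$latent)) {
      lat <- scene_set$truth$latent[[cat]]
      box <- latent_box(lat, cat, config)

      scene_noise <- stats::rnorm(n, sd = config$scene_noise_sd)
      e <- matrix(stats::rnorm(n * S, sd = config$subject_noise_sd), n, S)
      zero <- matrix(stats::runif(n * S) < config$zero_likelihood_rate, n, S)
      jx <- matrix(stats::rnorm(n * S, sd = config$box_jitter_px), n, S)
      jy <- matrix(stats::rnorm(n * S, sd = config$box_jitter_px), n, S)
      ja <- matrix(stats::rnorm(n * S, sd = config$area_jitter_sdlog), n, S)
      jr <- matrix(stats::rnorm(n * S, sd = config$aspect_jitter_sdlog), n, S)

      lik <- clip01(lat$likelihood + scene_noise + e)
      lik[zero] <- 0
      bx <- clip_range(box$x + jx, 0, config$image_width)
      by <- clip_range(box$y + jy, 0, config$image_height)
      ba <- box$area * exp(ja)
      br <- box$aspect * exp(jr)
      absent <- lik == 0
      bx[absent] <- NA_real_; by[absent] <- NA_real_
      ba[absent] <- NA_real_; br[absent] <- NA_real_

      ci <- ci + 1
      out[[ci]] <- data.frame(
        subject_id = rep(subj_id, each = n),
        scene_id = rep(scene_set$scenes$scene_id, S),
        category = cat,
        likelihood = as.vector(lik),
        box_x = as.vector(bx), box_y = as.vector(by),
        box_area = as.vector(ba), box_aspect = as.vector(br),
        stringsAsFactors = FALSE)
    }
    ratings <- do.call(rbind, out)
    rownames(ratings) <- NULL
    ratings
  })
}
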