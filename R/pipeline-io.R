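## Serialization of fitted objects and truth records for the file-based
## stage handoff. JSON only (text deliverables); matrices round-trip as
## nested arrays.

pca_to_list <- function(p)
  list(center = unname(p$center), scale = unname(p$scale),
       rotation = unname(p$rotation), sdev = p$sdev, k = p$k,
       variance_captured = p$variance_captured, features = p$features)

pca_from_list <- function(l) {
  rot <- if (is.list(l$rotation))
    do.call(rbind, lapply(l$rotation, as.numeric)) else as.matrix(l$rotation)
  rownames(rot) <- l$features
  structure(list(center = stats::setNames(as.numeric(l$center), l$features),
                 scale = stats::setNames(as.numeric(l$scale), l$features),
                 rotation = rot, sdev = as.numeric(l$sdev),
                 k = as.integer(l$k),
                 variance_captured = as.numeric(l$variance_captured),
                 features = l$features), class = "channel_pca")
}

model_to_list <- function(m)
  list(response = m$response, category = m$category, subset = m$subset,
       intercept = m$intercept, weights = as.list(m$weights),
       pcas = lapply(m$pcas, pca_to_list))

model_from_list <- function(l) {
  w <- unlist(l$weights)
  structure(list(subset = unlist(l$subset),
                 pcas = lapply(l$pcas, pca_from_list),
                 intercept = as.numeric(l$intercept), weights = w,
                 response = l$response, category = l$category,
                 train_ids = NULL), class = "expectation_model")
}

#' Write / read fitted expectation models
#'
#' Serializes a named list of [fit_expectation_model()] objects (weights,
#' intercept and full per-channel PCA state) to a single JSON file.
#'
#' @param models Named list of expectation models.
#' @param path JSON path.
#' @return `write_models` the path; `read_models` the named model list.
#' @export
write_models <- function(models, path) {
  write_json_atomic(lapply(models, model_to_list), path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  lapply(raw, model_from_list)
}

## truth record: only the pieces needed downstream (C-channel observation
## model + generating weights); factor scores are not persisted.
truth_to_list <- function(truth) {
  cfg <- truth$config
  list(n_scenes = cfg$n_scenes, n_subjects = cfg$n_subjects,
       n_factors = cfg$n_factors, coarse_dim = cfg$coarse_dim,
       target_dim = cfg$target_dim,
       image_width = cfg$image_width, image_height = cfg$image_height,
       nontarget_vocabulary = as.list(cfg$nontarget_vocabulary),
       channel_noise_sd = as.list(cfg$channel_noise_sd),
       subject_noise_sd = cfg$subject_noise_sd,
       scene_noise_sd = cfg$scene_noise_sd,
       zero_likelihood_rate = cfg$zero_likelihood_rate,
       seed = cfg$seed,
       true_weights = cfg$true_weights,
       lambda_C = truth$lambda[["C"]],
       loadings_C = unname(truth$loadings[["C"]]))
}

truth_from_list <- function(l) {
  cfg <- list(n_scenes = l$n_scenes, n_subjects = l$n_subjects,
              n_factors = l$n_factors, coarse_dim = l$coarse_dim,
              target_dim = l$target_dim,
              image_width = l$image_width, image_height = l$image_height,
              nontarget_vocabulary = unlist(l$nontarget_vocabulary),
              channel_noise_sd = unlist(l$channel_noise_sd),
              subject_noise_sd = l$subject_noise_sd,
              scene_noise_sd = l$scene_noise_sd,
              zero_likelihood_rate = l$zero_likelihood_rate,
              seed = l$seed,
              true_weights = rapply(l$true_weights, as.numeric,
                                    how = "replace"))
  list(config = cfg,
       lambda = list(C = as.numeric(l$lambda_C)),
       loadings = list(C = as.matrix(l$loadings_C)))
}

require_artifact <- function(dir, file, stage) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop_input("missing ", file, "; run stage '", stage, "' first")
  path
}

## channel matrix <-> CSV (scene_id + numbered feature columns)
write_channel_csv <- function(m, path) {
  df <- data.frame(scene_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_pipeline_csv(df, path)
}

read_channel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$scene_id
  m
}
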