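## Back-project a model's component weights for one channel into raw
## feature space: d(yhat)/d(feature_j) = (rotation %*% w_components)_j / scale_j
backproject_weights <- function(model, channel) {
  if (!channel %in% model$subset)
    stop_input("model does not include the ", channel, " channel")
  idx <- grep(paste0("^", channel, "[0-9]+$"), names(model$weights))
  w <- model$weights[idx]
  pca <- model$pcas[[channel]]
  as.numeric(pca$rotation %*% w) / pca$scale
}

#' Correlation of nontarget-label weights between two models
#'
#' Back-projects the nontarget (N) component weights of two expectation
#' models through their PCA loadings to per-label regression weights, and
#' correlates the two label-weight vectors (Pearson). A negative value
#' indicates that nontarget objects which push one category's likelihood up
#' push the other's down (e.g. highway furniture raising car likelihood and
#' lowering person likelihood).
#'
#' @param model_a,model_b Two [fit_expectation_model()] results whose
#'   subsets include the N channel (e.g. car and person likelihood models).
#' @return List with `r`, the per-label weight vectors `weights_a`,
#'   `weights_b`, and the label names.
#' @export
nontarget_weight_correlation <- function(model_a, model_b) {
  wa <- backproject_weights(model_a, "N")
  wb <- backproject_weights(model_b, "N")
  if (length(wa) != length(wb))
    stop_input("models were fit on different nontarget vocabularies")
  labels <- model_a$pcas$N$features %||% seq_along(wa)
  list(r = stats::cor(wa, wb), weights_a = stats::setNames(wa, labels),
       weights_b = stats::setNames(wb, labels), labels = labels)
}

#' Recover effective latent-component weights from a fitted model
#'
#' For synthetic data the generator's truth record stores, per channel, the
#' latent factor loadings and strengths. This helper maps a fitted model's
#' feature-space weights back onto the latent components, giving the
#' model's average marginal effect per generating component: for the
#' continuous channels the chain rule through the observation model
#' `X = Z (lambda A) + noise`; for the binary N channel each label's
#' back-projected weight is additionally attenuated by the probit link's
#' average derivative. Correlating the result with the generating weights
#' quantifies parameter recovery.
#'
#' @param model An [fit_expectation_model()] result fit on channels from
#'   [generate_scene_set()].
#' @param truth The scene set's `truth` record.
#' @param channels Channels to recover (default the model's subset).
#' @return Named numeric vector of effective latent weights (length
#'   `n_factors` per channel, names like `N1..N20, C1..C20`).
#' @export
recover_latent_weights <- function(model, truth,
                                   channels = model$subset) {
  out <- list()
  for (ch in channels) {
    b <- backproject_weights(model, ch)
    if (ch == "N") {
      sdv <- sqrt(truth$probit_colvar)
      atten <- stats::dnorm(truth$probit_thresholds / sdv) / sdv
      b <- b * atten
    }
    w_eff <- as.numeric((truth$lambda[[ch]] * truth$loadings[[ch]]) %*% b)
    out[[ch]] <- stats::setNames(w_eff,
                                 sprintf("%s%d", ch, seq_along(w_eff)))
  }
  do.call(c, unname(out))
}

#' Parameter recovery against the noise-free generating signal
#'
#' Quantifies how faithfully a model fit on noisy behavioural aggregates
#' recovers the generator's weights: the same pipeline (identical channel
#' PCAs and design) is refit on the noise-free latent response stored in
#' the truth record, giving the oracle weight vector the generator implies
#' in design space; the fitted and oracle weight vectors are then
#' correlated. This isolates the effect of rating noise on estimation from
#' the information loss intrinsic to the observed channels (e.g. the
#' binarized nontarget labels).
#'
#' @param model An [fit_expectation_model()] result fit on channels from
#'   [generate_scene_set()].
#' @param truth The scene set's `truth` record.
#' @param channels The channel matrices the model was fit on.
#' @return List with `r` (correlation of fitted vs oracle weights),
#'   `weights` and `oracle_weights`.
#' @export
weight_recovery <- function(model, truth, channels) {
  cat <- model$category; resp <- model$response
  if (is.na(cat) || is.na(resp))
    stop_input("model must carry its category and response labels")
  s <- truth$latent[[cat]][[resp]]
  if (is.null(s)) stop_input("truth has no latent ", cat, "/", resp)
  oracle <- fit_expectation_model(channels, s,
                                  subset = paste(model$subset,
                                                 collapse = ""),
                                  pca_k = model$pcas[[1]]$k,
                                  response = resp, category = cat)
  list(r = stats::cor(model$weights, oracle$weights),
       weights = model$weights, oracle_weights = oracle$weights)
}

#' Generating latent weights for one category and response
#'
#' Companion to [recover_latent_weights()]: the true latent-component
#' weights the generator used, concatenated over the requested channels.
#'
#' @param truth A scene set's `truth` record.
#' @param category,response Which generating weight vector.
#' @param channels Channels to include, in order.
#' @return Named numeric vector matching [recover_latent_weights()] layout.
#' @export
generating_weights <- function(truth, category = "car",
                               response = "likelihood",
                               channels = c("N", "C")) {
  w <- truth$config$true_weights[[category]][[response]]
  if (is.null(w)) stop_input("no generating weights for ", category, "/",
                             response)
  out <- lapply(stats::setNames(channels, channels), function(ch)
    stats::setNames(w[[ch]], sprintf("%s%d", ch, seq_along(w[[ch]]))))
  do.call(c, unname(out))
}
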