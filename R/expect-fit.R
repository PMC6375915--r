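#' Ordinary least squares with an intercept
#'
#' Solves `y = b0 + X b` by least squares via the singular value
#' decomposition. On rank-deficient designs the minimum-norm solution is
#' returned with a warning (base `lm` would instead drop columns).
#'
#' @param X Design matrix (rows = observations).
#' @param y Response vector.
#' @return List with `intercept` and named `weights` (length `ncol(X)`).
#' @export
#' @examples
#' X <- matrix(1:10, 10, 1)
#' fit_linear(X, 2 * X[, 1])$weights  # 2
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop_input("rows(X) must equal length(y)")
  A <- cbind(`(Intercept)` = 1, X)
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (sum(pos) < ncol(A))
    warning("rank-deficient design; returning the minimum-norm solution",
            call. = FALSE)
  b <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  w <- as.numeric(b[-1])
  names(w) <- colnames(X)
  list(intercept = as.numeric(b[1]), weights = w)
}

#' Fit a linear expectation model on a channel subset
#'
#' Fits the standard pipeline for one response variable: per-channel PCA to
#' `pca_k` components on the supplied scenes, horizontal concatenation of
#' the channel projections, then ordinary least squares `y = Xb`.
#'
#' @param channels Named list of channel matrices (any of T, N, C), rows in
#'   scene order.
#' @param y Per-scene response (e.g. mean likelihood from
#'   [aggregate_ratings()]).
#' @param subset Channel subset, e.g. `"NC"`.
#' @param pca_k Components per channel (default 20).
#' @param response,category Optional labels stored with the model.
#' @param scene_ids Optional training-scene ids stored with the model.
#' @return Object of class `expectation_model`: `subset`, fitted `pcas`,
#'   `intercept`, `weights` (named by design column), labels.
#' @export
fit_expectation_model <- function(channels, y, subset = "NC", pca_k = 20,
                                  response = NA_character_,
                                  category = NA_character_,
                                  scene_ids = NULL) {
  subset <- parse_subset(subset)
  keep <- !is.na(y)
  pcas <- lapply(stats::setNames(subset, subset), function(ch) {
    if (is.null(channels[[ch]]))
      stop_input("channel ", ch, " not supplied")
    fit_channel_pca(channels[[ch]][keep, , drop = FALSE], k = pca_k)
  })
  X <- assemble_design(subset, pcas,
                       lapply(channels[subset],
                              function(m) m[keep, , drop = FALSE]))
  fit <- fit_linear(X, y[keep])
  structure(list(subset = subset, pcas = pcas,
                 intercept = fit$intercept, weights = fit$weights,
                 response = response, category = category,
                 train_ids = scene_ids[keep] %||% which(keep)),
            class = "expectation_model")
}

#' Predict an expectation model on new scenes
#'
#' @param object An [fit_expectation_model()] result.
#' @param newdata Either a named list of channel matrices or a single
#'   matrix/data.frame containing the required feature columns (matched by
#'   name through each channel's PCA).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.expectation_model <- function(object, newdata, ...) {
  channels <- if (is.list(newdata) && !is.data.frame(newdata)) newdata else
    stats::setNames(rep(list(newdata), length(object$subset)),
                    object$subset)
  X <- assemble_design(object$subset, object$pcas, channels)
  as.numeric(object$intercept + X %*% object$weights)
}

#' @export
print.expectation_model <- function(x, ...) {
  cat("Expectation model:",
      if (!is.na(x$category)) x$category else "", "/",
      if (!is.na(x$response)) x$response else "?",
      "on channels", paste(x$subset, collapse = "+"),
      sprintf("(%d design columns)", length(x$weights)), "\n")
  invisible(x)
}
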