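## Late fusion: augmenting detector confidence scores with predicted
## contextual priors via cross-validated linear discriminant analysis.

#' Predict contextual priors for novel scenes
#'
#' Applies a set of fitted expectation models to the feature columns of an
#' evaluation table, yielding one predicted prior per requested response per
#' scene (e.g. predicted likelihood, y-location, scale) without any human
#' annotation of the new scenes.
#'
#' @param models Named list of [fit_expectation_model()] results; names
#'   become the output columns (prefixed `prior_`).
#' @param newdata Matrix or data.frame containing the feature columns the
#'   models were fit on (matched by name), or a named list of channel
#'   matrices.
#' @return Data.frame of predicted priors, columns `prior_<name>`.
#' @export
predict_priors <- function(models, newdata) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop_input("models must be a named list")
  out <- lapply(models, function(m) predict(m, newdata))
  out <- as.data.frame(out, optional = TRUE)
  names(out) <- paste0("prior_", names(models))
  out
}

## Two-class linear discriminant with pooled covariance and empirical class
## priors. Ridge-stabilizes a (near-)singular pooled covariance, logging the
## jitter used. Returns the discriminant direction and offset; the signed
## discriminant value is used as the ROC score.
lda_train <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 < 2 || n1 < 2) stop_input("each class needs at least 2 cases")
  X0 <- X[y == 0, , drop = FALSE]; X1 <- X[y == 1, , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  S <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) / (n0 + n1 - 2)
  ridge <- 0
  repeat {
    Sr <- S + diag(ridge, ncol(S))
    w <- tryCatch(solve(Sr, m1 - m0), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    ridge <- if (ridge == 0) 1e-8 * mean(diag(S)) else ridge * 10
    if (!is.finite(ridge) || ridge > 1e6 * mean(diag(S)))
      stop_input("pooled covariance could not be stabilized")
  }
  if (ridge > 0)
    message(sprintf("singular pooled covariance: ridge-stabilized with %g",
                    ridge))
  offset <- 0.5 * sum(w * (m0 + m1)) - log(n1 / n0)
  list(w = as.numeric(w), offset = offset, ridge = ridge)
}

lda_score <- function(fit, X) as.numeric(as.matrix(X) %*% fit$w - fit$offset)

#' Fusion configuration
#'
#' @param priors Character vector of prior columns of the evaluation table
#'   to fuse with the detector score, or `"all"` for every column starting
#'   with `prior_`. `character(0)` gives the score-only baseline.
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param standardize Z-standardize prior columns with training-fold
#'   statistics before fusion (score and priors live on incommensurate
#'   scales).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(priors = "all", folds = 5, seed = 1L,
                          standardize = TRUE) {
  structure(list(priors = priors, folds = as.integer(folds),
                 seed = as.integer(seed), standardize = standardize),
            class = "fusion_config")
}

resolve_priors <- function(priors, eval) {
  if (identical(priors, "all"))
    priors <- grep("^prior_", names(eval), value = TRUE)
  missing <- setdiff(priors, names(eval))
  if (length(missing))
    stop_input("evaluation table lacks prior column(s): ",
               paste(missing, collapse = ", "))
  priors
}

#' Train a cross-validated fused classifier
#'
#' Late fusion of a detector's confidence score with predicted contextual
#' priors: the feature vector per scene is the score concatenated with the
#' selected prior columns; a linear discriminant with pooled covariance is
#' fit on each training fold (priors z-standardized by training-fold
#' statistics) and evaluated out of fold. The signed discriminant value is
#' the ROC score.
#'
#' @param eval Evaluation table with columns `label` (0/1), `score`, and
#'   any prior columns. Needs at least 10 scenes per class.
#' @param config A [fusion_config()].
#' @return Object of class `fusion_result`: `accuracy_mean` (mean of
#'   fold-wise top-1 accuracies), `accuracy_sd` (sd across folds),
#'   `fold_accuracy`, `auc`, `roc` (ROC points over out-of-fold
#'   discriminant values), `scores`, `features`, `folds`, `seed`.
#' @export
train_fused_classifier <- function(eval, config = fusion_config()) {
  if (!all(c("label", "score") %in% names(eval)))
    stop_input("evaluation table needs 'label' and 'score' columns")
  if (any(is.na(eval$score))) stop_input("missing detector scores")
  y <- as.integer(eval$label)
  if (!all(y %in% c(0L, 1L))) stop_input("labels must be 0/1")
  if (sum(y == 0) < 10 || sum(y == 1) < 10)
    stop_input("need at least 10 scenes per class")
  priors <- resolve_priors(config$priors, eval)
  X <- as.matrix(cbind(score = eval$score,
                       eval[, priors, drop = FALSE]))
  n <- nrow(X)
  k <- config$folds
  folds <- with_seed(config$seed, sample(rep(seq_len(k), length.out = n)))

  oof <- numeric(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    if (config$standardize && length(priors)) {
      mu <- colMeans(Xtr[, priors, drop = FALSE])
      sg <- apply(Xtr[, priors, drop = FALSE], 2, stats::sd)
      sg[sg == 0] <- 1
      Xtr[, priors] <- sweep(sweep(Xtr[, priors, drop = FALSE], 2, mu),
                             2, sg, "/")
      Xte[, priors] <- sweep(sweep(Xte[, priors, drop = FALSE], 2, mu),
                             2, sg, "/")
    }
    fit <- lda_train(Xtr, y[tr])
    sc <- lda_score(fit, Xte)
    oof[!tr] <- sc
    fold_acc[f] <- mean((sc > 0) == (y[!tr] == 1L))
  }
  roc <- roc_curve(oof, y)
  structure(list(accuracy_mean = mean(fold_acc),
                 accuracy_sd = stats::sd(fold_acc),
                 fold_accuracy = fold_acc,
                 auc = roc$auc, roc = roc$points, scores = oof,
                 features = c("score", priors), folds = folds,
                 seed = config$seed),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "Fused classifier [%s]: accuracy %.3f +/- %.3f, AUC %.3f\n",
    paste(x$features, collapse = " + "), x$accuracy_mean, x$accuracy_sd,
    x$auc))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique score values (plus
#' infinite endpoints), recording the false- and true-positive rates; the
#' AUC is the trapezoidal area, which for tied scores equals the
#' Mann-Whitney concordance with ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more confident the
#'   target is present).
#' @param labels 0/1 presence labels; both classes must be present.
#' @return List with `points` (data.frame threshold, fpr, tpr, monotone
#'   non-decreasing in both rates) and `auc`.
#' @export
#' @examples
#' roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc  # 0.75
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_input("scores and labels must have equal length")
  if (any(is.na(scores)) || any(is.na(labels)))
    stop_input("scores and labels must be complete")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_input("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0) / n_neg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Augmentation results over a grid of prior sets
#'
#' Trains one fused classifier per prior configuration (always including
#' the score-only baseline) and tabulates cross-validated accuracy, AUC,
#' and the accuracy delta in percentage points versus the baseline.
#'
#' @param eval Evaluation table (see [train_fused_classifier()]).
#' @param prior_sets Named list of character vectors of prior columns; an
#'   entry `character(0)` (or the automatically added `"baseline"`) is the
#'   score-only model.
#' @param folds,seed,standardize Passed to [fusion_config()].
#' @return Data.frame: config, features, accuracy_mean, accuracy_sd, auc,
#'   delta_points; plus the per-config `fusion_result`s as attribute
#'   `"results"`.
#' @export
augmentation_table <- function(eval, prior_sets, folds = 5, seed = 1L,
                               standardize = TRUE) {
  if (is.null(names(prior_sets)))
    stop_input("prior_sets must be a named list")
  if (!any(vapply(prior_sets, length, 0L) == 0))
    prior_sets <- c(list(baseline = character(0)), prior_sets)
  results <- lapply(prior_sets, function(p)
    train_fused_classifier(eval, fusion_config(priors = p, folds = folds,
                                               seed = seed,
                                               standardize = standardize)))
  base_idx <- which(vapply(prior_sets, length, 0L) == 0)[1]
  base_acc <- results[[base_idx]]$accuracy_mean
  out <- data.frame(
    config = names(prior_sets),
    features = vapply(results, function(r)
      paste(r$features, collapse = "+"), ""),
    accuracy_mean = vapply(results, function(r) r$accuracy_mean, 0),
    accuracy_sd = vapply(results, function(r) r$accuracy_sd, 0),
    auc = vapply(results, function(r) r$auc, 0),
    delta_points = vapply(results, function(r)
      100 * (r$accuracy_mean - base_acc), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
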