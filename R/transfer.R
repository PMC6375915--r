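#' Association index between an object category and an anchor category
#'
#' The absolute difference between the conditional probability of the
#' object occurring when the anchor is present and its marginal
#' probability: `|p(object | anchor present) - p(object)|`, estimated by
#' counting over the presence matrix. Zero exactly when the sample
#' conditional and marginal frequencies agree.
#'
#' @param presence Binary matrix or data.frame, scenes x object categories
#'   (anchor categories included as columns).
#' @param object Column name of the object category.
#' @param anchor Column name of the anchor category (e.g. "car"); must be
#'   present in at least one scene.
#' @return Association index in `[0, 1]`.
#' @export
#' @examples
#' P <- cbind(car = c(1, 1, 0, 0), bicycle = c(1, 1, 1, 0))
#' association_index(P, "bicycle", "car")  # |1 - 0.75| = 0.25
association_index <- function(presence, object, anchor) {
  presence <- as.matrix(presence)
  for (col in c(object, anchor))
    if (!col %in% colnames(presence))
      stop_input("presence matrix has no column '", col, "'")
  a <- presence[, anchor]
  if (sum(a == 1) == 0)
    stop_input("association index undefined: anchor '", anchor,
               "' is never present")
  o <- presence[, object]
  abs(mean(o[a == 1]) - mean(o))
}

#' Per-object association indices against one or more anchors
#'
#' @inheritParams association_index
#' @param objects Object columns to score (default all non-anchor columns).
#' @param anchors Anchor columns (default intersect of car/person with the
#'   available columns).
#' @return Data.frame: object, one column per anchor, and `mean_association`
#'   across anchors.
#' @export
association_table <- function(presence, objects = NULL, anchors = NULL) {
  presence <- as.matrix(presence)
  if (is.null(anchors))
    anchors <- intersect(c("car", "person"), colnames(presence))
  if (!length(anchors)) stop_input("no anchor columns found")
  if (is.null(objects))
    objects <- setdiff(colnames(presence), anchors)
  out <- data.frame(object = objects, stringsAsFactors = FALSE)
  for (an in anchors)
    out[[paste0("association_", an)]] <-
      vapply(objects, function(ob) association_index(presence, ob, an), 0)
  out$mean_association <-
    rowMeans(out[, paste0("association_", anchors), drop = FALSE])
  out
}

#' Transfer experiment: do anchor priors help associated categories?
#'
#' For every associated object category in a synthetic evaluation set, a
#' score-only baseline classifier and a classifier fused with the anchor's
#' contextual prior are trained and cross-validated; the improvement in
#' percentage points is tabulated together with the category's association
#' index to the anchor.
#'
#' @param eval_set An [generate_eval_set()] result with associated objects.
#' @param prior Numeric vector of per-scene prior values (default the
#'   eval set's latent prior signal; typically a [predict_priors()]
#'   column).
#' @param folds,seed Cross-validation settings.
#' @return Data.frame of class `transfer_summary`: category, n_scenes,
#'   association, baseline_accuracy, augmented_accuracy,
#'   improvement_points.
#' @export
transfer_experiment <- function(eval_set, prior = NULL, folds = 5,
                                seed = 1L) {
  stopifnot(inherits(eval_set, "eval_set"))
  if (is.null(eval_set$object_scores))
    stop_input("eval set has no associated objects")
  if (is.null(prior)) prior <- eval_set$eval$prior_signal
  anchor <- eval_set$eval$category[1]
  objs <- setdiff(colnames(eval_set$presence), anchor)
  assoc <- association_table(eval_set$presence, objects = objs,
                             anchors = anchor)

  rows <- lapply(objs, function(ob) {
    df <- data.frame(label = eval_set$presence[, ob],
                     score = eval_set$object_scores[, ob],
                     prior_anchor = prior)
    base <- train_fused_classifier(df, fusion_config(
      priors = character(0), folds = folds, seed = seed))
    fused <- train_fused_classifier(df, fusion_config(
      priors = "prior_anchor", folds = folds, seed = seed))
    data.frame(category = ob,
               n_scenes = sum(df$label == 1),
               association = assoc$mean_association[assoc$object == ob],
               baseline_accuracy = base$accuracy_mean,
               augmented_accuracy = fused$accuracy_mean,
               improvement_points = 100 * (fused$accuracy_mean -
                                             base$accuracy_mean),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("transfer_summary", class(out))
  out
}

#' Correlates augmentation benefit with baseline accuracy and association
#'
#' Two Pearson correlations over categories, with two-sided p-values from
#' the t distribution of the correlation: improvement vs. baseline
#' accuracy (expected negative: weaker detectors gain more) and improvement
#' vs. mean association index (expected positive: categories coupled to the
#' anchors gain more).
#'
#' @param summary A [transfer_experiment()] result (or any data.frame with
#'   columns improvement_points, baseline_accuracy, association).
#' @return List of two lists (`vs_baseline`, `vs_association`), each with
#'   `r` and `p`; `NA` with a warning for constant columns.
#' @export
benefit_correlation <- function(summary) {
  need <- c("improvement_points", "baseline_accuracy", "association")
  missing <- setdiff(need, names(summary))
  if (length(missing))
    stop_input("summary lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(summary) < 3)
    stop_input("need at least 3 categories")
  cor_pair <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant column: correlation undefined", call. = FALSE)
      return(list(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(vs_baseline = cor_pair(summary$improvement_points,
                              summary$baseline_accuracy),
       vs_association = cor_pair(summary$improvement_points,
                                 summary$association))
}
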