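#' Aggregate subject ratings into per-scene responses
#'
#' Produces the regression responses of the expectation models: for every
#' scene x category, the mean likelihood over all raters, and the mean box
#' x, y, area and aspect over the raters who gave a non-zero likelihood
#' (only those raters placed a box). Box aggregates are `NA` when no rater
#' gave a non-zero likelihood.
#'
#' @param ratings Subject rating table as produced by
#'   [generate_subject_ratings()] (columns subject_id, scene_id, category,
#'   likelihood, box_x, box_y, box_area, box_aspect).
#' @return Data.frame with one row per scene x category: scene_id,
#'   category, likelihood, x, y, area, aspect, n_raters, n_nonzero_raters.
#' @export
aggregate_ratings <- function(ratings) {
  need <- c("subject_id", "scene_id", "category", "likelihood",
            "box_x", "box_y", "box_area", "box_aspect")
  missing <- setdiff(need, names(ratings))
  if (length(missing))
    stop_input("ratings table lacks columns: ",
               paste(missing, collapse = ", "))
  if (nrow(ratings) == 0 || any(is.na(ratings$likelihood)))
    stop_input("every scene needs at least one rater with a likelihood")
  if (any(ratings$likelihood < 0 | ratings$likelihood > 1))
    stop_input("likelihood ratings must lie in [0, 1]")
  nz <- ratings$likelihood > 0
  if (any(nz & (is.na(ratings$box_x) | is.na(ratings$box_y) |
                is.na(ratings$box_area) | is.na(ratings$box_aspect))))
    stop_input("non-zero likelihood ratings must carry a complete box")

  key <- interaction(ratings$scene_id, ratings$category, drop = TRUE,
                     lex.order = TRUE)
  first <- !duplicated(key)
  agg_mean <- function(x, subset = rep(TRUE, length(x))) {
    x2 <- ifelse(subset, x, NA_real_)
    as.numeric(tapply(x2, key, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }))
  }
  ord <- order(unique(key))  # tapply returns levels sorted
  out <- data.frame(
    scene_id = ratings$scene_id[first][order(key[first])],
    category = ratings$category[first][order(key[first])],
    likelihood = agg_mean(ratings$likelihood),
    x = agg_mean(ratings$box_x, nz),
    y = agg_mean(ratings$box_y, nz),
    area = agg_mean(ratings$box_area, nz),
    aspect = agg_mean(ratings$box_aspect, nz),
    n_raters = as.integer(tapply(ratings$likelihood, key, length)),
    n_nonzero_raters = as.integer(tapply(nz, key, sum)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Spearman-Brown correction of a split-half correlation
#'
#' Maps the reliability of half the data to the reliability of the full
#' data: `rc = 2 r / (r + 1)`. Monotone increasing and `>= r` on `[0, 1]`.
#'
#' @param r Split-half correlation(s).
#' @return Corrected correlation(s).
#' @export
#' @examples
#' spearman_brown(0.5)  # 2/3
spearman_brown <- function(r) 2 * r / (r + 1)

#' Split-half noise ceiling of the across-subject mean
#'
#' Estimates the upper bound on model-data correlation implied by
#' inter-subject variability: subjects are repeatedly split into two random
#' halves, the two groups' per-scene mean responses are correlated across
#' scenes, and the split-half correlation is Spearman-Brown corrected to
#' full-data reliability. For box responses, group means are taken over
#' the group's non-zero raters (scenes with none in a group are dropped
#' pairwise).
#'
#' @param ratings Subject rating table.
#' @param response One of "likelihood", "x", "y", "area", "aspect".
#' @param category Target category to analyse.
#' @param n_resamples Number of random halvings (default 1000).
#' @param seed Integer seed for the halvings.
#' @return List with `mean`, `sd` and the vector of corrected `samples`.
#' @export
noise_ceiling <- function(ratings, response = "likelihood", category = "car",
                          n_resamples = 1000, seed = 1L) {
  response <- match.arg(response,
                        c("likelihood", "x", "y", "area", "aspect"))
  col <- switch(response, likelihood = "likelihood", x = "box_x",
                y = "box_y", area = "box_area", aspect = "box_aspect")
  rt <- ratings[ratings$category == category, , drop = FALSE]
  if (nrow(rt) == 0) stop_input("no ratings for category ", category)
  subjects <- sort(unique(rt$subject_id))
  S <- length(subjects)
  if (S < 2)
    stop_input("noise ceiling is undefined with fewer than 2 subjects")
  scenes <- sort(unique(rt$scene_id))
  M <- matrix(NA_real_, length(scenes), S,
              dimnames = list(scenes, subjects))
  M[cbind(match(rt$scene_id, scenes), match(rt$subject_id, subjects))] <-
    rt[[col]]

  half <- S %/% 2
  samples <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    perm <- sample(S)
    m1 <- rowMeans(M[, perm[1:half], drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(M[, perm[(half + 1):S], drop = FALSE], na.rm = TRUE)
    r <- suppressWarnings(
      stats::cor(m1, m2, use = "pairwise.complete.obs"))
    spearman_brown(r)
  }, numeric(1)))
  list(mean = mean(samples, na.rm = TRUE),
       sd = stats::sd(samples, na.rm = TRUE),
       samples = samples, response = response, category = category,
       n_subjects = S, seed = as.integer(seed))
}
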