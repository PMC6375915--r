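## Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## small generator config for cheap unit tests
small_config <- function(seed = 1, ...) {
  generator_config(n_scenes = 60, n_subjects = 4, coarse_dim = 30,
                   target_dim = 15, n_factors = 5,
                   true_weights = small_weights(), seed = seed, ...)
}

small_weights <- function(n_factors = 5) {
  w <- default_true_weights(20)
  rapply(w, function(v) v[seq_len(n_factors)], how = "replace")
}

zero_weights <- function(n_factors = 20)
  rapply(default_true_weights(n_factors), function(v) v * 0,
         how = "replace")

small_scene_set <- function() memo("small_scene_set",
  generate_scene_set(small_config()))

small_ratings <- function() memo("small_ratings",
  generate_subject_ratings(small_scene_set()))

## full-scale study dataset (650 scenes, 11 subjects) shared by the
## acceptance checks
study_config <- function() generator_config(seed = 101)

study_data <- function() memo("study_data", {
  ss <- generate_scene_set(study_config())
  rt <- generate_subject_ratings(ss)
  agg <- aggregate_ratings(rt)
  a <- agg[agg$category == "car", ]
  y_car <- a$likelihood[match(rownames(ss$channels$T), a$scene_id)]
  p <- agg[agg$category == "person", ]
  y_person <- p$likelihood[match(rownames(ss$channels$T), p$scene_id)]
  list(scene_set = ss, ratings = rt, aggregates = agg,
       y_car = y_car, y_person = y_person)
})

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

## mean likelihood response aligned to a scene set's channel rows
study_response <- function(ss, category = "car") {
  agg <- aggregate_ratings(generate_subject_ratings(ss))
  a <- agg[agg$category == category, ]
  a$likelihood[match(rownames(ss$channels$T), a$scene_id)]
}

## hand-built detection records for the feature tests
make_detection <- function(scene_id = "s1", category = "car", view = 1,
                           score = -0.5, box_x = 0, box_y = 0,
                           box_width = 10, box_height = 10,
                           parts = rep(0.5, 16)) {
  df <- data.frame(scene_id = scene_id, category = category, view = view,
                   score = score, box_x = box_x, box_y = box_y,
                   box_width = box_width, box_height = box_height,
                   stringsAsFactors = FALSE)
  pm <- matrix(parts, nrow = nrow(df), ncol = 16, byrow = TRUE)
  colnames(pm) <- contextpriors:::PART_COLS
  cbind(df, pm)
}

## brute-force concordant-pair AUC (Mann-Whitney, ties counted one half)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
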