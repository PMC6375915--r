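## Target-detector summary features.
##
## A detection record is one row of a detections table with columns:
##   scene_id, category ("car"/"person"), view (1..3), score,
##   box_x, box_y, box_width, box_height (px, x/y = top-left corner),
##   part1_x, part1_y, ..., part8_x, part8_y  (part locations in the unit
##   square of the normalized detection box).

PART_COLS <- as.vector(t(outer(sprintf("part%d", 1:8), c("x", "y"),
                               paste, sep = "_")))

DETECTION_COLS <- c("scene_id", "category", "view", "score",
                    "box_x", "box_y", "box_width", "box_height", PART_COLS)

TARGET_CATEGORIES <- c("car", "person")

check_detections <- function(records) {
  missing <- setdiff(DETECTION_COLS, names(records))
  if (length(missing))
    stop_input("detections table lacks columns: ",
               paste(missing, collapse = ", "))
  if (any(!records$category %in% TARGET_CATEGORIES))
    stop_input("detection category must be one of: ",
               paste(TARGET_CATEGORIES, collapse = ", "))
  if (any(records$box_width <= 0 | records$box_height <= 0))
    stop_input("detection boxes must have positive width and height")
  if (any(is.na(as.matrix(records[PART_COLS]))))
    stop_input("malformed part offsets: missing values in part columns")
  invisible(records)
}

#' Read a detections table from CSV
#'
#' @param path Path to a CSV file with the detection-record columns
#'   (scene_id, category, view, score, box geometry, and eight part
#'   locations in unit-square coordinates).
#' @return A validated data.frame of detection records.
#' @export
read_detections <- function(path) {
  check_detections(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Dataset-wide mean part locations
#'
#' First pass of the part-deformation computation: the mean location of each
#' of the eight detected parts (in unit-square coordinates of the normalized
#' detection box) over all detections of each category in the dataset.
#'
#' @param records Detections table (all scenes).
#' @return Named list with one 8 x 2 matrix per category (columns x, y);
#'   categories with no detections default to the box center (0.5, 0.5).
#' @export
detection_part_means <- function(records) {
  check_detections(records)
  out <- list()
  for (cat in TARGET_CATEGORIES) {
    rc <- records[records$category == cat, , drop = FALSE]
    m <- matrix(0.5, 8, 2, dimnames = list(sprintf("part%d", 1:8),
                                           c("x", "y")))
    if (nrow(rc)) {
      pm <- colMeans(as.matrix(rc[PART_COLS]))
      m[, "x"] <- pm[seq(1, 16, by = 2)]
      m[, "y"] <- pm[seq(2, 16, by = 2)]
    }
    out[[cat]] <- m
  }
  out
}

## names of the 31 per-category summary statistics
summary_names_one <- function() {
  c("n_strong", "false_alarms", "mean_area",
    as.vector(t(outer(sprintf("deform_p%d", 1:8), c("dx", "dy"),
                      paste, sep = "_"))),
    sprintf("ecc_%d", 1:5),
    as.vector(outer(1:3, TARGET_CATEGORIES,
                    function(v, c) sprintf("view_%s_%d", c, v))),
    "mean_score")
}

#' Summarize a scene's detection records into the 62-dim target feature
#' vector
#'
#' Computes, separately for car and person and then concatenated
#' (31 + 31 = 62 values), the detection-summary statistics:
#' \itemize{
#'   \item `n_strong`: detections above the tight threshold (default -0.7,
#'     very few false alarms);
#'   \item `false_alarms`: detections between the weak (default -1.2) and
#'     tight thresholds, i.e. `n_weak - n_strong`;
#'   \item `mean_area`: mean box area (px^2) over strong detections;
#'   \item 16 part-deformation statistics: per-part mean (dx, dy)
#'     displacement of the detected part from its dataset-wide mean location
#'     (unit-square coordinates), averaged over the scene's detections;
#'   \item a 5-bin eccentricity histogram of box centers (equal-width annuli
#'     from the scene center out to half the frame diagonal);
#'   \item frequencies of the six detector models (2 categories x 3 views);
#'   \item `mean_score`: mean detector score over all (weak) detections.
#' }
#' Empty statistics default to 0, so a scene without detections for a
#' category yields an all-zero 31-vector for that category.
#'
#' @param records Detection records for one scene (possibly zero rows).
#' @param part_means Dataset-wide part means from [detection_part_means()];
#'   if `NULL`, computed from `records` alone (single-scene fallback).
#' @param strong_threshold,weak_threshold Score thresholds; strong must
#'   exceed weak.
#' @param frame Frame size `c(width, height)` in pixels.
#' @return Named numeric vector of length 62 (car block then person block).
#' @export
summarize_detections <- function(records, part_means = NULL,
                                 strong_threshold = -0.7,
                                 weak_threshold = -1.2,
                                 frame = c(width = 640, height = 480)) {
  if (strong_threshold <= weak_threshold)
    stop_input("strong_threshold must exceed weak_threshold")
  if (nrow(records) == 0 && is.null(part_means)) {
    out <- numeric(62)
    names(out) <- paste(rep(TARGET_CATEGORIES, each = 31),
                        rep(summary_names_one(), 2), sep = "_")
    return(out)
  }
  check_detections(records)
  if (is.null(part_means)) part_means <- detection_part_means(records)

  cx0 <- frame[[1]] / 2; cy0 <- frame[[2]] / 2
  r_out <- sqrt(frame[[1]]^2 + frame[[2]]^2) / 2

  blocks <- lapply(TARGET_CATEGORIES, function(cat) {
    rc <- records[records$category == cat, , drop = FALSE]
    v <- stats::setNames(numeric(31), summary_names_one())
    if (nrow(rc)) {
      strong <- rc$score > strong_threshold
      n_weak <- sum(rc$score > weak_threshold)
      v["n_strong"] <- sum(strong)
      v["false_alarms"] <- n_weak - sum(strong)
      if (any(strong))
        v["mean_area"] <- mean(rc$box_width[strong] * rc$box_height[strong])
      ## part deformation: scene-mean displacement from dataset means
      P <- as.matrix(rc[PART_COLS])
      ref <- as.vector(t(part_means[[cat]]))  # x1,y1,...,x8,y8 interleaved
      v[4:19] <- colMeans(P) - ref
      ## eccentricity histogram over box centers
      cx <- rc$box_x + rc$box_width / 2
      cy <- rc$box_y + rc$box_height / 2
      d <- sqrt((cx - cx0)^2 + (cy - cy0)^2)
      bin <- pmin(5L, pmax(1L, ceiling(d / (r_out / 5))))
      bin[d == 0] <- 1L
      v[20:24] <- tabulate(bin, 5L)
      ## model-type (category x view) frequencies
      for (ci in seq_along(TARGET_CATEGORIES))
        for (vw in 1:3)
          v[24 + (ci - 1) * 3 + vw] <-
            sum(rc$category == TARGET_CATEGORIES[ci] & rc$view == vw)
      v["mean_score"] <- mean(rc$score)
    }
    v
  })
  out <- c(blocks[[1]], blocks[[2]])
  names(out) <- paste(rep(TARGET_CATEGORIES, each = 31),
                      rep(summary_names_one(), 2), sep = "_")
  out
}

#' Build the T feature channel from a detections table
#'
#' Two-pass construction: dataset-wide mean part locations first, then one
#' 62-dim summary per scene. Scenes without detections get all-zero rows.
#'
#' @param records Detections table covering any subset of the scenes.
#' @param scene_ids Character vector of all scene ids (row order of the
#'   resulting channel).
#' @inheritParams summarize_detections
#' @return Numeric matrix scenes x 62 with rownames `scene_ids`.
#' @export
build_target_channel <- function(records, scene_ids,
                                 strong_threshold = -0.7,
                                 weak_threshold = -1.2,
                                 frame = c(width = 640, height = 480)) {
  check_detections(records)
  unknown <- setdiff(unique(records$scene_id), scene_ids)
  if (length(unknown))
    stop_input("detections reference unknown scenes: ",
               paste(utils::head(unknown, 3), collapse = ", "))
  pm <- detection_part_means(records)
  rows <- lapply(scene_ids, function(sid)
    summarize_detections(records[records$scene_id == sid, , drop = FALSE],
                         part_means = pm,
                         strong_threshold = strong_threshold,
                         weak_threshold = weak_threshold, frame = frame))
  out <- do.call(rbind, rows)
  rownames(out) <- scene_ids
  out
}
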