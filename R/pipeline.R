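## End-to-end orchestration: file-based stage handoff inside a run
## directory, with a manifest recording the configuration hash, per-stage
## seeds and output checksums.

RESPONSES <- c("likelihood", "x", "y", "area", "aspect")

stage_simulate <- function(cfg, dir, seeds) {
  gen <- generator_config(n_scenes = cfg$simulate.n_scenes,
                          n_subjects = cfg$simulate.n_subjects,
                          seed = seeds[["simulate"]])
  ss <- generate_scene_set(gen)
  ratings <- generate_subject_ratings(ss)
  write_pipeline_csv(ratings, file.path(dir, "ratings.csv"))
  for (ch in c("T", "N", "C"))
    write_channel_csv(ss$channels[[ch]],
                      file.path(dir, sprintf("channels_%s.csv", ch)))
  write_json_atomic(truth_to_list(ss$truth), file.path(dir, "truth.json"))
  invisible(NULL)
}

stage_aggregate <- function(cfg, dir, seeds) {
  ratings <- utils::read.csv(require_artifact(dir, "ratings.csv",
                                              "simulate"),
                             stringsAsFactors = FALSE)
  write_pipeline_csv(aggregate_ratings(ratings),
                     file.path(dir, "aggregates.csv"))
  invisible(NULL)
}

read_pipeline_channels <- function(dir, stage_needed = "simulate") {
  lapply(stats::setNames(c("T", "N", "C"), c("T", "N", "C")), function(ch)
    read_channel_csv(require_artifact(dir, sprintf("channels_%s.csv", ch),
                                      stage_needed)))
}

## response vector for one category, aligned to the channel row order
response_vector <- function(agg, channels, category, response) {
  a <- agg[agg$category == category, , drop = FALSE]
  a[[response]][match(rownames(channels$T), a$scene_id)]
}

stage_fit <- function(cfg, dir, seeds) {
  channels <- read_pipeline_channels(dir)
  agg <- utils::read.csv(require_artifact(dir, "aggregates.csv",
                                          "aggregate"),
                         stringsAsFactors = FALSE)
  models <- list()
  fits <- list()
  i <- 0
  for (cat in c("car", "person")) {
    for (resp in RESPONSES) {
      y <- response_vector(agg, channels, cat, resp)
      for (sub in c("NC", "C")) {
        m <- fit_expectation_model(channels, y, subset = sub,
                                   pca_k = cfg$fit.pca_k,
                                   response = resp, category = cat,
                                   scene_ids = rownames(channels$T))
        models[[sprintf("%s_%s_%s", cat, resp, sub)]] <- m
        cv <- crossval_correlation(channels, y, k = cfg$fit.crossval_k,
                                   seed = seeds[["fit"]], subset = sub,
                                   pca_k = cfg$fit.pca_k,
                                   pca_refit = cfg$fit.pca_refit)
        i <- i + 1
        fits[[i]] <- data.frame(category = cat, response = resp,
                                subset = sub, cv_r = cv$r,
                                n_scenes = sum(!is.na(y)),
                                stringsAsFactors = FALSE)
      }
    }
  }
  write_models(models, file.path(dir, "models.json"))
  write_pipeline_csv(do.call(rbind, fits), file.path(dir, "fits.csv"))
  nw <- nontarget_weight_correlation(models$car_likelihood_NC,
                                     models$person_likelihood_NC)
  write_pipeline_csv(
    data.frame(measure = "nontarget_weight_correlation", r = nw$r),
    file.path(dir, "weight_correlation.csv"))
  invisible(NULL)
}

stage_compare <- function(cfg, dir, seeds) {
  channels <- read_pipeline_channels(dir)
  agg <- utils::read.csv(require_artifact(dir, "aggregates.csv",
                                          "aggregate"),
                         stringsAsFactors = FALSE)
  tabs <- lapply(seq_along(c("car", "person")), function(i) {
    cat <- c("car", "person")[i]
    y <- response_vector(agg, channels, cat, "likelihood")
    cmp <- compare_models(channels, y, n_splits = cfg$compare.n_splits,
                          train_frac = cfg$compare.train_frac,
                          seed = seeds[["compare"]] + i - 1L,
                          pca_k = cfg$fit.pca_k,
                          pca_refit = cfg$compare.pca_refit)
    cbind(category = cat, cmp$table, stringsAsFactors = FALSE)
  })
  write_pipeline_csv(do.call(rbind, tabs),
                     file.path(dir, "comparison_table.csv"))
  invisible(NULL)
}

stage_ceiling <- function(cfg, dir, seeds) {
  ratings <- utils::read.csv(require_artifact(dir, "ratings.csv",
                                              "simulate"),
                             stringsAsFactors = FALSE)
  rows <- list(); i <- 0
  for (cat in c("car", "person"))
    for (resp in RESPONSES) {
      nc <- noise_ceiling(ratings, response = resp, category = cat,
                          n_resamples = cfg$ceiling.n_resamples,
                          seed = seeds[["ceiling"]])
      i <- i + 1
      rows[[i]] <- data.frame(category = cat, response = resp,
                              ceiling_mean = nc$mean, ceiling_sd = nc$sd,
                              stringsAsFactors = FALSE)
    }
  write_pipeline_csv(do.call(rbind, rows), file.path(dir, "ceiling.csv"))
  invisible(NULL)
}

## thin an ROC to at most `max_points` rows for the CSV export
thin_roc <- function(points, max_points = 200) {
  n <- nrow(points)
  if (n <= max_points) return(points)
  points[unique(round(seq(1, n, length.out = max_points))), , drop = FALSE]
}

stage_fuse <- function(cfg, dir, seeds) {
  truth <- truth_from_list(
    jsonlite::read_json(require_artifact(dir, "truth.json", "simulate"),
                        simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = TRUE))
  models <- read_models(require_artifact(dir, "models.json", "fit"))
  fusion_rows <- list(); roc_rows <- list()
  for (i in seq_along(c("car", "person"))) {
    cat <- c("car", "person")[i]
    ecfg <- eval_config(n_pos = cfg$fuse.n_pos, n_neg = cfg$fuse.n_neg,
                        seed = seeds[["fuse"]] + i - 1L)
    es <- generate_eval_set(ecfg, truth = truth, category = cat)
    prior_models <- stats::setNames(
      lapply(RESPONSES, function(r) models[[sprintf("%s_%s_C", cat, r)]]),
      RESPONSES)
    priors <- predict_priors(prior_models, es$eval)
    eval_aug <- cbind(es$eval[c("scene_id", "category", "label", "score",
                                "prior_signal")], priors)
    sets <- list(lklhd = "prior_likelihood",
                 ylocn = "prior_y",
                 scale = "prior_area",
                 lklhd_ylocn_scale = c("prior_likelihood", "prior_y",
                                       "prior_area"),
                 all = paste0("prior_", RESPONSES))
    tab <- augmentation_table(eval_aug, sets, folds = cfg$fuse.folds,
                              seed = seeds[["fuse"]] + 10L + i)
    fusion_rows[[i]] <- cbind(category = cat, tab, stringsAsFactors = FALSE)
    res <- attr(tab, "results")
    for (cfg_name in c("baseline", "all")) {
      rp <- thin_roc(res[[cfg_name]]$roc)
      roc_rows[[length(roc_rows) + 1]] <-
        cbind(category = cat, config = cfg_name, rp,
              stringsAsFactors = FALSE)
    }
    write_pipeline_csv(eval_aug, file.path(dir,
                                           sprintf("eval_%s.csv", cat)))
    write_pipeline_csv(as.data.frame(es$presence),
                       file.path(dir, sprintf("presence_%s.csv", cat)))
    write_pipeline_csv(as.data.frame(es$object_scores),
                       file.path(dir, sprintf("object_scores_%s.csv", cat)))
  }
  write_pipeline_csv(do.call(rbind, fusion_rows),
                     file.path(dir, "fusion_results.csv"))
  write_pipeline_csv(do.call(rbind, roc_rows),
                     file.path(dir, "roc_points.csv"))
  invisible(NULL)
}

stage_transfer <- function(cfg, dir, seeds) {
  sums <- list(); cors <- list()
  for (i in seq_along(c("car", "person"))) {
    cat <- c("car", "person")[i]
    eval_aug <- utils::read.csv(
      require_artifact(dir, sprintf("eval_%s.csv", cat), "fuse"),
      stringsAsFactors = FALSE)
    presence <- as.matrix(utils::read.csv(
      require_artifact(dir, sprintf("presence_%s.csv", cat), "fuse"),
      check.names = FALSE))
    oscores <- as.matrix(utils::read.csv(
      require_artifact(dir, sprintf("object_scores_%s.csv", cat), "fuse"),
      check.names = FALSE))
    es <- structure(list(eval = eval_aug, presence = presence,
                         object_scores = oscores), class = "eval_set")
    ts <- transfer_experiment(es, prior = eval_aug$prior_likelihood,
                              folds = cfg$transfer.folds,
                              seed = seeds[["transfer"]] + i - 1L)
    bc <- benefit_correlation(ts)
    sums[[i]] <- cbind(anchor = cat, as.data.frame(ts),
                       stringsAsFactors = FALSE)
    cors[[i]] <- data.frame(anchor = cat,
                            r_vs_baseline = bc$vs_baseline$r,
                            p_vs_baseline = bc$vs_baseline$p,
                            r_vs_association = bc$vs_association$r,
                            p_vs_association = bc$vs_association$p,
                            stringsAsFactors = FALSE)
  }
  write_pipeline_csv(do.call(rbind, sums),
                     file.path(dir, "transfer_summary.csv"))
  write_pipeline_csv(do.call(rbind, cors),
                     file.path(dir, "transfer_correlations.csv"))
  invisible(NULL)
}

stage_report <- function(cfg, dir, seeds) {
  lines <- report(dir, write = FALSE)
  tmp <- file.path(dir, "report.txt.tmp")
  writeLines(lines, tmp)
  file.rename(tmp, file.path(dir, "report.txt"))
  invisible(NULL)
}

STAGE_OUTPUTS <- list(
  simulate = c("ratings.csv", "channels_T.csv", "channels_N.csv",
               "channels_C.csv", "truth.json"),
  aggregate = "aggregates.csv",
  fit = c("models.json", "fits.csv", "weight_correlation.csv"),
  compare = "comparison_table.csv",
  ceiling = "ceiling.csv",
  fuse = c("fusion_results.csv", "roc_points.csv",
           "eval_car.csv", "eval_person.csv",
           "presence_car.csv", "presence_person.csv",
           "object_scores_car.csv", "object_scores_person.csv"),
  transfer = c("transfer_summary.csv", "transfer_correlations.csv"),
  report = "report.txt")

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order (simulate, aggregate,
#' fit, compare, ceiling, fuse, transfer, report), handing data between
#' stages through files in `out_dir`. A stage whose upstream outputs are
#' missing fails with an error naming the stage to run first. After the
#' stages complete, `manifest.json` records the flattened configuration,
#' its MD5 hash, the per-stage seeds derived from the master seed, and MD5
#' checksums of every output file; identical configurations produce
#' identical manifests.
#'
#' @param config A [default_run_config()] / [read_run_config()] result.
#' @param out_dir Run directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @param force Overwrite existing stage outputs (atomically). Without it,
#'   rerunning a stage whose outputs exist is an error.
#' @param verbose Log one timestamped line per stage (console only).
#' @return Invisibly, a list with `dir` and the `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("contextpriors_run_"),
                         stages = "all", force = FALSE, verbose = TRUE) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- pipeline_seeds(config)

  for (st in stages) {
    existing <- file.path(out_dir, STAGE_OUTPUTS[[st]])
    existing <- existing[file.exists(existing)]
    if (length(existing) && !force)
      stop_input("outputs of stage '", st,
                 "' already exist; use force = TRUE to overwrite")
    if (verbose)
      message(sprintf("[%s] stage %s (seed %s)",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"), st,
                      if (st %in% names(seeds)) seeds[[st]] else "-"))
    switch(st,
           simulate = stage_simulate(config, out_dir, seeds),
           aggregate = stage_aggregate(config, out_dir, seeds),
           fit = stage_fit(config, out_dir, seeds),
           compare = stage_compare(config, out_dir, seeds),
           ceiling = stage_ceiling(config, out_dir, seeds),
           fuse = stage_fuse(config, out_dir, seeds),
           transfer = stage_transfer(config, out_dir, seeds),
           report = stage_report(config, out_dir, seeds))
  }

  files <- sort(unlist(STAGE_OUTPUTS, use.names = FALSE))
  files <- files[file.exists(file.path(out_dir, files))]
  checksums <- vapply(files, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), "")
  manifest <- list(config = config[order(names(config))],
                   config_md5 = md5_of_string(
                     config_canonical_string(config)),
                   seeds = as.list(seeds),
                   files = as.list(checksums))
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(dir = out_dir, manifest = manifest))
}
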