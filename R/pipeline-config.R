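PIPELINE_STAGES <- c("simulate", "aggregate", "fit", "compare", "ceiling",
                     "fuse", "transfer", "report")

#' Default pipeline configuration
#'
#' A flat named list of stage-prefixed parameters driving [run_pipeline()].
#' One master `seed` expands deterministically into per-stage seeds. The
#' defaults reproduce the study conditions end to end: 650 scenes, 11
#' subjects, 20-component channel PCAs, 1000 x 80-20 split model
#' comparison, 1000 split-half resamples for the ceilings, and
#' 3000-per-class evaluation sets for the fusion experiments.
#'
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate.n_scenes = 650L,
    simulate.n_subjects = 11L,
    fit.pca_k = 20L,
    fit.crossval_k = 5L,
    fit.pca_refit = TRUE,
    compare.n_splits = 1000L,
    compare.train_frac = 0.8,
    compare.pca_refit = FALSE,
    ceiling.n_resamples = 1000L,
    fuse.n_pos = 3000L,
    fuse.n_neg = 3000L,
    fuse.folds = 5L,
    transfer.folds = 5L), class = "run_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines of the form `key = value` (stage-prefixed keys, `#` comments
#' allowed); unspecified keys keep their [default_run_config()] values.
#'
#' @param path Path to the configuration file.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_input("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- if (tolower(val) %in% c("true", "false"))
      as.logical(toupper(val)) else
        suppressWarnings(as.numeric(val))
    if (is.na(parsed) && !is.logical(parsed)) parsed <- val
    if (is.numeric(parsed) && parsed == round(parsed) &&
        abs(parsed) < 2^31) parsed <- as.integer(parsed)
    cfg[[key]] <- parsed
  }
  cfg
}

#' Write a pipeline configuration to a flat key = value file
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste(k, "=", format(config[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

config_canonical_string <- function(config) {
  keys <- sort(names(config))
  paste(vapply(keys, function(k) paste0(k, "=", format(config[[k]])), ""),
        collapse = "\n")
}

pipeline_seeds <- function(config)
  derive_seeds(config$seed, setdiff(PIPELINE_STAGES, "report"))
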