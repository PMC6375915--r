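#' Render a human-readable summary of a pipeline run
#'
#' A pure function of the run directory's CSV outputs: re-rendering the
#' same directory is byte-identical. Produces the channel-subset model
#' comparison (with noise ceilings), the augmentation accuracy table, and
#' the transfer summary. Missing sections yield a partial report with
#' warnings; an empty run directory is an error.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @param write Also write `report.txt` into the run directory.
#' @return Character vector of report lines, invisibly; printed to the
#'   console when interactive.
#' @export
report <- function(run_dir, write = FALSE) {
  known <- unlist(STAGE_OUTPUTS, use.names = FALSE)
  if (!dir.exists(run_dir) ||
      !any(file.exists(file.path(run_dir, known))))
    stop_input("no pipeline outputs found in ", run_dir)

  lines <- c("contextpriors pipeline report",
             "=============================", "")
  grab <- function(f) {
    path <- file.path(run_dir, f)
    if (!file.exists(path)) {
      warning("missing ", f, "; partial report", call. = FALSE)
      return(NULL)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }

  cmp <- grab("comparison_table.csv")
  ceil <- grab("ceiling.csv")
  if (!is.null(cmp)) {
    lines <- c(lines, "Model comparison (test correlation over splits)",
               "-----------------------------------------------")
    for (cat in unique(cmp$category)) {
      lines <- c(lines, sprintf("%s likelihood:", cat))
      if (!is.null(ceil)) {
        cl <- ceil[ceil$category == cat & ceil$response == "likelihood", ]
        if (nrow(cl))
          lines <- c(lines, sprintf("  Ceil %5.2f +/- %4.2f",
                                    cl$ceiling_mean, cl$ceiling_sd))
      }
      cc <- cmp[cmp$category == cat, ]
      for (j in seq_len(nrow(cc)))
        lines <- c(lines, sprintf(
          "  %-4s %5.2f +/- %4.2f  %s", cc$subset[j], cc$mean_r[j],
          cc$sd_r[j],
          if (isTRUE(cc$reference[j]) || cc$reference[j] == "TRUE")
            "(reference)" else
            sprintf("exceedance %.3f", cc$exceedance_fraction[j])))
      lines <- c(lines, "")
    }
  }

  fits <- grab("fits.csv")
  if (!is.null(fits)) {
    lines <- c(lines, "Cross-validated model performance (NC subset)",
               "----------------------------------------------")
    nc <- fits[fits$subset == "NC", ]
    for (j in seq_len(nrow(nc)))
      lines <- c(lines, sprintf("  %-6s %-10s r = %5.2f (n = %d)",
                                nc$category[j], nc$response[j], nc$cv_r[j],
                                nc$n_scenes[j]))
    lines <- c(lines, "")
  }

  fus <- grab("fusion_results.csv")
  if (!is.null(fus)) {
    lines <- c(lines, "Detector augmentation (cross-validated accuracy)",
               "------------------------------------------------")
    for (cat in unique(fus$category)) {
      lines <- c(lines, sprintf("%s:", cat))
      fc <- fus[fus$category == cat, ]
      for (j in seq_len(nrow(fc)))
        lines <- c(lines, sprintf(
          "  %-18s acc %.3f +/- %.3f  AUC %.3f  delta %+5.2f pts",
          fc$config[j], fc$accuracy_mean[j], fc$accuracy_sd[j], fc$auc[j],
          fc$delta_points[j]))
      lines <- c(lines, "")
    }
  }

  ts <- grab("transfer_summary.csv")
  tc <- grab("transfer_correlations.csv")
  if (!is.null(ts)) {
    lines <- c(lines, "Transfer to associated categories",
               "---------------------------------")
    for (an in unique(ts$anchor)) {
      lines <- c(lines, sprintf("anchor %s:", an))
      ta <- ts[ts$anchor == an, ]
      for (j in seq_len(nrow(ta)))
        lines <- c(lines, sprintf(
          "  %-10s assoc %.3f  base %.3f -> fused %.3f  (%+5.2f pts)",
          ta$category[j], ta$association[j], ta$baseline_accuracy[j],
          ta$augmented_accuracy[j], ta$improvement_points[j]))
      if (!is.null(tc)) {
        ca <- tc[tc$anchor == an, ]
        if (nrow(ca))
          lines <- c(lines, sprintf(
            "  benefit vs baseline r = %+.2f (p = %.2g); vs association r = %+.2f (p = %.2g)",
            ca$r_vs_baseline, ca$p_vs_baseline, ca$r_vs_association,
            ca$p_vs_association))
      }
      lines <- c(lines, "")
    }
  }

  if (write) {
    tmp <- file.path(run_dir, "report.txt.tmp")
    writeLines(lines, tmp)
    file.rename(tmp, file.path(run_dir, "report.txt"))
  }
  if (interactive()) cat(lines, sep = "\n")
  invisible(lines)
}
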