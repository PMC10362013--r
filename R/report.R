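#' Per-sample share of CTC groups
#'
#' Fraction of each sample's classified rare events falling in the given
#' CTC-designated channel groups (e.g. `CK` alone, or `c("CK", "CK|EpCAM")`
#' for the EpCAM assay).
#'
#' @param enumeration Table from [enumerate_cells()].
#' @param ctc_groups Character vector of group names counted as CTCs.
#' @return Data frame: `sample_id`, `cohort`, `ctc_count`, `total_count`,
#'   `share` (fraction in \[0, 1\]).
#' @export
ctc_share <- function(enumeration, ctc_groups = "CK") {
  by_sample <- split(enumeration, enumeration$sample_id)
  out <- do.call(rbind, lapply(by_sample, function(s) {
    tot <- sum(s$count)
    ctc <- sum(s$count[s$group %in% ctc_groups])
    data.frame(sample_id = s$sample_id[1], cohort = s$cohort[1],
               ctc_count = ctc, total_count = tot,
               share = if (tot > 0) ctc / tot else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id), ]
}

#' Cohort summary report
#'
#' Aggregates the pipeline's outputs into one report: per-cohort,
#' per-group mean and range of the per-mL rates; the fraction of patients
#' whose CK CTC share of total rare events exceeds 50% (whole-percent,
#' rounded half up); clonal fractions per channel group; and the
#' stratifier's confusion matrix. Cohort fractions are reported at whole
#' percent and cell shares at one decimal, matching the conventional
#' printed precision of enumeration reports. Empty inputs give an empty
#' report rather than an error.
#'
#' @param enumeration [enumerate_cells()] output (or `NULL`).
#' @param meta Sample metadata.
#' @param clonality Optional [call_clonality()] result.
#' @param cell_groups Optional `cell_id`-to-`group` map for clonal
#'   fractions.
#' @param stratifier Optional `stratifier_result`.
#' @param ctc_groups Groups counted as CTCs for the share summary.
#' @return List of class `cohort_report`.
#' @export
summarize_cohort <- function(enumeration = NULL, meta = NULL,
                             clonality = NULL, cell_groups = NULL,
                             stratifier = NULL, ctc_groups = "CK") {
  report <- list()
  if (!is.null(enumeration) && nrow(enumeration)) {
    stats_by <- do.call(rbind, lapply(
      split(enumeration, list(enumeration$cohort, enumeration$group),
            drop = TRUE),
      function(s) data.frame(
        cohort = s$cohort[1], group = s$group[1],
        mean_cells_per_ml = mean(s$cells_per_ml),
        min_cells_per_ml = min(s$cells_per_ml),
        max_cells_per_ml = max(s$cells_per_ml),
        stringsAsFactors = FALSE)))
    rownames(stats_by) <- NULL
    report$group_rates <- stats_by

    shares <- ctc_share(enumeration, ctc_groups)
    report$ctc_share <- transform(
      shares, share_pct = round_half_up(100 * share, 1))
    sclc_shares <- shares[shares$cohort == "SCLC", , drop = FALSE]
    if (nrow(sclc_shares)) {
      n_over <- sum(sclc_shares$share > 0.5)
      report$pct_patients_ctc_over_half <-
        round_half_up(100 * n_over / nrow(sclc_shares))
      report$n_patients_ctc_over_half <- n_over
    }
  }
  if (!is.null(clonality) && !is.null(cell_groups)) {
    report$clonal_fractions <- clonal_fraction_by_group(clonality, cell_groups)
  }
  if (!is.null(stratifier)) {
    report$confusion <- as.data.frame(stratifier$confusion)
    report$oob_accuracy_pct <- round_half_up(100 * stratifier$oob_accuracy)
    report$chosen_k <- stratifier$chosen_k
    report$chosen_m <- stratifier$chosen_m
  }
  structure(report, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report\n")
  if (!is.null(x$pct_patients_ctc_over_half)) {
    cat(sprintf("  patients with CTC share > 50%%: %d (%.0f%%)\n",
                x$n_patients_ctc_over_half, x$pct_patients_ctc_over_half))
  }
  if (!is.null(x$oob_accuracy_pct)) {
    cat(sprintf("  stratifier OOB accuracy: %.0f%% (k = %d, pruned to %d)\n",
                x$oob_accuracy_pct, x$chosen_k, x$chosen_m))
  }
  if (!is.null(x$clonal_fractions)) {
    cat("  clonal fractions by group:\n")
    print(x$clonal_fractions)
  }
  invisible(x)
}
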