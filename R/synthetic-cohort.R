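#' Default per-group rare-cell abundance calibration
#'
#' Mean circulating rare-cell rates (cells per mL of blood-equivalent) for
#' each Landscape channel group in the SCLC and normal-donor (ND) cohorts.
#' The CK CTC means (411.19 vs 0.35 cells/mL) and CK|Vim means (23.82 vs
#' 1.03 cells/mL) are the published cohort means; the remaining six groups
#' are calibrated so the cohort totals match the published overall rare-cell
#' rates (602.39 cells/mL for SCLC, 65.67 cells/mL for ND), apportioned to
#' reflect that donor backgrounds are dominated by (CD45/CD31), Vim and
#' DAPI-only events while SCLC adds epithelial and mixed-phenotype cells.
#' Per-sample rates are drawn lognormally around these means with a common
#' log-scale standard deviation.
#'
#' @param log_sd Log-scale standard deviation of the per-sample lognormal
#'   rate distribution (same for every group).
#' @return A data frame with columns `cohort`, `group`, `mean_cells_per_ml`,
#'   `log_sd`.
#' @export
default_group_abundance <- function(log_sd = 1.2) {
  check_scalar(log_sd, "log_sd", positive = TRUE)
  groups <- assay_groups("landscape")
  sclc <- c("CK" = 411.19, "CK|Vim" = 23.82, "CK|(CD45/CD31)" = 15,
            "CK|Vim|(CD45/CD31)" = 12, "Vim" = 45, "Vim|(CD45/CD31)" = 25,
            "(CD45/CD31)" = 40, "DAPI" = 30.38)
  nd <- c("CK" = 0.35, "CK|Vim" = 1.03, "CK|(CD45/CD31)" = 0.8,
          "CK|Vim|(CD45/CD31)" = 0.5, "Vim" = 12, "Vim|(CD45/CD31)" = 8,
          "(CD45/CD31)" = 25, "DAPI" = 17.99)
  data.frame(
    cohort = rep(c("SCLC", "ND"), each = length(groups)),
    group = rep(groups, 2),
    mean_cells_per_ml = c(sclc[groups], nd[groups]),
    log_sd = log_sd,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Morphometric feature names
#'
#' Feature vectors are organised in per-channel blocks whose names are
#' prefixed by the channel they were measured on (`CK.`, `Vim.`,
#' `CD45CD31.`, `DAPI.`), so that the channel attribution of model
#' importances can be read off the feature name.
#'
#' @param n Total number of morphometric features (split evenly over the
#'   four channels).
#' @return Character vector of feature names.
#' @export
morpho_feature_names <- function(n = 56L) {
  n <- as.integer(n)
  stopifnot(n >= 4L, n %% 4L == 0L)
  per <- n %/% 4L
  prefixes <- c("CK", "Vim", "CD45CD31", "DAPI")
  unlist(lapply(prefixes, function(p) sprintf("%s.f%02d", p, seq_len(per))),
         use.names = FALSE)
}

#' Specify a synthetic rare-cell cohort
#'
#' Bundles the parameters of the synthetic cohort generator: cohort sizes,
#' blood-equivalent volume per test, nucleated cells imaged per slide, and
#' the per-group abundance calibration.
#'
#' @param n_sclc,n_nd Number of SCLC patients and normal donors.
#' @param volume_ml Blood-equivalent volume per test, in mL.
#' @param slide_cell_total_mean Named vector (`SCLC`, `ND`) of mean nucleated
#'   cells imaged per slide; two slides make one test.
#' @param group_abundance Abundance table as returned by
#'   [default_group_abundance()].
#' @param morpho_dim Number of morphometric features per event.
#' @param group_shift Morphometric shift (in SD units) applied to the feature
#'   block of each marker a group is positive for; this is what makes the
#'   eight groups morphologically separable.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sclc = 14L, n_nd = 10L, volume_ml = 1.0,
                        slide_cell_total_mean = c(SCLC = 2304659, ND = 2116477),
                        group_abundance = default_group_abundance(),
                        morpho_dim = 56L, group_shift = 2.5, seed = 1L) {
  check_scalar(n_sclc, "n_sclc", nonneg = TRUE)
  check_scalar(n_nd, "n_nd", nonneg = TRUE)
  check_scalar(volume_ml, "volume_ml", positive = TRUE)
  check_scalar(group_shift, "group_shift")
  check_scalar(seed, "seed")
  if (!all(c("SCLC", "ND") %in% names(slide_cell_total_mean))) {
    stop("`slide_cell_total_mean` needs entries for SCLC and ND")
  }
  stopifnot(is.data.frame(group_abundance),
            all(c("cohort", "group", "mean_cells_per_ml", "log_sd") %in%
                  names(group_abundance)))
  if (!all(is.finite(group_abundance$mean_cells_per_ml)) ||
      any(group_abundance$mean_cells_per_ml < 0) ||
      !all(is.finite(group_abundance$log_sd)) ||
      any(group_abundance$log_sd <= 0)) {
    stop("group_abundance means must be finite and >= 0, log_sd finite and > 0")
  }
  need <- expand.grid(cohort = c("SCLC", "ND"), group = assay_groups("landscape"),
                      stringsAsFactors = FALSE)
  have <- paste(group_abundance$cohort, group_abundance$group)
  if (!all(paste(need$cohort, need$group) %in% have)) {
    stop("group_abundance must cover every Landscape group for both cohorts")
  }
  structure(list(n_sclc = as.integer(n_sclc), n_nd = as.integer(n_nd),
                 volume_ml = volume_ml,
                 slide_cell_total_mean = slide_cell_total_mean,
                 group_abundance = group_abundance,
                 morpho_dim = as.integer(morpho_dim),
                 group_shift = group_shift,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw per-sample rare-cell rates for one channel group
#'
#' Samples per-mL rates from the lognormal abundance model of one (cohort,
#' group) cell. The lognormal is parameterised so its population mean equals
#' the configured group mean: `mu = log(mean) - log_sd^2 / 2`.
#'
#' @param n Number of draws.
#' @param mean_cells_per_ml Target population mean rate.
#' @param log_sd Log-scale standard deviation.
#' @return Numeric vector of rates (cells/mL); all zero when the mean is 0.
#' @export
draw_group_rates <- function(n, mean_cells_per_ml, log_sd = 1.2) {
  check_scalar(mean_cells_per_ml, "mean_cells_per_ml", nonneg = TRUE)
  check_scalar(log_sd, "log_sd", positive = TRUE)
  if (mean_cells_per_ml == 0) return(rep(0, n))
  rlnorm(n, meanlog = log(mean_cells_per_ml) - log_sd^2 / 2, sdlog = log_sd)
}

# Channel intensity models (arbitrary fluorescence units). Positive marker
# signal sits well above the common-cell background; the default static gate
# of 150 separates them.
intensity_positive <- function(n) rlnorm(n, meanlog = log(500), sdlog = 0.25)
intensity_background <- function(n) rlnorm(n, meanlog = log(50), sdlog = 0.30)
intensity_dapi <- function(n) rlnorm(n, meanlog = log(800), sdlog = 0.20)

#' Generate a synthetic rare-cell cohort
#'
#' Simulates sample metadata and a per-cell event table with the statistical
#' structure the downstream pipeline assumes: per-sample, per-group event
#' counts are `round(volume_ml * rate)` with lognormal rates centred on the
#' configured group means; each event carries channel intensities consistent
#' with its group (positive markers above the default gate, negative markers
#' at background) and a morphometric vector whose channel blocks are shifted
#' for the markers the group is positive for.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `meta` (one row per sample: `sample_id`, `cohort`,
#'   `volume_ml`, `slide_ids`, `nucleated_cells`) and `events` (one row per
#'   cell: ids, `group` (the generating truth), channel intensities and
#'   morphometric features). Deterministic given `spec$seed`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_sclc = 2, n_nd = 2, seed = 7))
#' table(cohort$events$cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    samples <- data.frame(
      sample_id = c(sprintf("SCLC-%02d", seq_len(spec$n_sclc)),
                    sprintf("ND-%02d", seq_len(spec$n_nd))),
      cohort = c(rep("SCLC", spec$n_sclc), rep("ND", spec$n_nd)),
      stringsAsFactors = FALSE
    )
    n_samp <- nrow(samples)
    if (n_samp == 0L) {
      return(list(meta = empty_meta(), events = empty_events(spec$morpho_dim)))
    }
    slide_mean <- spec$slide_cell_total_mean[samples$cohort]
    # two slides per test; slide totals jitter ~5% around the cohort mean
    s1 <- round(slide_mean * exp(rnorm(n_samp, 0, 0.05)))
    s2 <- round(slide_mean * exp(rnorm(n_samp, 0, 0.05)))
    meta <- data.frame(
      sample_id = samples$sample_id,
      cohort = samples$cohort,
      volume_ml = spec$volume_ml,
      slide_1 = paste0(samples$sample_id, "-A"),
      slide_2 = paste0(samples$sample_id, "-B"),
      nucleated_cells_slide_1 = as.numeric(s1),
      nucleated_cells_slide_2 = as.numeric(s2),
      stringsAsFactors = FALSE
    )

    ab <- spec$group_abundance
    feat_names <- morpho_feature_names(spec$morpho_dim)
    blocks <- sub("\\..*$", "", feat_names)
    markers <- assay_markers("landscape")
    groups <- assay_groups("landscape")
    patt <- group_marker_pattern(groups, "landscape")

    chunks <- vector("list", n_samp * length(groups))
    ci <- 0L
    for (i in seq_len(n_samp)) {
      for (g in groups) {
        row <- ab[ab$cohort == samples$cohort[i] & ab$group == g, ][1, ]
        rate <- draw_group_rates(1L, row$mean_cells_per_ml, row$log_sd)
        n_ev <- as.integer(round(spec$volume_ml * rate))
        if (n_ev <= 0L) next
        pos <- patt[g, ]
        intens <- sapply(markers, function(m) {
          if (pos[[m]]) intensity_positive(n_ev) else intensity_background(n_ev)
        })
        intens <- matrix(intens, nrow = n_ev,
                         dimnames = list(NULL, markers))
        morpho <- matrix(rnorm(n_ev * spec$morpho_dim), nrow = n_ev,
                         dimnames = list(NULL, feat_names))
        # shift the feature block of each positive marker
        block_of <- c(ck = "CK", vim = "Vim", cd45cd31 = "CD45CD31")
        for (m in markers[pos]) {
          morpho[, blocks == block_of[[m]]] <-
            morpho[, blocks == block_of[[m]]] + spec$group_shift
        }
        slide <- sample(c(meta$slide_1[i], meta$slide_2[i]), n_ev, replace = TRUE)
        ci <- ci + 1L
        chunks[[ci]] <- data.frame(
          cell_id = NA_character_,
          sample_id = samples$sample_id[i],
          slide_id = slide,
          cohort = samples$cohort[i],
          group = g,
          dapi = intensity_dapi(n_ev),
          intens,
          morpho,
          stringsAsFactors = FALSE,
          check.names = FALSE
        )
      }
    }
    events <- if (ci == 0L) empty_events(spec$morpho_dim)
              else do.call(rbind, chunks[seq_len(ci)])
    if (nrow(events)) {
      events$cell_id <- sprintf("cell-%06d", seq_len(nrow(events)))
      rownames(events) <- NULL
    }
    list(meta = meta, events = events)
  })
}

empty_meta <- function() {
  data.frame(sample_id = character(), cohort = character(),
             volume_ml = numeric(), slide_1 = character(), slide_2 = character(),
             nucleated_cells_slide_1 = numeric(),
             nucleated_cells_slide_2 = numeric(), stringsAsFactors = FALSE)
}

empty_events <- function(morpho_dim = 56L) {
  base <- data.frame(cell_id = character(), sample_id = character(),
                     slide_id = character(), cohort = character(),
                     group = character(), dapi = numeric(), ck = numeric(),
                     vim = numeric(), cd45cd31 = numeric(),
                     stringsAsFactors = FALSE)
  for (f in morpho_feature_names(morpho_dim)) base[[f]] <- numeric()
  base
}

#' Engineered feature matrix with known correlation structure
#'
#' Builds a cells-by-features matrix of `n_pairs` near-duplicate feature
#' pairs (the second member equals the first plus small independent jitter,
#' so pairwise correlation exceeds 0.99) plus `n_independent` mutually
#' independent standard-normal features. Used to exercise correlation-based
#' feature selection: with the default design, grouping at |r| > 0.9 keeps
#' one representative per pair, hence `n_pairs + n_independent` features.
#'
#' @param n_cells Number of rows.
#' @param n_pairs Number of near-duplicate pairs.
#' @param n_independent Number of independent features.
#' @param jitter_sd SD of the jitter added to the duplicate member.
#' @param seed Integer seed.
#' @return Numeric matrix with named columns (`dupA01`/`dupB01`, ...,
#'   `indep01`, ...).
#' @export
simulate_correlated_features <- function(n_cells = 1000L, n_pairs = 34L,
                                         n_independent = 22L, jitter_sd = 0.05,
                                         seed = 1L) {
  with_seed(seed, {
    base <- matrix(rnorm(n_cells * n_pairs), n_cells, n_pairs)
    dup <- base + matrix(rnorm(n_cells * n_pairs, sd = jitter_sd),
                         n_cells, n_pairs)
    indep <- matrix(rnorm(n_cells * n_independent), n_cells, n_independent)
    x <- cbind(base, dup, indep)
    colnames(x) <- c(sprintf("dupA%02d", seq_len(n_pairs)),
                     sprintf("dupB%02d", seq_len(n_pairs)),
                     sprintf("indep%02d", seq_len(n_independent)))
    x
  })
}
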