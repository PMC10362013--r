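#' Fit channel positivity gates
#'
#' A marker is called positive when its intensity exceeds the gate. Two gate
#' methods are supported: `static` passes user thresholds through unchanged;
#' `k_sigma_background` sets each marker's threshold to
#' `median + k * mad` (scaled MAD) of a background population of common
#' cells, per slide when the background table carries a `slide_id` column
#' with more than one slide. The k-sigma rule is a robust, analyst-free
#' analogue of visual gating against the common-cell background.
#'
#' @param events Background event table with the marker intensity columns
#'   (and optionally `slide_id`). Ignored for `method = "static"`.
#' @param method `"static"` or `"k_sigma_background"`.
#' @param k Multiplier for the scaled MAD.
#' @param thresholds Named numeric vector of static thresholds (must include
#'   `dapi` and the assay markers). Default gates every channel at 150
#'   fluorescence units, matching the synthetic intensity model.
#' @param assay Assay whose markers are gated.
#' @return An object of class `gate_config`: list with `method`, `k`, and
#'   `thresholds`, a data frame with one row per slide (or a single row with
#'   `slide_id = NA` for global gates) and one column per channel.
#' @export
fit_gates <- function(events = NULL,
                      method = c("static", "k_sigma_background"),
                      k = 5,
                      thresholds = c(dapi = 150, ck = 150, vim = 150,
                                     cd45cd31 = 150, epcam = 150, cd45 = 150),
                      assay = c("landscape", "epcam")) {
  method <- match.arg(method)
  assay <- match.arg(assay)
  check_scalar(k, "k", positive = TRUE)
  channels <- c("dapi", assay_markers(assay))
  if (method == "static") {
    if (!all(channels %in% names(thresholds))) {
      stop("static thresholds missing channel(s): ",
           paste(setdiff(channels, names(thresholds)), collapse = ", "))
    }
    if (any(!is.finite(thresholds[channels]))) stop("thresholds must be finite")
    th <- as.data.frame(as.list(thresholds[channels]))
    th <- cbind(data.frame(slide_id = NA_character_), th)
    return(structure(list(method = method, k = k, thresholds = th),
                     class = "gate_config"))
  }
  if (is.null(events) || !nrow(events)) {
    stop("k_sigma_background gating needs a non-empty background table")
  }
  if (!all(channels %in% names(events))) {
    stop("background table missing channel(s): ",
         paste(setdiff(channels, names(events)), collapse = ", "))
  }
  slides <- if ("slide_id" %in% names(events)) events$slide_id
            else rep(NA_character_, nrow(events))
  th <- do.call(rbind, lapply(unique(slides), function(s) {
    sub <- events[is.na(s) | slides == s, channels, drop = FALSE]
    row <- vapply(channels,
                  function(ch) median(sub[[ch]]) + k * mad(sub[[ch]]),
                  numeric(1))
    cbind(data.frame(slide_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(row)))
  }))
  rownames(th) <- NULL
  structure(list(method = method, k = k, thresholds = th),
            class = "gate_config")
}

# Threshold row applying to a vector of slide ids: returns a matrix
# (n x channels) of thresholds.
gate_matrix <- function(gates, slide_id, channels) {
  th <- gates$thresholds
  if (nrow(th) == 1L && is.na(th$slide_id[1])) {
    idx <- rep(1L, length(slide_id))
  } else {
    idx <- match(slide_id, th$slide_id)
    if (any(is.na(idx))) {
      stop("no gate fitted for slide(s): ",
           paste(unique(slide_id[is.na(idx)]), collapse = ", "))
    }
  }
  as.matrix(th[idx, channels, drop = FALSE])
}

#' Classify events into channel-based groups
#'
#' Assigns each DAPI-positive event to exactly one of the eight
#' marker-combination groups of the assay: a marker is positive iff its
#' intensity strictly exceeds its gate, and the resulting three-bit
#' positivity pattern maps bijectively onto the group names. Events whose
#' DAPI intensity is at or below the DAPI gate are not nucleated cells:
#' they are flagged (`dapi_pass = FALSE`, `group = NA`) rather than
#' classified.
#'
#' @param events Event table with `cell_id`, `sample_id`, the assay's
#'   intensity columns and `dapi` (plus `slide_id` if gates are per slide).
#' @param gates A [fit_gates()] result.
#' @param assay `"landscape"` or `"epcam"`.
#' @return Data frame of channel calls: `cell_id`, `sample_id`, `group`,
#'   `dapi_pass`.
#' @export
classify_events <- function(events, gates, assay = c("landscape", "epcam")) {
  assay <- match.arg(assay)
  stopifnot(inherits(gates, "gate_config"))
  markers <- assay_markers(assay)
  channels <- c("dapi", markers)
  if (!all(channels %in% names(events))) {
    stop("events missing channel column(s): ",
         paste(setdiff(channels, names(events)), collapse = ", "))
  }
  if (!nrow(events)) {
    return(data.frame(cell_id = character(), sample_id = character(),
                      group = character(), dapi_pass = logical(),
                      stringsAsFactors = FALSE))
  }
  slide <- if ("slide_id" %in% names(events)) events$slide_id
           else rep(NA_character_, nrow(events))
  th <- gate_matrix(gates, slide, channels)
  dapi_pass <- events$dapi > th[, "dapi"]
  pos <- vapply(markers, function(m) events[[m]] > th[, m],
                logical(nrow(events)))
  pos <- matrix(pos, nrow = nrow(events), dimnames = list(NULL, markers))
  tt <- marker_truth_table(assay)
  key <- pos[, 1] * 4L + pos[, 2] * 2L + pos[, 3]
  tt_key <- tt$m1 * 4L + tt$m2 * 2L + tt$m3
  group <- tt$group[match(key, tt_key)]
  group[!dapi_pass] <- NA_character_
  data.frame(cell_id = events$cell_id, sample_id = events$sample_id,
             group = group, dapi_pass = dapi_pass, stringsAsFactors = FALSE)
}

#' Enumerate channel groups per sample
#'
#' Tabulates classified events per (sample, group): raw count, cells per mL
#' of blood-equivalent volume, cells per million nucleated cells imaged
#' (both slides of the test), and the group's proportion of the sample's
#' classified rare events. Groups with no events in a sample are reported
#' as zero; DAPI-rejected events are excluded.
#'
#' @param calls Channel calls from [classify_events()].
#' @param meta Sample metadata with `sample_id`, `cohort`, `volume_ml` and
#'   (for per-million rates) `nucleated_cells_slide_1`/`_2`.
#' @param assay Assay whose eight groups define the table rows.
#' @return Data frame with columns `sample_id`, `cohort`, `group`, `count`,
#'   `cells_per_ml`, `cells_per_million`, `proportion`.
#' @export
enumerate_cells <- function(calls, meta, assay = c("landscape", "epcam")) {
  assay <- match.arg(assay)
  groups <- assay_groups(assay)
  stopifnot(all(c("sample_id", "volume_ml") %in% names(meta)))
  if (any(!is.finite(meta$volume_ml)) || any(meta$volume_ml <= 0)) {
    stop("every sample needs a finite positive volume_ml")
  }
  calls <- calls[!is.na(calls$group), , drop = FALSE]
  if (nrow(calls) && !all(calls$sample_id %in% meta$sample_id)) {
    stop("calls reference samples absent from metadata")
  }
  grid <- expand.grid(sample_id = meta$sample_id, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(calls)) {
    cnt <- as.data.frame(table(sample_id = calls$sample_id,
                               group = calls$group),
                         stringsAsFactors = FALSE)
    names(cnt)[3] <- "count"
    out <- merge(grid, cnt, by = c("sample_id", "group"), all.x = TRUE)
    out$count[is.na(out$count)] <- 0L
  } else {
    out <- grid
    out$count <- integer(nrow(grid))
  }
  mi <- match(out$sample_id, meta$sample_id)
  out$cohort <- if ("cohort" %in% names(meta)) meta$cohort[mi] else NA_character_
  out$cells_per_ml <- out$count / meta$volume_ml[mi]
  nuc <- if (all(c("nucleated_cells_slide_1", "nucleated_cells_slide_2") %in%
               names(meta))) {
    meta$nucleated_cells_slide_1[mi] + meta$nucleated_cells_slide_2[mi]
  } else NA_real_
  out$cells_per_million <- out$count / nuc * 1e6
  tot <- tapply(out$count, out$sample_id, sum)[out$sample_id]
  out$proportion <- ifelse(tot > 0, out$count / tot, 0)
  out <- out[order(match(out$sample_id, meta$sample_id),
                   match(out$group, groups)),
             c("sample_id", "cohort", "group", "count", "cells_per_ml",
               "cells_per_million", "proportion")]
  rownames(out) <- NULL
  out
}

#' Compare cohorts per channel group
#'
#' Two-sided Mann-Whitney U test of the per-sample rates between the two
#' cohorts, one test per channel group, with significance stars at the
#' 0.05 / 0.01 / 0.001 / 0.0001 levels. No multiple-testing correction is
#' applied by default (significance is read at raw p <= 0.05);
#' Benjamini-Hochberg adjusted p-values are available via `p_adjust`.
#'
#' @param enumeration Table from [enumerate_cells()] with a `cohort` column.
#' @param value One of `"cells_per_ml"`, `"cells_per_million"`, `"count"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame per group: cohort means, U statistic, `p_value`,
#'   optional `p_adjusted`, and `stars`.
#' @export
compare_cohorts <- function(enumeration, value = "cells_per_ml",
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(value %in% names(enumeration), "cohort" %in% names(enumeration))
  cohorts <- sort(unique(enumeration$cohort))
  if (length(cohorts) != 2L) stop("need exactly two non-empty cohorts")
  groups <- unique(enumeration$group)
  res <- do.call(rbind, lapply(groups, function(g) {
    sub <- enumeration[enumeration$group == g, ]
    x <- sub[[value]][sub$cohort == cohorts[1]]
    y <- sub[[value]][sub$cohort == cohorts[2]]
    if (!length(x) || !length(y)) stop("one cohort is empty for group ", g)
    mw <- mann_whitney_u(x, y)
    data.frame(group = g,
               mean_1 = mean(x), mean_2 = mean(y),
               U = mw$statistic, p_value = mw$p_value,
               method = mw$method, stringsAsFactors = FALSE)
  }))
  names(res)[names(res) == "mean_1"] <- paste0("mean_", cohorts[1])
  names(res)[names(res) == "mean_2"] <- paste0("mean_", cohorts[2])
  if (p_adjust == "BH") res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  p_for_stars <- if (p_adjust == "BH") res$p_adjusted else res$p_value
  res$stars <- significance_stars(p_for_stars)
  rownames(res) <- NULL
  res
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = TRUE) |>
    as.character()
}
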