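#' Channel-based cell groups of the Landscape and EpCAM assays
#'
#' Each DAPI-positive rare-cell event is assigned to exactly one of eight
#' marker-positivity combinations. The Landscape panel uses pan-cytokeratin
#' (CK), Vimentin (Vim) and a pooled CD45/CD31 channel; the EpCAM panel uses
#' CK, EpCAM and CD45. The three binary markers map bijectively onto the
#' eight named groups.
#'
#' @param assay `"landscape"` or `"epcam"`.
#' @return `assay_groups()`: character vector of the eight group names.
#'   `assay_markers()`: character vector of the three gate-able marker
#'   column names (besides `dapi`).
#' @examples
#' assay_groups("landscape")
#' assay_markers("epcam")
#' @export
assay_groups <- function(assay = c("landscape", "epcam")) {
  assay <- match.arg(assay)
  marker_truth_table(assay)$group
}

#' @rdname assay_groups
#' @export
assay_markers <- function(assay = c("landscape", "epcam")) {
  assay <- match.arg(assay)
  if (assay == "landscape") c("ck", "vim", "cd45cd31") else c("ck", "epcam", "cd45")
}

# Truth table mapping the 2^3 marker-positivity patterns to group names.
# Column order matches assay_markers(assay).
marker_truth_table <- function(assay = c("landscape", "epcam")) {
  assay <- match.arg(assay)
  if (assay == "landscape") {
    data.frame(
      m1 = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
      m2 = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  TRUE,  FALSE, FALSE),
      m3 = c(FALSE, FALSE, TRUE,  TRUE,  FALSE, TRUE,  TRUE,  FALSE),
      group = c("CK", "CK|Vim", "CK|(CD45/CD31)", "CK|Vim|(CD45/CD31)",
                "Vim", "Vim|(CD45/CD31)", "(CD45/CD31)", "DAPI"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      m1 = c(TRUE,  TRUE,  TRUE,  FALSE, TRUE,  FALSE, FALSE, FALSE),
      m2 = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
      m3 = c(FALSE, FALSE, TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE),
      group = c("CK", "CK|EpCAM", "CK|CD45", "EpCAM|CD45", "CK|EpCAM|CD45",
                "CD45", "EpCAM", "DAPI"),
      stringsAsFactors = FALSE
    )
  }
}

# Marker-positivity pattern (logical length-3, order = assay_markers) for a
# given group name.
group_marker_pattern <- function(group, assay) {
  tt <- marker_truth_table(assay)
  i <- match(group, tt$group)
  if (any(is.na(i))) {
    stop("unknown group(s): ", paste(group[is.na(i)], collapse = ", "))
  }
  m <- as.matrix(tt[i, c("m1", "m2", "m3"), drop = FALSE])
  colnames(m) <- assay_markers(assay)
  rownames(m) <- group
  m
}
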