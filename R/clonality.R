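#' Clonality rule
#'
#' A sample's cells are clonally altered when more than two cells share at
#' least three alterations in concordance. Two alterations are matched when
#' they lie on the same chromosome, have the same direction, and overlap
#' reciprocally by at least `reciprocal_overlap` of each one's length.
#'
#' @param min_group_size Minimum cells per clonal group ("more than two"
#'   cells, hence 3).
#' @param min_shared_alterations Minimum concordant alterations between two
#'   cells (or across a group, see `semantics` of [call_clonality()]).
#' @param reciprocal_overlap Minimum reciprocal overlap fraction in (0, 1].
#' @return A list of class `clonality_rule`.
#' @export
clonality_rule <- function(min_group_size = 3L, min_shared_alterations = 3L,
                           reciprocal_overlap = 0.5) {
  stopifnot(min_group_size >= 3L, min_shared_alterations >= 1L,
            reciprocal_overlap > 0, reciprocal_overlap <= 1)
  structure(list(min_group_size = as.integer(min_group_size),
                 min_shared_alterations = as.integer(min_shared_alterations),
                 reciprocal_overlap = reciprocal_overlap),
            class = "clonality_rule")
}

# Number of alterations of `a` having a reciprocal-overlap match in `b`
# (same chrom + direction, overlap >= frac of both lengths).
n_matched_alterations <- function(a, b, frac) {
  if (!nrow(a) || !nrow(b)) return(0L)
  hits <- vapply(seq_len(nrow(a)), function(i) {
    cand <- b[b$chrom == a$chrom[i] & b$direction == a$direction[i], ,
              drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    ov <- pmin(a$end_bin[i], cand$end_bin) -
      pmax(a$start_bin[i], cand$start_bin) + 1L
    len_a <- a$end_bin[i] - a$start_bin[i] + 1L
    len_b <- cand$end_bin - cand$start_bin + 1L
    any(ov >= frac * len_a & ov >= frac * len_b)
  }, logical(1))
  sum(hits)
}

# TRUE when cells with alteration sets a, b are concordant under the rule.
cells_concordant <- function(a, b, rule) {
  min(n_matched_alterations(a, b, rule$reciprocal_overlap),
      n_matched_alterations(b, a, rule$reciprocal_overlap)) >=
    rule$min_shared_alterations
}

#' Call clonality within one sample
#'
#' Builds the concordance graph over a sample's QC-passed cells (an edge
#' when two cells share at least `min_shared_alterations` matched
#' alterations) and flags every member of a connected component with at
#' least `min_group_size` cells as clonally altered. Under
#' `semantics = "group_intersection"` a component is additionally required
#' to have at least `min_shared_alterations` alterations matched across
#' every member.
#'
#' @param alterations Data frame of alterations for all cells of one sample
#'   (columns of [extract_alterations()] plus `cell_id`), or a named list of
#'   per-cell alteration tables.
#' @param cell_ids Cells to consider (cells with no alterations still count
#'   as cells; they simply cannot be concordant). Defaults to the cells
#'   present in `alterations`.
#' @param rule A [clonality_rule()].
#' @param semantics `"pairwise"` (default) or `"group_intersection"`.
#' @return Object of class `clonal_call`: data frame `cells` (`cell_id`,
#'   `clonal`, `group_id`), list `groups` of cell-id vectors, and the rule.
#' @export
call_clonality <- function(alterations, cell_ids = NULL,
                           rule = clonality_rule(),
                           semantics = c("pairwise", "group_intersection")) {
  semantics <- match.arg(semantics)
  if (is.data.frame(alterations)) {
    stopifnot("cell_id" %in% names(alterations))
    alt_list <- split(alterations, alterations$cell_id)
  } else {
    alt_list <- alterations
  }
  if (is.null(cell_ids)) cell_ids <- names(alt_list)
  cell_ids <- as.character(cell_ids)
  n <- length(cell_ids)
  empty_alt <- data.frame(chrom = character(), start_bin = integer(),
                          end_bin = integer(), direction = character(),
                          stringsAsFactors = FALSE)
  alt_of <- function(id) alt_list[[id]] %||% empty_alt

  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    keep <- vapply(seq_len(ncol(pairs)), function(j) {
      cells_concordant(alt_of(cell_ids[pairs[1, j]]),
                       alt_of(cell_ids[pairs[2, j]]), rule)
    }, logical(1))
    edges <- t(pairs[, keep, drop = FALSE])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  groups <- list()
  clonal <- logical(n)
  group_id <- rep(NA_integer_, n)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < rule$min_group_size) next
    if (semantics == "group_intersection") {
      # alterations of the first member matched in every other member
      ref <- alt_of(cell_ids[members[1]])
      shared <- vapply(seq_len(nrow(ref)), function(i) {
        all(vapply(members[-1], function(mj) {
          n_matched_alterations(ref[i, , drop = FALSE],
                                alt_of(cell_ids[mj]),
                                rule$reciprocal_overlap) > 0L
        }, logical(1)))
      }, logical(1))
      if (sum(shared) < rule$min_shared_alterations) next
    }
    groups[[length(groups) + 1L]] <- cell_ids[members]
    clonal[members] <- TRUE
    group_id[members] <- length(groups)
  }
  structure(list(
    cells = data.frame(cell_id = cell_ids, clonal = clonal,
                       group_id = group_id, stringsAsFactors = FALSE),
    groups = groups,
    rule = rule,
    semantics = semantics
  ), class = "clonal_call")
}

#' @export
print.clonal_call <- function(x, ...) {
  cat(sprintf("clonal_call: %d/%d cell(s) clonally altered in %d group(s)\n",
              sum(x$cells$clonal), nrow(x$cells), length(x$groups)))
  invisible(x)
}

#' Clonal fraction per channel group
#'
#' Fraction of cells flagged clonally altered within each channel group,
#' e.g. 16 of 20 CK CTCs clonal gives 80% for the CK group.
#'
#' @param clonal_call A [call_clonality()] result.
#' @param cell_groups Data frame mapping `cell_id` to `group`.
#' @return Data frame per group: `n_cells`, `n_clonal`, `clonal_fraction`
#'   (percent, one decimal).
#' @export
clonal_fraction_by_group <- function(clonal_call, cell_groups) {
  stopifnot(inherits(clonal_call, "clonal_call"),
            all(c("cell_id", "group") %in% names(cell_groups)))
  d <- merge(clonal_call$cells, cell_groups[, c("cell_id", "group")],
             by = "cell_id")
  out <- do.call(rbind, lapply(split(d, d$group), function(s) {
    data.frame(group = s$group[1], n_cells = nrow(s),
               n_clonal = sum(s$clonal),
               clonal_fraction = round_half_up(100 * mean(s$clonal), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
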