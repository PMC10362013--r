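# Shared fixtures, all built in code.

# Small cohort: full group structure at 5% of a mL so tests stay fast.
small_cohort <- function(seed = 11, volume_ml = 0.05) {
  generate_cohort(cohort_spec(volume_ml = volume_ml, seed = seed))
}

# Channel-call table for the UM-001-style EpCAM worked example:
# 178 cells, 69 CK|EpCAM + 59 CK CTCs plus 50 non-CTC events.
um001_calls <- function() {
  groups <- c(rep("CK|EpCAM", 69), rep("CK", 59), rep("CK|CD45", 12),
              rep("EpCAM|CD45", 8), rep("CK|EpCAM|CD45", 6), rep("DAPI", 14),
              rep("CD45", 6), rep("EpCAM", 4))
  data.frame(cell_id = sprintf("um-%03d", seq_along(groups)),
             sample_id = "UM-001", group = groups, dapi_pass = TRUE,
             stringsAsFactors = FALSE)
}

um001_meta <- function() {
  data.frame(sample_id = "UM-001", cohort = "SCLC", volume_ml = 1,
             nucleated_cells_slide_1 = 2e6, nucleated_cells_slide_2 = 2e6,
             stringsAsFactors = FALSE)
}

# Noiseless bin counts for n_clonal cells carrying three 20-bin losses
# (10q, 13q, 17p) and n_flat flat diploid cells, as one sample of CK CTCs.
clonal_fixture_genomes <- function(n_clonal = 16, n_flat = 4, seed = 5) {
  gs <- genome_spec(
    alteration_template = sclc_alteration_template(
      losses = c("10q", "13q", "17p"), gains = character(0)),
    noise_model = "noiseless")
  cells <- data.frame(
    cell_id = sprintf("ck-%02d", seq_len(n_clonal + n_flat)),
    group = "CK", sample_id = "P1", stringsAsFactors = FALSE)
  frac <- n_clonal / (n_clonal + n_flat)
  generate_genomes(gs, cells,
                   coupling = pheno_geno_coupling(
                     p_clonal_by_group = c(CK = frac)),
                   exact_allocation = TRUE, seed = seed)
}

# Profile every cell of a bin-count table; noiseless data segments quickly.
profile_all <- function(bin_counts, n_perm = 300, seed = 2) {
  lapply(split(bin_counts, bin_counts$cell_id), function(b) {
    profile_cell(b$count, b$chrom, b$start, b$end, cell_id = b$cell_id[1],
                 n_perm = n_perm, seed = seed)
  })
}

# Alteration table (cell_id + extract_alterations columns) for profiles.
alterations_of <- function(profiles, min_bins = 5) {
  do.call(rbind, lapply(profiles, function(p) {
    a <- extract_alterations(p, min_bins = min_bins)
    if (!nrow(a)) return(NULL)
    cbind(data.frame(cell_id = p$cell_id, stringsAsFactors = FALSE), a)
  }))
}

# Independent full-enumeration oracle for the two-sided Mann-Whitney test:
# enumerate every assignment of the observed ranks to group 1.
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(r), n1)
  w_all <- apply(sets, 2, function(i) sum(r[i]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Simple one-cell alteration table builder for clonality tests.
alt_table <- function(cell_id, regions) {
  do.call(rbind, lapply(regions, function(r) {
    data.frame(cell_id = cell_id, chrom = r[[1]],
               start_bin = as.integer(r[[2]]), end_bin = as.integer(r[[3]]),
               direction = r[[4]], stringsAsFactors = FALSE)
  }))
}
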