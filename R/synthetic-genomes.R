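#' Specify a synthetic single-cell genome
#'
#' Defines the bin grid and the clonal alteration template used to simulate
#' single-cell sequencing bin counts. The default genome is an abstract
#' 22-autosome grid of 100 bins each (2,200 bins, nominal 1 Mb bins) rather
#' than real hg19 coordinates; a real bin grid may be supplied instead.
#'
#' @param chromosomes Named integer vector: bins per chromosome, in order.
#' @param bin_size Nominal bin width in base pairs (used only for output
#'   coordinates).
#' @param alteration_template Data frame of clonal alterations with columns
#'   `chrom`, `start_bin`, `end_bin` (1-based inclusive bin indices within
#'   the chromosome) and `cn` (target integer copy number, 0..8). See
#'   [sclc_alteration_template()].
#' @param mean_reads_per_bin Expected unique reads per bin at copy number 2.
#' @param noise_model `"noiseless"` (counts exactly proportional to copy
#'   number) or `"poisson"`.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes = setNames(rep(100L, 22),
                                               paste0("chr", 1:22)),
                        bin_size = 1e6,
                        alteration_template = sclc_alteration_template(),
                        mean_reads_per_bin = 100,
                        noise_model = c("noiseless", "poisson")) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.numeric(chromosomes), length(chromosomes) >= 1,
            all(chromosomes >= 1), !is.null(names(chromosomes)))
  check_scalar(mean_reads_per_bin, "mean_reads_per_bin", positive = TRUE)
  tmpl <- alteration_template
  stopifnot(is.data.frame(tmpl),
            all(c("chrom", "start_bin", "end_bin", "cn") %in% names(tmpl)))
  if (nrow(tmpl)) {
    if (!all(tmpl$chrom %in% names(chromosomes))) {
      stop("alteration template names a chromosome absent from the genome")
    }
    if (any(tmpl$start_bin < 1) ||
        any(tmpl$end_bin > chromosomes[tmpl$chrom]) ||
        any(tmpl$start_bin > tmpl$end_bin)) {
      stop("alteration template region outside chromosome bounds")
    }
    if (any(tmpl$cn < 0 | tmpl$cn > 8 | tmpl$cn != round(tmpl$cn))) {
      stop("template copy numbers must be integers in 0..8")
    }
  }
  structure(list(chromosomes = setNames(as.integer(chromosomes),
                                        names(chromosomes)),
                 bin_size = bin_size,
                 alteration_template = tmpl,
                 mean_reads_per_bin = mean_reads_per_bin,
                 noise_model = noise_model),
            class = "genome_spec")
}

#' Clonal SCLC alteration template
#'
#' The copy-number alterations recurrently clonal in SCLC circulating tumor
#' cells: single-copy losses on 3p (RASSF1), 10q (PTEN), 13q (RB1) and 17p
#' (TP53), and single-copy gains on 1q, 3q, 5p and 8q (MYC). Regions are
#' expressed as bin ranges on the abstract default genome, p-arm regions at
#' the start of the chromosome and q-arm regions at the end.
#'
#' @param losses,gains Character vectors naming which of the template arms to
#'   include, e.g. `c("3p", "10q")`.
#' @return Data frame with columns `chrom`, `start_bin`, `end_bin`, `cn`,
#'   `label`.
#' @export
sclc_alteration_template <- function(losses = c("3p", "10q", "13q", "17p"),
                                     gains = c("1q", "3q", "5p", "8q")) {
  arms <- data.frame(
    label = c("3p", "10q", "13q", "17p", "1q", "3q", "5p", "8q"),
    chrom = c("chr3", "chr10", "chr13", "chr17", "chr1", "chr3", "chr5", "chr8"),
    start_bin = c(1L, 61L, 31L, 1L, 61L, 71L, 1L, 61L),
    end_bin = c(20L, 80L, 50L, 20L, 100L, 100L, 20L, 100L),
    cn = c(1L, 1L, 1L, 1L, 3L, 3L, 3L, 3L),
    stringsAsFactors = FALSE
  )
  keep <- arms$label %in% c(losses, gains)
  arms[keep, c("chrom", "start_bin", "end_bin", "cn", "label")]
}

#' Phenotype-genotype coupling for the synthetic generator
#'
#' Describes how clonal genomic status is coupled to phenotype in simulated
#' cohorts: the probability that a cell of each channel group carries the
#' clonal alteration template, and which morphometric features shift (in
#' pooled-SD units) in clonally altered cells. The default makes 12
#' CK-related and 7 Vim-related features informative at a 1.5 SD shift,
#' leaving 37 of the 56 default features uninformative.
#'
#' @param p_clonal_by_group Named numeric vector of clonal probabilities per
#'   channel group (groups absent from the vector get probability 0).
#' @param informative_features Data frame with columns `feature` and `shift`.
#' @param n_noise_features Number of uninformative features (bookkeeping
#'   only; checked against the feature space when genomes are generated).
#' @return An object of class `pheno_geno_coupling`.
#' @export
pheno_geno_coupling <- function(
    p_clonal_by_group = c("CK" = 0.8, "CK|Vim" = 0.3, "CK|(CD45/CD31)" = 0.3,
                          "CK|Vim|(CD45/CD31)" = 0.3, "Vim" = 0.15,
                          "Vim|(CD45/CD31)" = 0.15, "(CD45/CD31)" = 0.05,
                          "DAPI" = 0.1),
    informative_features = data.frame(
      feature = c(sprintf("CK.f%02d", 1:12), sprintf("Vim.f%02d", 1:7)),
      shift = 1.5,
      stringsAsFactors = FALSE),
    n_noise_features = 37L) {
  stopifnot(is.numeric(p_clonal_by_group),
            all(p_clonal_by_group >= 0 & p_clonal_by_group <= 1),
            is.data.frame(informative_features),
            all(c("feature", "shift") %in% names(informative_features)),
            all(is.finite(informative_features$shift)))
  structure(list(p_clonal_by_group = p_clonal_by_group,
                 informative_features = informative_features,
                 n_noise_features = as.integer(n_noise_features)),
            class = "pheno_geno_coupling")
}

# Bin grid of a genome_spec: data.frame(chrom, start, end) with 0-based
# half-open coordinates, plus within-chromosome 1-based bin index.
genome_bins <- function(gspec) {
  chroms <- gspec$chromosomes
  do.call(rbind, lapply(names(chroms), function(ch) {
    idx <- seq_len(chroms[[ch]])
    data.frame(chrom = ch, bin = idx,
               start = (idx - 1) * gspec$bin_size,
               end = idx * gspec$bin_size,
               stringsAsFactors = FALSE)
  }))
}

# Per-bin integer copy-number vector implied by a template on a genome.
template_cn_vector <- function(gspec) {
  bins <- genome_bins(gspec)
  cn <- rep(2L, nrow(bins))
  tmpl <- gspec$alteration_template
  for (i in seq_len(nrow(tmpl))) {
    sel <- bins$chrom == tmpl$chrom[i] &
      bins$bin >= tmpl$start_bin[i] & bins$bin <= tmpl$end_bin[i]
    cn[sel] <- tmpl$cn[i]
  }
  cn
}

#' Generate synthetic single-cell genomes
#'
#' Simulates per-cell genomic bin read counts for the cells of an event
#' table. Each cell is labelled clonal with the group-specific probability of
#' the coupling (or by forced exact allocation); clonal cells carry the
#' genome's alteration template with expected reads
#' `mean_reads_per_bin * CN / 2` per bin, non-clonal cells and white-blood-
#' cell controls are flat diploid. In `noiseless` mode counts equal their
#' expectation exactly; in `poisson` mode they are Poisson draws. Clonal
#' cells additionally have the coupling's informative morphometric features
#' shifted (in pooled-SD units) in the returned event table.
#'
#' @param gspec A [genome_spec()].
#' @param cells Event table (rows are cells; must have `cell_id`, `group`,
#'   `sample_id`). Cells with group `"WBC"` are always flat controls.
#' @param coupling A [pheno_geno_coupling()].
#' @param exact_allocation If `TRUE`, exactly `round(p * n)` cells per
#'   (sample, group) are made clonal, taken in table order, instead of
#'   independent Bernoulli draws.
#' @param seed Integer seed.
#' @return List with `bin_counts` (long data frame: `cell_id`, `chrom`,
#'   `start`, `end`, `count`; 0-based half-open), `truth` (per cell:
#'   `cell_id`, `sample_id`, `group`, `clonal`, `template`) and `events`
#'   (the input table with informative-feature shifts applied).
#' @export
generate_genomes <- function(gspec, cells, coupling = pheno_geno_coupling(),
                             exact_allocation = FALSE, seed = 1L) {
  stopifnot(inherits(gspec, "genome_spec"),
            is.data.frame(cells),
            all(c("cell_id", "group", "sample_id") %in% names(cells)))
  with_seed(seed, {
    n <- nrow(cells)
    p <- coupling$p_clonal_by_group[cells$group]
    p[is.na(p)] <- 0
    p[cells$group == "WBC"] <- 0
    clonal <- logical(n)
    if (exact_allocation) {
      key <- paste(cells$sample_id, cells$group)
      for (k in unique(key)) {
        idx <- which(key == k)
        n_cl <- as.integer(round(p[idx[1]] * length(idx)))
        clonal[idx[seq_len(n_cl)]] <- TRUE
      }
    } else {
      clonal <- runif(n) < p
    }

    bins <- genome_bins(gspec)
    cn_template <- template_cn_vector(gspec)
    m <- gspec$mean_reads_per_bin
    expected_flat <- rep(m, nrow(bins))
    expected_clonal <- m * cn_template / 2

    counts_list <- lapply(seq_len(n), function(i) {
      mu <- if (clonal[i]) expected_clonal else expected_flat
      if (gspec$noise_model == "poisson") rpois(length(mu), mu) else mu
    })
    bin_counts <- data.frame(
      cell_id = rep(cells$cell_id, each = nrow(bins)),
      chrom = rep(bins$chrom, n),
      start = rep(bins$start, n),
      end = rep(bins$end, n),
      count = unlist(counts_list, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      cell_id = cells$cell_id,
      sample_id = cells$sample_id,
      group = cells$group,
      clonal = clonal,
      template = ifelse(clonal, "sclc_clonal", "flat"),
      stringsAsFactors = FALSE
    )

    events <- cells
    inf <- coupling$informative_features
    present <- inf$feature %in% names(events)
    for (j in which(present)) {
      f <- inf$feature[j]
      s <- sd(events[[f]])
      if (!is.finite(s) || s == 0) s <- 1
      events[[f]][clonal] <- events[[f]][clonal] + inf$shift[j] * s
    }
    list(bin_counts = bin_counts, truth = truth, events = events)
  })
}

#' Simulate cells with phenotype-genotype coupling only
#'
#' Convenience generator for the single-cell alteration classifier: draws
#' standard-normal morphometric feature vectors for `n_altered` clonally
#' altered and `n_not` unaltered cells, shifting the coupling's informative
#' features in the altered class.
#'
#' @param n_altered,n_not Cells per class.
#' @param coupling A [pheno_geno_coupling()].
#' @param morpho_dim Number of features (named via [morpho_feature_names()]).
#' @param seed Integer seed.
#' @return List with `features` (matrix) and `clonal` (logical vector).
#' @export
simulate_coupled_cells <- function(n_altered = 300L, n_not = 300L,
                                   coupling = pheno_geno_coupling(),
                                   morpho_dim = 56L, seed = 1L) {
  with_seed(seed, {
    n <- n_altered + n_not
    feat <- morpho_feature_names(morpho_dim)
    x <- matrix(rnorm(n * length(feat)), n, length(feat),
                dimnames = list(NULL, feat))
    clonal <- rep(c(TRUE, FALSE), c(n_altered, n_not))
    inf <- coupling$informative_features
    for (j in seq_len(nrow(inf))) {
      f <- inf$feature[j]
      if (f %in% feat) x[clonal, f] <- x[clonal, f] + inf$shift[j]
    }
    list(features = x, clonal = clonal)
  })
}
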