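#' Normalize bin counts to copy-number ratios
#'
#' Per-bin ratio = count / mean(count), so the ratio profile has mean 1 and
#' is invariant to sequencing depth. With per-bin GC content supplied, a
#' LOWESS fit of ratio on GC is divided out (GC correction) before
#' re-centring to mean 1.
#'
#' @param counts Numeric vector of per-bin unique-read counts.
#' @param gc Optional numeric vector of per-bin GC fractions.
#' @return Numeric vector of mean-normalized ratios.
#' @export
normalize_bins <- function(counts, gc = NULL) {
  counts <- as.numeric(counts)
  if (!length(counts) || all(counts == 0)) {
    stop("bin counts must contain at least one nonzero bin")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("bin counts must be finite and non-negative")
  }
  r <- counts / mean(counts)
  if (!is.null(gc)) {
    stopifnot(length(gc) == length(counts))
    fit <- stats::lowess(gc, r, f = 0.3)
    trend <- stats::approx(fit$x, fit$y, xout = gc, rule = 2)$y
    trend[trend <= 0] <- 1
    r <- r / trend
    r <- r / mean(r)
  }
  r
}

#' Median absolute pairwise difference (MAPD) and quality score
#'
#' MAPD is the median of `abs(r[i + 1] - r[i])` over adjacent bin pairs within each
#' chromosome — a robust per-cell noise measure that ignores true
#' copy-number steps (which are rare among adjacent pairs). The cell quality
#' score is its reciprocal, `QS = 1 / MAPD`, so the inclusion threshold
#' QS >= 2.5 corresponds to MAPD <= 0.4. A noiseless profile has MAPD 0 and
#' infinite quality score.
#'
#' @param ratios Numeric vector of normalized bin ratios.
#' @param chrom Chromosome of each bin (adjacent differences are not taken
#'   across chromosome boundaries).
#' @return `mapd()`: a single number. `quality_score()`: `1 / MAPD`
#'   (`Inf` when MAPD is 0).
#' @export
mapd <- function(ratios, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("genome", length(ratios))
  stopifnot(length(chrom) == length(ratios))
  d <- unlist(lapply(split(ratios, factor(chrom, unique(chrom))), diff),
              use.names = FALSE)
  if (!length(d)) stop("need at least 2 bins on some chromosome")
  median(abs(d))
}

#' @rdname mapd
#' @export
quality_score <- function(ratios, chrom = NULL) {
  m <- mapd(ratios, chrom)
  if (m == 0) Inf else 1 / m
}

# Max two-sample |t| over all split points of x honouring min_len, plus the
# argmax. Vectorized over split points via cumulative sums. Splits with zero
# pooled variance but distinct means score Inf.
best_split_t <- function(x, min_len) {
  n <- length(x)
  if (n < 2L * min_len) return(NULL)
  i <- seq.int(min_len, n - min_len)
  cs <- cumsum(x); css <- cumsum(x^2)
  tot <- cs[n]; tot2 <- css[n]
  n1 <- i; n2 <- n - i
  m1 <- cs[i] / n1
  m2 <- (tot - cs[i]) / n2
  ss1 <- css[i] - n1 * m1^2
  ss2 <- (tot2 - css[i]) - n2 * m2^2
  sp2 <- pmax(ss1 + ss2, 0) / pmax(n - 2, 1)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- abs(m1 - m2)
  t <- ifelse(se > 1e-12, diff / se, ifelse(diff > 1e-12, Inf, 0))
  j <- which.max(t)
  list(stat = t[j], split = i[j])
}

# Recursive binary segmentation of one chromosome's ratio vector.
# Returns integer breakpoints (last bin index of each left part).
segment_one <- function(x, alpha, min_seg_bins, n_perm) {
  out <- integer(0)
  recurse <- function(lo, hi) {
    seg <- x[lo:hi]
    bs <- best_split_t(seg, min_seg_bins)
    if (is.null(bs) || bs$stat <= 0 || is.nan(bs$stat)) return(invisible())
    # permutation p-value of the max-|t| statistic
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      pb <- best_split_t(sample(seg), min_seg_bins)
      if (pb$stat >= bs$stat) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    if (p >= alpha) return(invisible())
    cut <- lo + bs$split - 1L
    out <<- c(out, cut)
    recurse(lo, cut)
    recurse(cut + 1L, hi)
  }
  recurse(1L, length(x))
  sort(out)
}

#' Segment a ratio profile
#'
#' Recursive binary segmentation, per chromosome: the candidate breakpoint
#' maximizing the two-sample t statistic between the flanking bin means is
#' accepted when its permutation p-value falls below `alpha` and both sides
#' keep at least `min_seg_bins` bins, then each side is segmented
#' recursively. Deterministic given `seed`.
#'
#' @param ratios Normalized bin ratios (one cell).
#' @param chrom Chromosome of each bin.
#' @param alpha Permutation significance level for accepting a split.
#' @param min_seg_bins Minimum bins per segment.
#' @param n_perm Permutations per candidate split.
#' @param seed Integer seed for the permutation draws.
#' @return Data frame of segments: `chrom`, `start_bin`, `end_bin` (1-based
#'   inclusive bin indices within the chromosome), `n_bins`, `mean_ratio`.
#' @export
segment_ratios <- function(ratios, chrom, alpha = 0.01, min_seg_bins = 5L,
                           n_perm = 1000L, seed = 1L) {
  stopifnot(length(ratios) == length(chrom))
  chrom_f <- factor(chrom, unique(chrom))
  with_seed(seed, {
    segs <- lapply(levels(chrom_f), function(ch) {
      x <- ratios[chrom_f == ch]
      cuts <- segment_one(x, alpha, min_seg_bins, as.integer(n_perm))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, length(x))
      data.frame(chrom = ch, start_bin = starts, end_bin = ends,
                 n_bins = ends - starts + 1L,
                 mean_ratio = vapply(seq_along(starts), function(i)
                   mean(x[starts[i]:ends[i]]), numeric(1)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
  })
}

#' Integer copy numbers by ploidy grid search
#'
#' Scans candidate ploidies (scale factors turning mean-normalized ratios
#' into copy numbers) and picks the one minimizing the length-weighted
#' squared distance of scaled segment ratios from integers:
#' `sum(n_bins * (ratio * P - round(ratio * P))^2)`. Each grid point is
#' refined by continuous local optimization over its half-step
#' neighbourhood, so ploidies falling between grid points (a profile's mean
#' copy number is rarely a round number) are still found exactly. Ties —
#' in particular the whole-genome-doubling degeneracy, where 2P fits any
#' profile P fits — go to the ploidy closest to 2 (diploid). Segment copy
#' number is `round(mean_ratio * P)`.
#'
#' @param segments Segment table from [segment_ratios()].
#' @param ploidy_grid Candidate ploidies.
#' @return List with `ploidy` and `segments` (input plus integer `cn`).
#' @export
call_integers <- function(segments,
                          ploidy_grid = seq(1.5, 5.0, by = 0.05)) {
  stopifnot(nrow(segments) >= 1)
  r <- segments$mean_ratio
  w <- segments$n_bins
  obj <- function(p) {
    s <- r * p
    sum(w * (s - round(s))^2)
  }
  step <- if (length(ploidy_grid) > 1) min(diff(sort(ploidy_grid))) else 0.05
  refined <- vapply(ploidy_grid, function(p) {
    o <- stats::optimize(obj, c(p - step / 2, p + step / 2), tol = 1e-8)
    c(o$minimum, o$objective)
  }, numeric(2))
  # keep the plain grid points in the running too
  cand_p <- c(ploidy_grid, refined[1, ])
  cand_e <- c(vapply(ploidy_grid, obj, numeric(1)), refined[2, ])
  best <- min(cand_e)
  cand <- cand_p[cand_e <= best + 1e-9]
  ploidy <- cand[which.min(abs(cand - 2))]
  segments$cn <- as.integer(round(r * ploidy))
  list(ploidy = ploidy, segments = segments)
}

#' Reconstruct a single-cell copy-number profile
#'
#' End-to-end per-cell profile: normalization, (optional GC correction),
#' segmentation, ploidy grid search and integer copy-number calling, plus
#' the per-cell noise metrics used by QC.
#'
#' @param counts Per-bin read counts of one cell.
#' @param chrom Chromosome per bin.
#' @param start,end Optional per-bin coordinates (0-based half-open) carried
#'   into SEG/BED output; bin indices are used when absent.
#' @param cell_id Cell identifier.
#' @param gc Optional per-bin GC for correction.
#' @param alpha,min_seg_bins,n_perm,seed Segmentation parameters, see
#'   [segment_ratios()].
#' @param ploidy_grid See [call_integers()].
#' @return Object of class `cn_profile`: ratios, segments with integer CN,
#'   ploidy, per-bin `bins` table, `quality_score`, `mapd`,
#'   `nonzero_bin_fraction`.
#' @export
profile_cell <- function(counts, chrom, start = NULL, end = NULL,
                         cell_id = "cell", gc = NULL, alpha = 0.01,
                         min_seg_bins = 5L, n_perm = 1000L, seed = 1L,
                         ploidy_grid = seq(1.5, 5.0, by = 0.05)) {
  ratios <- normalize_bins(counts, gc)
  segs <- segment_ratios(ratios, chrom, alpha, min_seg_bins, n_perm, seed)
  ic <- call_integers(segs, ploidy_grid)
  if (is.null(start)) {
    idx <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
    start <- (idx - 1); end <- idx
  }
  structure(list(
    cell_id = cell_id,
    bins = data.frame(chrom = chrom, start = start, end = end,
                      count = as.numeric(counts), ratio = ratios,
                      stringsAsFactors = FALSE),
    segments = ic$segments,
    ploidy = ic$ploidy,
    quality_score = quality_score(ratios, chrom),
    mapd = mapd(ratios, chrom),
    nonzero_bin_fraction = mean(counts > 0)
  ), class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile %s: %d bins, %d segment(s), ploidy %.2f, QS %s\n",
              x$cell_id, nrow(x$bins), nrow(x$segments), x$ploidy,
              format(round(x$quality_score, 2))))
  invisible(x)
}

#' QC thresholds for single-cell profiles
#'
#' Inclusion criteria for sequenced cells: total reads above 50,000,
#' total alignment rate above 50%, quality score at least 2.5 (threshold
#' inclusive), and reads across the whole genome — operationalized as a
#' minimum fraction of nonzero bins (guarding against apoptosis-induced
#' profiles).
#'
#' @param min_reads Exclusive lower bound on total reads.
#' @param min_alignment Exclusive lower bound on alignment rate.
#' @param min_qs Inclusive lower bound on the quality score.
#' @param min_nonzero_bin_fraction Inclusive lower bound on the fraction of
#'   bins with at least one read.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads = 50000, min_alignment = 0.5,
                          min_qs = 2.5, min_nonzero_bin_fraction = 0.95) {
  stopifnot(min_reads > 0, min_alignment > 0, min_qs > 0,
            min_nonzero_bin_fraction > 0)
  structure(list(min_reads = min_reads, min_alignment = min_alignment,
                 min_qs = min_qs,
                 min_nonzero_bin_fraction = min_nonzero_bin_fraction),
            class = "qc_thresholds")
}

#' Apply QC to single-cell profiles
#'
#' A cell passes when total reads exceed `min_reads`, alignment rate exceeds
#' `min_alignment`, quality score is at least `min_qs` and the nonzero-bin
#' fraction is at least `min_nonzero_bin_fraction`. Failing criteria are
#' listed per cell.
#'
#' @param profiles A `cn_profile` or list of them.
#' @param meta Per-cell sequencing metadata: `cell_id`, `total_reads`,
#'   `alignment_rate`.
#' @param thresholds A [qc_thresholds()].
#' @return Data frame per cell: the four metrics, `pass`, and
#'   `failed_criteria` (comma-separated; empty when passing).
#' @export
apply_qc <- function(profiles, meta, thresholds = qc_thresholds()) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  stopifnot(all(c("cell_id", "total_reads", "alignment_rate") %in% names(meta)))
  rows <- lapply(profiles, function(p) {
    i <- match(p$cell_id, meta$cell_id)
    if (is.na(i)) stop("no sequencing metadata for cell ", p$cell_id)
    reads <- meta$total_reads[i]
    align <- meta$alignment_rate[i]
    fails <- c(
      if (!(reads > thresholds$min_reads)) "total_reads",
      if (!(align > thresholds$min_alignment)) "alignment_rate",
      if (!(p$quality_score >= thresholds$min_qs)) "quality_score",
      if (!(p$nonzero_bin_fraction >= thresholds$min_nonzero_bin_fraction))
        "nonzero_bin_fraction"
    )
    data.frame(cell_id = p$cell_id, total_reads = reads,
               alignment_rate = align, quality_score = p$quality_score,
               nonzero_bin_fraction = p$nonzero_bin_fraction,
               pass = length(fails) == 0L,
               failed_criteria = paste(fails, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract copy-number alterations from a profile
#'
#' Maximal runs of bins with integer copy number different from the
#' autosomal baseline of 2, at least `min_bins` long, within one
#' chromosome. Runs interrupted by even a single neutral bin are reported
#' as separate alterations (no bridging). Direction is `gain` for CN > 2,
#' `loss` for CN < 2.
#'
#' @param profile A `cn_profile` (with integer CN per segment) or a segment
#'   table carrying `chrom`, `start_bin`, `end_bin`, `cn`.
#' @param min_bins Minimum run length in bins.
#' @param baseline Baseline copy number (2 for autosomes).
#' @return Data frame: `chrom`, `start_bin`, `end_bin`, `n_bins`, `cn`,
#'   `direction`. Zero rows for an all-neutral profile.
#' @export
extract_alterations <- function(profile, min_bins = 5L, baseline = 2L) {
  segs <- if (inherits(profile, "cn_profile")) profile$segments else profile
  stopifnot(all(c("chrom", "start_bin", "end_bin", "cn") %in% names(segs)))
  out <- list()
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_bin), , drop = FALSE]
    # expand to per-bin CN, then take maximal non-neutral runs
    cn_bins <- rep(s$cn, s$end_bin - s$start_bin + 1L)
    off <- s$start_bin[1] - 1L
    r <- rle(cn_bins != baseline)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      len <- r$lengths[i]
      if (len < min_bins) next
      # a run of altered bins may mix CN levels; split by level
      rr <- rle(cn_bins[starts[i]:ends[i]])
      re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
      for (j in seq_along(rr$values)) {
        if (rr$lengths[j] < min_bins) next
        a <- starts[i] + rs[j] - 1L; b <- starts[i] + re[j] - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_bin = a + off, end_bin = b + off,
          n_bins = b - a + 1L, cn = rr$values[j],
          direction = if (rr$values[j] > baseline) "gain" else "loss",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), n_bins = integer(), cn = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Alteration table for a set of profiles
#'
#' Applies [extract_alterations()] to each profile and stacks the results
#' with a `cell_id` column — the input format of [call_clonality()]. Cells
#' with no alterations contribute no rows.
#'
#' @param profiles A `cn_profile` or list of them.
#' @param min_bins,baseline Passed to [extract_alterations()].
#' @return Data frame: `cell_id` plus the [extract_alterations()] columns.
#' @export
alterations_table <- function(profiles, min_bins = 5L, baseline = 2L) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    a <- extract_alterations(p, min_bins = min_bins, baseline = baseline)
    if (!nrow(a)) return(NULL)
    cbind(data.frame(cell_id = p$cell_id, stringsAsFactors = FALSE), a)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(cell_id = character(), chrom = character(),
                      start_bin = integer(), end_bin = integer(),
                      n_bins = integer(), cn = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
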