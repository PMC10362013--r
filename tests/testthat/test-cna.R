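test_that("normalization gives mean-1 ratios and simple worked values", {
  expect_equal(normalize_bins(rep(7, 10)), rep(1, 10))
  expect_equal(normalize_bins(c(100, 50, 100, 150)), c(1, 0.5, 1, 1.5))
  # scale invariance
  set.seed(61)
  x <- rpois(200, 90)
  expect_equal(normalize_bins(x), normalize_bins(10 * x))
  expect_equal(mean(normalize_bins(x)), 1, tolerance = 1e-9)
  expect_error(normalize_bins(rep(0, 5)), "nonzero")
})

test_that("MAPD and quality score behave at the boundaries", {
  expect_equal(mapd(rep(1, 10)), 0)
  expect_equal(quality_score(rep(1, 10)), Inf)
  # alternating 0.8 / 1.2: every adjacent difference is 0.4 -> QS exactly 2.5
  r <- rep(c(0.8, 1.2), 25)
  expect_equal(mapd(r), 0.4)
  expect_equal(quality_score(r), 2.5)
  # differences are not taken across chromosome boundaries
  r2 <- c(1, 1, 5, 5)
  expect_equal(mapd(r2, chrom = c("a", "a", "b", "b")), 0)
  expect_error(mapd(1, chrom = "a"), "2 bins")
})

test_that("quality score falls below 2.5 only at very low coverage", {
  # Poisson noise: MAPD ~ 0.674 * sqrt(2/m), so QS < 2.5 requires roughly
  # m < 6 reads/bin; at 25 reads/bin QS sits well above the threshold
  qs_at <- function(m, seed) {
    set.seed(seed)
    mean(vapply(1:20, function(i) {
      quality_score(normalize_bins(rpois(2000, m)))
    }, numeric(1)))
  }
  expect_gt(qs_at(25, 62), 2.5)
  expect_lt(qs_at(4, 63), 2.5)
})

test_that("segmentation finds no breakpoints in flat profiles", {
  segs <- segment_ratios(rep(1, 100), rep("c1", 100), n_perm = 100, seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bin, 1)
  expect_equal(segs$end_bin, 100)
})

test_that("a noiseless step is split exactly at the boundary", {
  x <- c(rep(1, 50), rep(0.5, 50))
  segs <- segment_ratios(x, rep("c1", 100), n_perm = 200, seed = 2)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end_bin[1], 50)
  expect_equal(segs$mean_ratio, c(1, 0.5))
})

test_that("breakpoints are recovered within 2 bins under Poisson noise", {
  # CN template {2,1,2,3} over 4 x 50 bins at 200 reads/bin
  cn <- rep(c(2, 1, 2, 3), each = 50)
  hit <- vapply(1:20, function(s) {
    set.seed(700 + s)
    counts <- rpois(200, 200 * cn / 2)
    segs <- segment_ratios(normalize_bins(counts), rep("c1", 200),
                           n_perm = 200, seed = s)
    cuts <- segs$end_bin[-nrow(segs)]
    length(cuts) == 3 && all(abs(sort(cuts) - c(50, 100, 150)) <= 2)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("segmentation of segment means is idempotent", {
  x <- c(rep(1, 40), rep(0.5, 30), rep(1.5, 30))
  s1 <- segment_ratios(x, rep("c1", 100), n_perm = 200, seed = 3)
  expanded <- rep(s1$mean_ratio, s1$n_bins)
  s2 <- segment_ratios(expanded, rep("c1", 100), n_perm = 200, seed = 4)
  expect_equal(s2$start_bin, s1$start_bin)
  expect_equal(s2$end_bin, s1$end_bin)
})

test_that("ploidy grid search hits the worked examples", {
  seg <- function(r) data.frame(chrom = "c1",
                                start_bin = seq_along(r) * 10 - 9,
                                end_bin = seq_along(r) * 10,
                                n_bins = 10, mean_ratio = r)
  d <- call_integers(seg(1.0))
  expect_equal(d$ploidy, 2.0)
  expect_equal(d$segments$cn, 2L)
  t1 <- call_integers(seg(c(1.0, 0.5, 1.5)))
  expect_equal(t1$ploidy, 2.0)
  expect_equal(t1$segments$cn, c(2L, 1L, 3L))
  t2 <- call_integers(seg(c(1.0, 0.75, 1.25)))
  expect_equal(t2$ploidy, 4.0)
  expect_equal(t2$segments$cn, c(4L, 3L, 5L))
})

test_that("QC applies every inclusion rule with the stated boundaries", {
  gs_counts <- rep(100, 60)
  p <- profile_cell(gs_counts, rep(c("c1", "c2"), each = 30), n_perm = 50)
  meta <- data.frame(cell_id = "cell", total_reads = 49000,
                     alignment_rate = 0.9)
  r1 <- apply_qc(p, meta)
  expect_false(r1$pass)
  expect_match(r1$failed_criteria, "total_reads")
  # boundary case: reads just above 50k, alignment just above 50%, QS
  # exactly 2.5 (inclusive), full coverage -> pass
  p2 <- p
  p2$quality_score <- 2.5
  meta2 <- data.frame(cell_id = "cell", total_reads = 50001,
                      alignment_rate = 0.51)
  expect_true(apply_qc(p2, meta2)$pass)
  expect_error(apply_qc(p, data.frame(cell_id = "other", total_reads = 1,
                                      alignment_rate = 1)),
               "metadata")
})

test_that("a tabulated five-cell QC fixture keeps exactly the compliant three", {
  mk <- function(id, qs, cov) {
    p <- profile_cell(rep(100, 40), rep("c1", 40), n_perm = 50,
                      cell_id = id)
    p$quality_score <- qs
    p$nonzero_bin_fraction <- cov
    p
  }
  profs <- list(mk("a", 10, 1), mk("b", 2.4, 1), mk("c", 3, 1),
                mk("d", 5, 0.8), mk("e", 2.5, 0.99))
  meta <- data.frame(cell_id = c("a", "b", "c", "d", "e"),
                     total_reads = c(8e4, 8e4, 6e4, 9e4, 7e4),
                     alignment_rate = c(0.9, 0.9, 0.8, 0.9, 0.7))
  qc <- apply_qc(profs, meta)
  expect_equal(qc$cell_id[qc$pass], c("a", "c", "e"))
})

test_that("alteration extraction takes maximal non-neutral runs, no bridging", {
  seg <- function(cn, nb) {
    ends <- cumsum(nb)
    data.frame(chrom = "c1", start_bin = ends - nb + 1L, end_bin = ends,
               n_bins = nb, cn = cn)
  }
  expect_equal(nrow(extract_alterations(seg(2L, 50L))), 0)
  one <- extract_alterations(seg(c(2L, 1L, 2L), c(20L, 10L, 20L)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_bin, 21)
  expect_equal(one$end_bin, 30)
  expect_equal(one$direction, "loss")
  # two loss runs split by a single neutral bin stay separate
  two <- extract_alterations(seg(c(1L, 2L, 1L), c(10L, 1L, 10L)))
  expect_equal(nrow(two), 2)
  expect_equal(two$direction, c("loss", "loss"))
  # short runs below min_bins are dropped
  expect_equal(nrow(extract_alterations(seg(c(2L, 3L, 2L), c(20L, 4L, 20L)))),
               0)
})

test_that("noiseless synthetic genomes are recovered exactly end to end", {
  gg <- clonal_fixture_genomes(n_clonal = 2, n_flat = 1, seed = 8)
  profs <- profile_all(gg$bin_counts, n_perm = 300, seed = 6)
  truth <- sclc_alteration_template(losses = c("10q", "13q", "17p"),
                                    gains = character(0))
  truth <- truth[order(truth$chrom, truth$start_bin), ]
  for (id in gg$truth$cell_id) {
    p <- profs[[id]]
    a <- extract_alterations(p)
    if (gg$truth$clonal[gg$truth$cell_id == id]) {
      # mean copy number: 60 of 2200 bins at CN 1, the rest diploid
      expect_equal(p$ploidy, (2140 * 2 + 60 * 1) / 2200, tolerance = 1e-6)
      a <- a[order(a$chrom, a$start_bin), ]
      expect_equal(a$chrom, truth$chrom)
      expect_equal(a$start_bin, truth$start_bin)
      expect_equal(a$end_bin, truth$end_bin)
      expect_equal(a$cn, truth$cn)
    } else {
      expect_equal(p$ploidy, 2)
      expect_equal(nrow(a), 0)
    }
    expect_equal(p$quality_score, Inf)
  }
})

test_that("profiles are invariant to count scaling", {
  set.seed(64)
  counts <- rpois(150, 120)
  chrom <- rep(c("c1", "c2", "c3"), each = 50)
  p1 <- profile_cell(counts, chrom, n_perm = 100, seed = 11)
  p2 <- profile_cell(counts * 7, chrom, n_perm = 100, seed = 11)
  expect_equal(p1$segments$mean_ratio, p2$segments$mean_ratio)
  expect_equal(p1$segments$cn, p2$segments$cn)
  expect_equal(p1$ploidy, p2$ploidy)
})
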