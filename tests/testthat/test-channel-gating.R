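test_that("static gates pass user thresholds through unchanged", {
  g <- fit_gates(method = "static",
                 thresholds = c(dapi = 120, ck = 100, vim = 100,
                                cd45cd31 = 100))
  expect_equal(g$thresholds$ck, 100)
  expect_equal(g$thresholds$dapi, 120)
  expect_true(is.na(g$thresholds$slide_id))
})

test_that("k-sigma gates equal median + k * mad of the background", {
  set.seed(31)
  bg <- data.frame(dapi = rnorm(2000, 500, 20), ck = rnorm(2000, 50, 10),
                   vim = rnorm(2000, 50, 10), cd45cd31 = rnorm(2000, 50, 10))
  g <- fit_gates(bg, method = "k_sigma_background", k = 5)
  expect_equal(g$thresholds$ck, median(bg$ck) + 5 * mad(bg$ck))
  # N(50, 10) background: threshold lands near 50 + 5 * 10
  expect_lt(abs(g$thresholds$ck - 100), 5)
  expect_error(fit_gates(bg[0, ], method = "k_sigma_background"), "non-empty")
})

test_that("k-sigma gates are computed per slide when backgrounds differ", {
  set.seed(32)
  bg <- data.frame(
    slide_id = rep(c("A", "B"), each = 1000),
    dapi = rnorm(2000, 500, 20),
    ck = c(rnorm(1000, 50, 10), rnorm(1000, 150, 10)),
    vim = rnorm(2000, 50, 10), cd45cd31 = rnorm(2000, 50, 10))
  g <- fit_gates(bg, method = "k_sigma_background", k = 5)
  th_a <- g$thresholds$ck[g$thresholds$slide_id == "A"]
  th_b <- g$thresholds$ck[g$thresholds$slide_id == "B"]
  expect_lt(abs(th_a - 100), 6)
  expect_lt(abs(th_b - 200), 6)
})

test_that("classification reproduces the eight-group truth table", {
  for (assay in c("landscape", "epcam")) {
    markers <- assay_markers(assay)
    combos <- expand.grid(m1 = c(TRUE, FALSE), m2 = c(TRUE, FALSE),
                          m3 = c(TRUE, FALSE))
    ev <- data.frame(cell_id = sprintf("c%d", seq_len(nrow(combos))),
                     sample_id = "S", dapi = 1000)
    for (i in seq_along(markers)) {
      ev[[markers[i]]] <- ifelse(combos[[i]], 1000, 10)
    }
    calls <- classify_events(ev, fit_gates(method = "static", assay = assay),
                             assay)
    # brute-force expectation: look the pattern up by hand from markers
    expected <- apply(combos, 1, function(row) {
      pos <- markers[as.logical(row)]
      hit <- vapply(assay_groups(assay), function(g) {
        patt <- liquidctc:::group_marker_pattern(g, assay)[1, ]
        identical(unname(patt[markers]), unname(as.logical(row)))
      }, logical(1))
      names(hit)[hit]
    })
    expect_equal(calls$group, unname(expected))
    expect_equal(sort(unique(calls$group)), sort(assay_groups(assay)))
  }
})

test_that("DAPI-negative events are flagged, not classified", {
  ev <- data.frame(cell_id = c("a", "b"), sample_id = "S",
                   dapi = c(10, 1000), ck = 1000, vim = 10, cd45cd31 = 10)
  calls <- classify_events(ev, fit_gates(method = "static"), "landscape")
  expect_false(calls$dapi_pass[1])
  expect_true(is.na(calls$group[1]))
  expect_equal(calls$group[2], "CK")
})

test_that("enumeration reproduces the UM-001 worked example", {
  enum <- enumerate_cells(um001_calls(), um001_meta(), assay = "epcam")
  expect_equal(sum(enum$count), 178)
  expect_equal(enum$count[enum$group == "CK|EpCAM"], 69)
  expect_equal(enum$count[enum$group == "CK"], 59)
  share <- ctc_share(enum, ctc_groups = c("CK", "CK|EpCAM"))
  expect_equal(share$ctc_count, 128)
  expect_equal(round(100 * share$share, 1), 71.9)
  # proportions sum to 1
  expect_equal(sum(enum$proportion), 1, tolerance = 1e-9)
})

test_that("empty call table enumerates to all zeros", {
  calls <- um001_calls()[0, ]
  enum <- enumerate_cells(calls, um001_meta(), assay = "epcam")
  expect_equal(nrow(enum), 8)
  expect_true(all(enum$count == 0))
  expect_true(all(enum$proportion == 0))
})

test_that("per-mL and per-million normalizations are arithmetic", {
  calls <- data.frame(cell_id = sprintf("c%d", 1:10), sample_id = "S",
                      group = "CK", dapi_pass = TRUE)
  meta <- data.frame(sample_id = "S", cohort = "SCLC", volume_ml = 2,
                     nucleated_cells_slide_1 = 3e6,
                     nucleated_cells_slide_2 = 2e6)
  enum <- enumerate_cells(calls, meta)
  expect_equal(sum(enum$cells_per_ml), 5)
  expect_equal(enum$cells_per_million[enum$group == "CK"], 10 / 5e6 * 1e6)
  expect_error(enumerate_cells(calls, transform(meta, volume_ml = NA)),
               "volume")
})

test_that("group counts are conserved and CK counts fall as the gate rises", {
  co <- small_cohort(seed = 13)
  gates_lo <- fit_gates(method = "static")
  calls <- classify_events(co$events, gates_lo, "landscape")
  expect_equal(sum(!is.na(calls$group)), nrow(co$events))
  enum <- enumerate_cells(calls, co$meta)
  expect_equal(sum(enum$count), nrow(co$events))

  ck_groups <- c("CK", "CK|Vim", "CK|(CD45/CD31)", "CK|Vim|(CD45/CD31)")
  count_ck <- function(th) {
    g <- fit_gates(method = "static",
                   thresholds = c(dapi = 150, ck = th, vim = 150,
                                  cd45cd31 = 150))
    cl <- classify_events(co$events, g, "landscape")
    sum(cl$group %in% ck_groups, na.rm = TRUE)
  }
  counts <- vapply(c(100, 200, 400, 600, 1000), count_ck, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cohort comparison flags the CK difference and handles errors", {
  co <- small_cohort(seed = 17)
  calls <- classify_events(co$events, fit_gates(method = "static"), "landscape")
  enum <- enumerate_cells(calls, co$meta)
  res <- compare_cohorts(enum)
  expect_equal(nrow(res), 8)
  expect_lt(res$p_value[res$group == "CK"], 0.001)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # BH adjustment is monotone and never smaller than raw p
  res_bh <- compare_cohorts(enum, p_adjust = "BH")
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value - 1e-12))
  one <- enum[enum$cohort == "SCLC", ]
  expect_error(compare_cohorts(one), "two")
})
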