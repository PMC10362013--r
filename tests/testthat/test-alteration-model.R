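test_that("engineered 90-feature block design selects exactly 56 features", {
  x <- simulate_correlated_features(n_cells = 1000, n_pairs = 34,
                                    n_independent = 22, seed = 71)
  sel <- select_features(x, corr_threshold = 0.9)
  expect_length(sel, 56)
  # one representative per duplicate pair, all independents kept
  expect_equal(sum(grepl("^indep", sel)), 22)
  expect_equal(sum(grepl("^dup", sel)), 34)
})

test_that("independent features are all retained; duplicates collapse", {
  set.seed(72)
  x <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  expect_setequal(select_features(x), colnames(x))
  # two identical columns: exactly one survives, name order breaks the tie
  x2 <- cbind(x, f00 = x[, "f01"])
  sel <- select_features(x2)
  expect_length(sel, 10)
  expect_true(xor("f00" %in% sel, "f01" %in% sel))
  expect_true("f00" %in% sel)  # equal variance -> lexicographically first
})

test_that("selection is idempotent and order-invariant", {
  x <- simulate_correlated_features(n_cells = 400, n_pairs = 10,
                                    n_independent = 8, seed = 73)
  sel <- select_features(x)
  expect_setequal(select_features(x[, sel]), sel)
  perm <- sample(ncol(x))
  expect_setequal(select_features(x[, perm]), sel)
})

test_that("the highest-variance member represents each correlation group", {
  set.seed(74)
  base <- rnorm(300)
  x <- cbind(lowvar = base + rnorm(300, sd = 0.05),
             hivar = 3 * base + rnorm(300, sd = 0.05),
             other = rnorm(300))
  expect_setequal(select_features(x), c("hivar", "other"))
})

test_that("degenerate feature-selection inputs are handled", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(select_features(x[1, , drop = FALSE]), "at least 2")
  x2 <- cbind(x, const = 1)
  expect_warning(sel <- select_features(x2), "constant")
  expect_setequal(sel, c("a", "b"))
})

test_that("label permutation gives chance-level AUC", {
  sim <- simulate_coupled_cells(120, 120, seed = 75)
  aucs <- vapply(1:5, function(s) {
    set.seed(800 + s)
    y <- sample(sim$clonal)
    train_eval(sim$features, y, n_folds = 5, n_trees = 200,
               seed = s)$cv_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("a perfectly separating feature gives AUC 1", {
  set.seed(76)
  x <- cbind(sep = c(rnorm(50, 10), rnorm(50, -10)),
             noise = rnorm(100))
  y <- rep(c(TRUE, FALSE), each = 50)
  ev <- train_eval(x, y, n_folds = 5, n_trees = 200, seed = 3)
  expect_equal(ev$cv_auc, 1)
})

test_that("pooled AUC agrees with the independent rank formula", {
  sim <- simulate_coupled_cells(80, 80, seed = 77)
  ev <- train_eval(sim$features, sim$clonal, n_folds = 4, n_trees = 200,
                   seed = 5)
  expect_equal(ev$cv_auc, rank_auc(sim$clonal, ev$scores), tolerance = 1e-10)
})

test_that("AUC is invariant to monotone transforms of a feature", {
  sim <- simulate_coupled_cells(100, 100, seed = 78)
  x <- sim$features
  x2 <- x
  x2[, "CK.f01"] <- exp(x2[, "CK.f01"])  # strictly monotone
  a1 <- train_eval(x, sim$clonal, n_folds = 3, n_trees = 200, seed = 7)$cv_auc
  a2 <- train_eval(x2, sim$clonal, n_folds = 3, n_trees = 200, seed = 7)$cv_auc
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("training requires both classes and is seed-deterministic", {
  sim <- simulate_coupled_cells(50, 50, seed = 79)
  expect_error(train_eval(sim$features, rep(TRUE, 100)), "both classes")
  e1 <- train_eval(sim$features, sim$clonal, n_folds = 3, n_trees = 100,
                   seed = 11)
  e2 <- train_eval(sim$features, sim$clonal, n_folds = 3, n_trees = 100,
                   seed = 11)
  expect_identical(e1$cv_auc, e2$cv_auc)
  expect_identical(e1$scores, e2$scores)
})

test_that("importances are normalized and channel-attributed", {
  sim <- simulate_coupled_cells(150, 150, seed = 80)
  ev <- train_eval(sim$features, sim$clonal, n_folds = 3, n_trees = 300,
                   seed = 13)
  expect_equal(sum(ev$importance), 1, tolerance = 1e-9)
  rk <- rank_importance(ev, top_k = 20)
  expect_equal(rk$ranking$channel,
               sub("\\..*$", "", rk$ranking$feature))
  expect_equal(sum(rk$top_channel_counts), 20)
  # informative CK features dominate the top of the ranking
  expect_gte(rk$top_channel_counts[["CK"]], 8)
})

test_that("a model trained on CK-only signal attributes the top to CK", {
  coup <- pheno_geno_coupling(
    informative_features = data.frame(feature = sprintf("CK.f%02d", 1:10),
                                      shift = 2))
  sim <- simulate_coupled_cells(120, 120, coupling = coup, seed = 81)
  ev <- train_eval(sim$features, sim$clonal, n_folds = 3, n_trees = 300,
                   seed = 17)
  rk <- rank_importance(ev, top_k = 10)
  expect_equal(rk$ranking$channel[1:10], rep("CK", 10))
})

test_that("CK features lead the top 20 across seeds under the default coupling", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_coupled_cells(150, 150, seed = 900 + s)
    ev <- train_eval(sim$features, sim$clonal, n_folds = 3, n_trees = 200,
                     seed = s)
    counts <- rank_importance(ev, top_k = 20)$top_channel_counts
    ck <- if ("CK" %in% names(counts)) counts[["CK"]] else 0L
    ck >= max(counts)
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("informative features outrank noise features on average", {
  sim <- simulate_coupled_cells(200, 200, seed = 82)
  ev <- train_eval(sim$features, sim$clonal, n_folds = 3, n_trees = 300,
                   seed = 19)
  rk <- rank_importance(ev, top_k = 20)$ranking
  inf <- pheno_geno_coupling()$informative_features$feature
  mean_rank_inf <- mean(rk$rank[rk$feature %in% inf])
  mean_rank_noise <- mean(rk$rank[!rk$feature %in% inf])
  expect_lt(mean_rank_inf, mean_rank_noise)
})
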