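#' Stratifier configuration
#'
#' Parameters of the patient-level classification procedure: the range of
#' cluster counts scanned, the forest size, the count normalization fed to
#' the forest, and the seed.
#'
#' @param k_min,k_max Smallest and largest cluster count scanned (the scan
#'   is capped at the number of events).
#' @param n_trees Trees per random forest.
#' @param normalization `"per_ml"` or `"per_million"`.
#' @param pruning Whether to run importance-ranked incremental pruning after
#'   the cluster-count scan.
#' @param seed Integer seed; every forest fit derives its RNG state from it.
#' @return An object of class `stratifier_config`.
#' @export
stratifier_config <- function(k_min = 2L, k_max = 100L, n_trees = 1000L,
                              normalization = c("per_ml", "per_million"),
                              pruning = TRUE, seed = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(k_min >= 2L, k_min <= k_max, n_trees >= 1L)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_trees = as.integer(n_trees), normalization = normalization,
                 pruning = isTRUE(pruning), seed = as.integer(seed)),
            class = "stratifier_config")
}

#' Build the morphological hierarchy of rare-cell events
#'
#' Agglomerative (Ward) clustering over the z-scored morphometric feature
#' vectors of all rare events, Euclidean distance. Cutting the tree at k
#' yields the k morphological clusters whose per-sample cell counts feed the
#' patient-level classifier. Constant features are dropped with a warning.
#'
#' @param events Event table; morphometric columns are auto-detected as the
#'   columns named by [morpho_feature_names()] conventions (prefix + `.f`)
#'   unless `feature_cols` is given.
#' @param feature_cols Optional character vector of feature columns.
#' @return Object of class `rare_cell_hierarchy`: list with the `hclust`
#'   tree, `cell_id`, `sample_id` and the feature names used.
#' @export
build_hierarchy <- function(events, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- grep("^(CK|Vim|CD45CD31|DAPI)\\.", names(events),
                         value = TRUE)
  }
  if (!length(feature_cols)) stop("no morphometric feature columns found")
  if (nrow(events) < 2L) stop("need at least 2 events to build a hierarchy")
  x <- as.matrix(events[, feature_cols, drop = FALSE])
  if (any(!is.finite(x))) stop("morphometric features must be finite")
  z <- zscore_columns(x)
  hc <- hclust(dist(z), method = "ward.D2")
  structure(list(hclust = hc,
                 cell_id = events$cell_id,
                 sample_id = events$sample_id,
                 features = colnames(z)),
            class = "rare_cell_hierarchy")
}

#' Per-sample cluster count matrix at a tree cut
#'
#' Cuts the morphological hierarchy into `k` clusters and tabulates each
#' sample's events per cluster, normalized to cells per mL or cells per
#' million nucleated cells. Rows cover every sample in `meta` (zero-filled).
#'
#' @param hierarchy A [build_hierarchy()] result.
#' @param k Number of clusters (2 <= k <= number of events).
#' @param meta Sample metadata (`sample_id`, `volume_ml`, slide nucleated
#'   counts for per-million).
#' @param normalization `"per_ml"`, `"per_million"` or `"count"`.
#' @return Numeric matrix, samples x k, rownames = sample ids.
#' @export
counts_at_k <- function(hierarchy, k, meta,
                        normalization = c("per_ml", "per_million", "count")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(hierarchy, "rare_cell_hierarchy"))
  n_ev <- length(hierarchy$cell_id)
  if (k < 2L || k > n_ev) stop("k must be in [2, number of events]")
  cl <- cutree(hierarchy$hclust, k = k)
  m <- matrix(0, nrow(meta), k,
              dimnames = list(meta$sample_id, paste0("cluster_", seq_len(k))))
  tab <- table(hierarchy$sample_id, cl)
  m[rownames(tab), as.integer(colnames(tab))] <- tab
  denom <- switch(normalization,
    count = rep(1, nrow(meta)),
    per_ml = meta$volume_ml,
    per_million = (meta$nucleated_cells_slide_1 +
                     meta$nucleated_cells_slide_2) / 1e6)
  m / denom
}

# Seeded forest fit; OOB error read from the last row of err.rate.
fit_forest <- function(x, y, n_trees, seed) {
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, ntree = n_trees, importance = FALSE)
}

oob_error <- function(fit) unname(fit$err.rate[nrow(fit$err.rate), "OOB"])

#' Scan cluster counts and select the minimum-OOB-error model
#'
#' For each cluster count k from `k_min` to `k_max` (capped at the number of
#' events), cuts the hierarchy at k, builds the normalized per-sample count
#' matrix, fits a seeded random forest of `n_trees` trees to predict the
#' cohort label, and records its out-of-bag (OOB) error. The chosen k
#' minimizes OOB error, ties resolved to the smallest k.
#'
#' @param hierarchy A [build_hierarchy()] result.
#' @param meta Sample metadata with a `cohort` column holding both classes.
#' @param config A [stratifier_config()].
#' @return List with `oob_error_by_k` (named numeric) and `chosen_k`.
#' @export
scan_k <- function(hierarchy, meta, config = stratifier_config()) {
  labels <- factor(meta$cohort)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("both classes must be present in meta$cohort")
  }
  k_hi <- min(config$k_max, length(hierarchy$cell_id))
  ks <- seq.int(config$k_min, k_hi)
  oob <- vapply(ks, function(k) {
    x <- counts_at_k(hierarchy, k, meta, config$normalization)
    oob_error(fit_forest(x, labels, config$n_trees, config$seed + k))
  }, numeric(1))
  names(oob) <- ks
  chosen_k <- ks[which.min(oob)]   # which.min takes the first (smallest k)
  list(oob_error_by_k = oob, chosen_k = chosen_k)
}

#' Importance pruning and final model report
#'
#' Fits the forest at the chosen cluster count, ranks clusters by importance
#' (mean decrease in impurity by default), then incrementally refits forests
#' on the top-m most important clusters for m = 2..k, selecting the m with
#' the lowest OOB error (ties to the smallest m). The final model's
#' out-of-bag votes give per-sample predictions and the confusion matrix.
#'
#' @param hierarchy A [build_hierarchy()] result.
#' @param meta Sample metadata with `cohort`.
#' @param config A [stratifier_config()].
#' @param scan Optional result of [scan_k()] (recomputed when `NULL`).
#' @param importance `"impurity"` (mean decrease in Gini) or `"permutation"`
#'   (mean decrease in accuracy).
#' @return Object of class `stratifier_result`: `oob_error_by_k`,
#'   `chosen_k`, `importances`, `pruned_clusters`, `oob_error_by_m`,
#'   `chosen_m`, `predictions` (per-sample OOB prediction), `confusion`,
#'   `oob_accuracy`, and the config.
#' @export
prune_and_finalize <- function(hierarchy, meta, config = stratifier_config(),
                               scan = NULL,
                               importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  if (is.null(scan)) scan <- scan_k(hierarchy, meta, config)
  labels <- factor(meta$cohort)
  k <- scan$chosen_k
  x <- counts_at_k(hierarchy, k, meta, config$normalization)
  set.seed(config$seed + k)
  full <- randomForest::randomForest(x = x, y = labels, ntree = config$n_trees,
                                     importance = (importance == "permutation"))
  imp_col <- if (importance == "permutation") "MeanDecreaseAccuracy"
             else "MeanDecreaseGini"
  imp_mat <- randomForest::importance(full,
                                      type = if (importance == "permutation") 1 else 2)
  imp <- imp_mat[, 1]
  names(imp) <- rownames(imp_mat)
  ord <- order(-imp, names(imp))       # ties broken by cluster name

  if (config$pruning && k > 2L) {
    ms <- seq.int(2L, k)
    oob_m <- vapply(ms, function(m) {
      keep <- sort(ord[seq_len(m)])    # original column order preserved
      xm <- x[, keep, drop = FALSE]
      oob_error(fit_forest(xm, labels, config$n_trees, config$seed + k))
    }, numeric(1))
    names(oob_m) <- ms
    chosen_m <- ms[which.min(oob_m)]
  } else {
    oob_m <- setNames(oob_error(full), as.character(k))
    chosen_m <- k
  }
  keep <- sort(ord[seq_len(chosen_m)])
  final <- fit_forest(x[, keep, drop = FALSE], labels, config$n_trees,
                      config$seed + k)
  pred <- final$predicted
  confusion <- table(truth = labels, predicted = pred)
  structure(list(
    oob_error_by_k = scan$oob_error_by_k,
    chosen_k = k,
    importances = sort(imp, decreasing = TRUE),
    pruned_clusters = colnames(x)[keep],
    oob_error_by_m = oob_m,
    chosen_m = chosen_m,
    predictions = data.frame(sample_id = meta$sample_id,
                             truth = as.character(labels),
                             predicted = as.character(pred),
                             stringsAsFactors = FALSE),
    confusion = confusion,
    oob_accuracy = mean(pred == labels),
    config = config
  ), class = "stratifier_result")
}

#' Full patient-level stratification pipeline
#'
#' Convenience wrapper: builds the morphological hierarchy over the events,
#' scans cluster counts with OOB-error model selection, prunes by
#' importance, and reports per-sample OOB predictions.
#'
#' @inheritParams build_hierarchy
#' @inheritParams scan_k
#' @param feature_cols Optional morphometric column names.
#' @return A `stratifier_result` (see [prune_and_finalize()]).
#' @export
stratify_patients <- function(events, meta, config = stratifier_config(),
                              feature_cols = NULL) {
  h <- build_hierarchy(events, feature_cols)
  scan <- scan_k(h, meta, config)
  prune_and_finalize(h, meta, config, scan)
}

#' @export
print.stratifier_result <- function(x, ...) {
  cat("Patient-level stratifier\n")
  cat(sprintf("  chosen k: %d (OOB error %.3f), pruned to %d cluster(s)\n",
              x$chosen_k, x$oob_error_by_k[as.character(x$chosen_k)],
              x$chosen_m))
  cat(sprintf("  OOB accuracy: %.1f%%\n", 100 * x$oob_accuracy))
  print(x$confusion)
  invisible(x)
}
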