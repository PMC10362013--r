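#' Correlation-based feature selection
#'
#' Groups features whose pairwise Pearson correlation exceeds the threshold
#' in absolute value — grouping is by connected components of the
#' |r| > threshold graph, so correlation chains collapse into one group —
#' and keeps the highest-variance feature of each group as its
#' representative (ties broken by feature name). Guards against
#' multicollinearity before model fitting. Constant features are dropped
#' with a warning.
#'
#' @param x Numeric matrix or data frame, cells x features, named columns.
#' @param corr_threshold Features with |r| strictly above this are grouped.
#' @param grouping `"components"` (default: transitive closure) or
#'   `"greedy"` (pairwise: scan features by descending variance, keep a
#'   feature unless it correlates above threshold with an already-kept one).
#' @return Character vector of selected feature names, in original column
#'   order. Invariant to column permutation.
#' @export
select_features <- function(x, corr_threshold = 0.9,
                            grouping = c("components", "greedy")) {
  grouping <- match.arg(grouping)
  stopifnot(corr_threshold > 0, corr_threshold < 1)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 cells to estimate correlations")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  v <- apply(x, 2, var)
  constant <- !is.finite(v) | v == 0
  if (any(constant)) {
    warning(sprintf("dropping %d constant feature(s)", sum(constant)),
            call. = FALSE)
    x <- x[, !constant, drop = FALSE]
    v <- v[!constant]
  }
  nm <- colnames(x)
  cm <- abs(cor(x))
  diag(cm) <- 0

  if (grouping == "greedy") {
    ord <- order(-v, nm)
    kept <- character(0)
    for (f in nm[ord]) {
      if (!length(kept) || all(cm[f, kept] <= corr_threshold)) {
        kept <- c(kept, f)
      }
    }
    return(nm[nm %in% kept])
  }

  adj <- cm > corr_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  kept <- vapply(split(nm, comp), function(members) {
    vi <- v[members]
    members[order(-vi, members)][1]
  }, character(1))
  nm[nm %in% kept]
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the rank statistic: the
#' probability that a positive outranks a negative, with ties counted half.
#'
#' @param labels Logical or two-level vector (`TRUE`/second level = positive).
#' @param scores Numeric predictions.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(labels, scores) {
  y <- if (is.logical(labels)) labels else labels == levels(factor(labels))[2]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: each class split as evenly as possible.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated single-cell alteration classifier
#'
#' Trains a random forest to predict the binary clonally-altered status of
#' single cells from their phenotypic features, evaluated by stratified
#' k-fold cross-validation with pooled out-of-fold predictions. The AUC is
#' computed on the pooled predicted class probabilities; per-fold AUCs and
#' ROC points are reported, and a forest fit on all cells provides the
#' importance ranking.
#'
#' @param x Feature matrix (cells x features), typically after
#'   [select_features()].
#' @param labels Logical (or two-level) clonal status per cell.
#' @param n_folds Cross-validation folds.
#' @param n_trees Trees per forest.
#' @param seed Integer seed (fold assignment and every forest).
#' @return Object of class `alteration_model_eval`: `cv_auc`, `fold_auc`,
#'   `roc` (data frame of specificity/sensitivity points), `scores`
#'   (pooled out-of-fold probabilities), `importance` (named, normalized to
#'   sum 1), `model` (full-data forest).
#' @export
train_eval <- function(x, labels, n_folds = 5L, n_trees = 1000L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(if (is.logical(labels)) ifelse(labels, "altered", "not_altered")
              else as.character(labels),
              levels = if (is.logical(labels)) c("not_altered", "altered")
                       else sort(unique(as.character(labels))))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  pos <- levels(y)[2]
  with_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    scores <- numeric(length(y))
    fold_auc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      set.seed(seed + f)
      fit <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                        ntree = n_trees)
      p <- predict(fit, x[!tr, , drop = FALSE], type = "prob")[, pos]
      scores[!tr] <- p
      fold_auc[f] <- rank_auc(y[!tr] == pos, p)
    }
    roc_obj <- pROC::roc(response = y, predictor = scores, levels = levels(y),
                         direction = "<", quiet = TRUE)
    cv_auc <- as.numeric(pROC::auc(roc_obj))
    set.seed(seed)
    full <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
    imp <- randomForest::importance(full, type = 2)[, 1]
    imp <- imp / sum(imp)
    structure(list(
      cv_auc = cv_auc,
      fold_auc = fold_auc,
      roc = data.frame(specificity = roc_obj$specificities,
                       sensitivity = roc_obj$sensitivities),
      scores = scores,
      labels = y,
      importance = imp,
      model = full,
      n_folds = n_folds
    ), class = "alteration_model_eval")
  })
}

#' @export
print.alteration_model_eval <- function(x, ...) {
  cat(sprintf("alteration model: %d-fold CV AUC %.3f (folds %s)\n",
              x$n_folds, x$cv_auc,
              paste(sprintf("%.2f", x$fold_auc), collapse = ", ")))
  invisible(x)
}

#' Channel-attributed importance ranking
#'
#' Sorts feature importances in decreasing order, tags every feature with
#' the channel encoded by its name prefix (the part before the first dot,
#' e.g. `CK`, `Vim`), and counts channels among the top k.
#'
#' @param eval An [train_eval()] result, or a named importance vector.
#' @param top_k Size of the head reported in `top_channel_counts`.
#' @return List with `ranking` (data frame: `feature`, `importance`,
#'   `channel`, `rank`) and `top_channel_counts` (named integer vector).
#' @export
rank_importance <- function(eval, top_k = 20L) {
  imp <- if (inherits(eval, "alteration_model_eval")) eval$importance else eval
  stopifnot(is.numeric(imp), !is.null(names(imp)))
  ord <- order(-imp, names(imp))
  ranking <- data.frame(
    feature = names(imp)[ord],
    importance = unname(imp[ord]),
    channel = sub("\\..*$", "", names(imp)[ord]),
    rank = seq_along(imp),
    stringsAsFactors = FALSE
  )
  k <- min(top_k, nrow(ranking))
  top <- table(ranking$channel[seq_len(k)])
  list(ranking = ranking,
       top_channel_counts = sort(setNames(as.integer(top), names(top)),
                                 decreasing = TRUE))
}
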