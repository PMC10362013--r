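#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. When `n1 * n2` does not
#' exceed `exact_limit` the null distribution of the rank sum is computed
#' exactly over all \eqn{\binom{n_1+n_2}{n_1}} assignments of the observed
#' (mid-)ranks — so the exact branch is valid in the presence of ties —
#' by dynamic programming over the rank multiset. Larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' The two-sided exact p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`
#' where `W` is the rank sum of the first sample.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_limit Use the exact branch when `length(x) * length(y)` is
#'   at most this.
#' @return List with `statistic` (the U statistic of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
mann_whitney_u <- function(x, y, exact_limit = 10000) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])              # rank sum of x
  u <- w - n1 * (n1 + 1) / 2            # U statistic of x

  if (n1 * n2 <= exact_limit) {
    # Exact null: distribution of the sum of n1 ranks drawn without
    # replacement from the observed midrank multiset. Midranks are halves,
    # so double them to land on an integer lattice.
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    # dp[[j]][s + 1] = number of ways to choose j ranks summing to s
    dp <- vector("list", n1 + 1L)
    dp[[1L]] <- c(1, numeric(tot))
    for (j in seq_len(n1)) dp[[j + 1L]] <- numeric(tot + 1L)
    for (v in r2) {
      for (j in rev(seq_len(n1))) {
        prev <- dp[[j]]
        shifted <- c(numeric(v), prev[seq_len(tot + 1L - v)])
        dp[[j + 1L]] <- dp[[j + 1L]] + shifted
      }
    }
    dist <- dp[[n1 + 1L]]               # counts over doubled rank sums
    total <- sum(dist)                  # == choose(n, n1)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)]) / total
    p_ge <- sum(dist[seq.int(w2 + 1L, tot + 1L)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = u, p_value = p, method = "exact"))
  }

  # Tie-corrected normal approximation with continuity correction.
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                               method = "normal_approx"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = u, p_value = p, method = "normal_approx")
}
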