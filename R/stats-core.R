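#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided p-value under the point-probability criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (relative tolerance 1e-7, guarding against floating-point ties). This
#' is the convention behind standard statistical software output for 2x2
#' clinical contingency tables. The sample odds ratio ad/bc is reported
#' alongside (infinite when bc = 0).
#'
#' @param a,b,c,d non-negative integer cell counts; row 1 = (a, b),
#'   row 2 = (c, d).
#' @param alternative `"two_sided"` (default, used by the pipeline) or
#'   `"greater"`/`"less"` for the one-sided upper/lower tail on cell a.
#' @return a list with `p_value`, `odds_ratio`, `statistic` (the observed
#'   table's point probability), `method`, `sidedness`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("table total must be at least 1")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
    two_sided = sum(dens[dens <= p_obs * (1 + 1e-7)]),
    greater   = sum(dens[support >= a]),
    less      = sum(dens[support <= a]))
  list(p_value = min(1, p),
       odds_ratio = if (b * c == 0) if (a * d == 0) NaN else Inf else (a * d) / (b * c),
       statistic = p_obs, method = "fisher_exact_2x2",
       sidedness = alternative)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' two-sided p-value. When both groups have zero variance and equal means
#' the statistic is defined as 0 with p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `statistic`, `p_value`, `df`, `method`, `sidedness`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) {
    t <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    return(list(statistic = t, p_value = if (t == 0) 1 else 0, df = NA_real_,
                method = "welch_t", sidedness = "two_sided"))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                 (vy / length(y))^2 / (length(y) - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
       method = "welch_t", sidedness = "two_sided")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of the rank-sum null when `min(n_x, n_y) <= 8` and
#' there are no ties across the pooled sample; otherwise the normal
#' approximation with tie correction and continuity correction. Two-sided.
#'
#' @param x,y nonempty numeric vectors.
#' @return list with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `method`, `exact` flag, `sidedness`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && min(nx, ny) <= 8
  if (exact) {
    # enumerate the exact distribution of U by the standard DP recursion
    probs <- u_null_distribution(nx, ny)
    mu <- nx * ny / 2
    # two-sided: double the smaller tail (symmetric null), capped at 1
    lower <- sum(probs[seq_len(floor(u) + 1)])
    upper <- sum(probs[(floor(u) + 1):length(probs)])
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = u, p_value = p, method = "wilcoxon_rank_sum",
       exact = exact, sidedness = "two_sided")
}

# P(U = 0..nx*ny) for the tie-free Mann-Whitney null, by counting partitions.
u_null_distribution <- function(nx, ny) {
  counts <- numeric(nx * ny + 1)  # index u+1
  # f(i, j, u): number of ways to choose ranks for i x's among i+j slots with U = u
  f <- matrix(0, nrow = nx + 1, ncol = nx * ny + 1)
  f[1, 1] <- 1
  for (j in seq_len(nx + ny)) {
    fn <- matrix(0, nrow = nx + 1, ncol = nx * ny + 1)
    for (i in 0:min(j, nx)) {
      # element j is a y: U unchanged; or an x: adds (number of ys so far) = j-1-(i-1)
      fn[i + 1, ] <- f[i + 1, ]
      if (i >= 1) {
        add <- j - i  # ys preceding this x
        if (add <= nx * ny) {
          src <- f[i, ]
          shifted <- c(rep(0, add), src)[seq_len(nx * ny + 1)]
          fn[i + 1, ] <- fn[i + 1, ] + shifted
        }
      }
    }
    f <- fn
  }
  counts <- f[nx + 1, ]
  counts / sum(counts)
}

#' Pearson or Spearman correlation with t-approximation p-value
#'
#' Spearman uses average ranks for ties. The p-value comes from the
#' t transform `r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom,
#' appropriate for the cohort sizes this pipeline targets.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p_value`, `method`, `n`, and `defined` (FALSE
#'   when either input has zero variance, in which case `r` is `NA`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, method = method,
                n = n, defined = FALSE))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p_value = p, method = method, n = n, defined = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: p(i) * n / i at sorted rank i, cumulative
#' minimum from the largest rank down, capped at 1, original order
#' restored. `NA` entries are passed through unchanged and excluded from
#' the ranking.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  n <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * pv[o]))
  out[ok][o] <- adj
  out
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= q) for X ~ Hypergeometric(white = m, black = n, drawn = k):
#' the kernel behind the over-representation test.
#'
#' @param q observed overlap count.
#' @param m number of "successes" in the universe.
#' @param n number of "failures" in the universe.
#' @param k number drawn.
#' @return upper-tail probability.
#' @export
hyper_upper_tail <- function(q, m, n, k) {
  stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
}
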