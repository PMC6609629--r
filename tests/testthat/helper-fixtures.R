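# Small in-code fixtures shared across test files.

make_expr <- function(values, genes = NULL, samples = NULL,
                      scale_tag = "raw_log2") {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale_tag)
}

make_ann <- function(classes, samples = NULL, ...) {
  if (is.null(samples)) samples <- paste0("S", seq_along(classes))
  data.frame(sample_id = samples, cohort = "test", disease_class = classes,
             stringsAsFactors = FALSE, ...)
}

# A small two-class cohort with k informative genes (shift in sd units)
# among noise, n_a primary + n_b metastatic samples.
make_two_class_cohort <- function(n_a = 20, n_b = 20, n_info = 3,
                                  n_noise = 7, shift = 2, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  classes <- rep(c("primary", "metastatic"), c(n_a, n_b))
  v <- matrix(rnorm((n_info + n_noise) * n), n_info + n_noise, n)
  v[seq_len(n_info), classes == "metastatic"] <-
    v[seq_len(n_info), classes == "metastatic"] + shift
  genes <- c(sprintf("INFO%d", seq_len(n_info)), sprintf("NOIS%d", seq_len(n_noise)))
  list(expr = make_expr(v, genes = genes), ann = make_ann(classes))
}

# Brute-force tie-aware concordance AUC over all positive/negative pairs.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Brute-force two-sided Fisher p by explicit enumeration over all tables
# with the observed margins, using binomial coefficients directly.
fisher_by_enumeration <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Brute-force log-rank chi-square: O-E accumulation with hypergeometric
# variance at each distinct event time (two groups).
logrank_by_accumulation <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  stopifnot(max(group) == 2)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
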