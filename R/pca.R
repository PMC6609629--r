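#' Principal component analysis of a standardized expression matrix
#'
#' Decomposes the sample x gene matrix (samples as observations, genes as
#' variables) by singular value decomposition. Because every gene row is
#' standardized, this is PCA on the gene correlation structure. All
#' `min(n_samples - 1, n_genes)` components are returned, so the
#' variance-explained fractions sum to 1. Component signs are oriented so
#' that the largest-|loading| gene on each component has a positive
#' loading, which makes results reproducible across SVD implementations.
#'
#' @param m an [expr_matrix()] with `scale_tag = "gene_standardized"`,
#'   >= 3 samples and >= 2 genes.
#' @return object of class `pca_model`: list with `loadings` (genes x
#'   components, orthonormal columns), `scores` (samples x components),
#'   `variance_explained` (fractions, decreasing), `sdev`.
#' @export
pca_fit <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale_tag != "gene_standardized")
    stop("pca_fit expects gene-standardized input (see standardize_genes)")
  x <- t(m$values)                       # samples x genes, columns mean 0
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("PCA needs at least 3 samples")
  if (p < 2) stop("PCA needs at least 2 genes")
  s <- svd(x)
  tot <- sum(s$d^2)
  if (tot <= 0) stop("rank-0 input: no variance to decompose")
  k <- min(n - 1, p)                     # centered columns: rank <= n - 1
  d <- s$d[seq_len(k)]
  loadings <- s$v[, seq_len(k), drop = FALSE]
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(d, k, k)
  for (j in seq_len(k)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(gene_ids(m), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(sample_ids(m), paste0("PC", seq_len(k)))
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = d^2 / tot, sdev = d / sqrt(n - 1)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d genes, %d samples, %d components; PC1 %.1f%%\n",
              nrow(x$loadings), nrow(x$scores), ncol(x$loadings),
              100 * x$variance_explained[1]))
  invisible(x)
}

# Tie-aware rank AUC of scores against a positive-class indicator,
# oriented to >= 0.5.
score_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}

#' Class separation along one principal component
#'
#' Quantifies how well a component's sample scores separate two disease
#' classes: the absolute Welch t statistic of the scores between classes,
#' and the rank-based AUC of scores versus class, oriented to >= 0.5.
#' Samples outside the two classes (e.g. normals) are ignored.
#'
#' @param model a [pca_fit()] result.
#' @param ann sample annotation covering the model's samples.
#' @param component 1-based component index.
#' @param class_a,class_b the two disease classes to separate (defaults
#'   `primary` vs `metastatic`); each needs >= 2 samples.
#' @return list with `component`, `statistic` (|Welch t|), `auc`,
#'   `class_a`, `class_b`.
#' @export
separation_statistic <- function(model, ann, component = 1,
                                 class_a = "primary", class_b = "metastatic") {
  if (component < 1 || component > ncol(model$scores))
    stop("component out of range")
  validate_annotation(ann)
  cls <- ann$disease_class[match(rownames(model$scores), ann$sample_id)]
  ia <- which(cls == class_a); ib <- which(cls == class_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each class needs at least 2 samples with scores")
  s <- model$scores[, component]
  wt <- welch_t(s[ia], s[ib])
  list(component = component, statistic = abs(wt$statistic),
       auc = score_auc(c(s[ia], s[ib]),
                       c(rep(FALSE, length(ia)), rep(TRUE, length(ib)))),
       class_a = class_a, class_b = class_b)
}

#' Pick the class-separating component among the leading ones
#'
#' Scans the first `k_max` components and returns the separation result of
#' the component whose |Welch t| statistic between the two classes is
#' largest. The default `k_max = 3` reflects that class structure in an
#' expression cohort typically surfaces within the first few components.
#'
#' @inheritParams separation_statistic
#' @param k_max number of leading components to scan (>= 1).
#' @return the winning [separation_statistic()] result.
#' @export
select_separating_component <- function(model, ann, k_max = 3,
                                        class_a = "primary",
                                        class_b = "metastatic") {
  if (k_max < 1) stop("k_max must be >= 1")
  k <- min(k_max, ncol(model$scores))
  seps <- lapply(seq_len(k), function(j)
    separation_statistic(model, ann, j, class_a, class_b))
  seps[[which.max(vapply(seps, `[[`, numeric(1), "statistic"))]]
}

#' Select the genes with the most extreme loadings on a component
#'
#' Both signs are eligible: selection is by |loading|, with deterministic
#' lexicographic tie-break on the gene identifier.
#'
#' @param model a [pca_fit()] result.
#' @param component 1-based component index.
#' @param k number of genes to keep, 1 <= k <= n_genes.
#' @return character vector of k gene ids, in decreasing |loading| order.
#' @export
select_extreme_loadings <- function(model, component, k) {
  l <- model$loadings[, component]
  if (k < 1 || k > length(l)) stop("k out of range (1..", length(l), ")")
  ord <- order(-abs(l), names(l))
  names(l)[ord][seq_len(k)]
}
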