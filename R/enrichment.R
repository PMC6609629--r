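#' Read a GMT gene-set file
#'
#' Standard format: one set per line — set name, description, then the
#' tab-separated member genes.
#'
#' @param path file path.
#' @return named list of normalized gene-id vectors; descriptions kept in
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) normalize_gene_ids(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2)
  sets
}

#' Write gene sets as GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional character vector (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

# Signal-to-noise metric for one class split; vectorized over genes.
s2n_metric <- function(values, ia, ib) {
  ma <- rowMeans(values[, ia, drop = FALSE])
  mb <- rowMeans(values[, ib, drop = FALSE])
  sa <- sqrt(rowSums((values[, ia, drop = FALSE] - ma)^2) / (length(ia) - 1))
  sb <- sqrt(rowSums((values[, ib, drop = FALSE] - mb)^2) / (length(ib) - 1))
  # GSEA convention: floor each sd at 0.2|mean| (0.2 when the mean is 0)
  floor_a <- pmax(0.2 * abs(ma), ifelse(ma == 0, 0.2, 0))
  floor_b <- pmax(0.2 * abs(mb), ifelse(mb == 0, 0.2, 0))
  (ma - mb) / (pmax(sa, floor_a) + pmax(sb, floor_b))
}

#' Rank genes by the signal-to-noise phenotype metric
#'
#' Per-gene `(mean_a - mean_b) / (sd_a + sd_b)` with each class sd floored
#' at `0.2 * |mean|` (0.2 when the mean is zero), the standard GSEA
#' phenotype metric. Genes are returned in descending metric order with a
#' deterministic gene-id tie-break.
#'
#' @param m an [expr_matrix()].
#' @param ann sample annotation.
#' @param class_a,class_b classes to contrast; each needs >= 3 samples.
#' @return data.frame `gene_id`, `metric`, descending.
#' @export
signal_to_noise_rank <- function(m, ann, class_a, class_b) {
  ann2 <- align_annotation(m, ann)
  ia <- which(ann2$disease_class == class_a)
  ib <- which(ann2$disease_class == class_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop("each class needs at least 3 samples")
  metric <- s2n_metric(m$values, ia, ib)
  ord <- order(-metric, gene_ids(m))
  data.frame(gene_id = gene_ids(m)[ord], metric = metric[ord],
             stringsAsFactors = FALSE)
}

# Core weighted Kolmogorov-Smirnov running sum. `hit` is a logical vector
# aligned with the (already ordered) metric vector.
ks_enrichment <- function(metric, hit, weight = 1) {
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranked list")
  if (nh == n)
    return(list(es = 0, running = numeric(n), flagged = TRUE))
  w <- abs(metric)^weight
  inc <- numeric(n)
  inc[hit] <- if (sum(w[hit]) > 0) w[hit] / sum(w[hit]) else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, flagged = FALSE)
}

#' GSEA enrichment score of a gene set against a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: hits increment proportionally
#' to `|metric|^weight` (normalized over hits), misses decrement
#' uniformly; the enrichment score is the signed maximum deviation of the
#' running sum from zero. With `weight = 0` this is the classical
#' two-sample KS statistic between hit positions and the uniform ranking.
#' A set covering the whole ranked list has no misses; the result is then
#' flagged degenerate with es = 0.
#'
#' @param ranked a [signal_to_noise_rank()]-style data.frame (`gene_id`,
#'   `metric`, descending).
#' @param gene_set character vector of member genes.
#' @param weight exponent on |metric| for hit increments (default 1).
#' @return list with `es`, `running` (profile over ranks), `flagged`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  hit <- ranked$gene_id %in% normalize_gene_ids(gene_set)
  ks_enrichment(ranked$metric, hit, weight)
}

#' Phenotype-permutation enrichment test (NES and nominal p)
#'
#' Class labels of the two contrasted phenotypes are permuted `n_perm`
#' times; each permutation re-derives the signal-to-noise ranking and the
#' enrichment score. The normalized enrichment score is the observed ES
#' divided by the mean |ES| of same-sign permutation scores, and the
#' nominal p-value is `(1 + #{same-sign permutation ES at least as
#' extreme}) / (1 + #same-sign permutations)`.
#'
#' @inheritParams signal_to_noise_rank
#' @param gene_set member genes.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param weight KS weight (default 1).
#' @return list with `es`, `nes`, `nominal_p`, `n_permutations`,
#'   `set_size` (hits in the ranked universe).
#' @export
nes_permutation_test <- function(m, ann, gene_set, class_a, class_b,
                                 n_perm = 1000, seed = 1, weight = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  ann2 <- align_annotation(m, ann)
  ia <- which(ann2$disease_class == class_a)
  ib <- which(ann2$disease_class == class_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop("each class needs at least 3 samples")
  idx <- c(ia, ib)
  v <- m$values[, idx, drop = FALSE]
  na <- length(ia)
  set <- normalize_gene_ids(gene_set)
  hit_of <- function(metric) {
    ord <- order(-metric, gene_ids(m))
    list(metric = metric[ord], hit = gene_ids(m)[ord] %in% set)
  }
  obs <- hit_of(s2n_metric(v, seq_len(na), (na + 1):ncol(v)))
  es_obs <- ks_enrichment(obs$metric, obs$hit, weight)$es
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  perm_es <- vapply(seq_len(n_perm), function(i) {
    sh <- sample(ncol(v))
    pr <- hit_of(s2n_metric(v, sh[seq_len(na)], sh[(na + 1):ncol(v)]))
    ks_enrichment(pr$metric, pr$hit, weight)$es
  }, numeric(1))
  same <- perm_es[sign(perm_es) == sign(es_obs)]
  if (!length(same)) {
    warning("no same-sign permutation scores; p at resolution limit")
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
  } else {
    nes <- es_obs / mean(abs(same))
    p <- (sum(abs(same) >= abs(es_obs)) + 1) / (length(same) + 1)
  }
  list(es = es_obs, nes = nes, nominal_p = p, n_permutations = n_perm,
       set_size = sum(obs$hit))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a hit list and a gene set, drawn from a universe of
#' `universe_size` genes.
#'
#' @param hits character vector of hit genes.
#' @param set character vector of set members.
#' @param universe_size total genes in the universe (>= both list sizes).
#' @return list with `overlap`, `p_value`, `method`.
#' @export
overrepresentation_test <- function(hits, set, universe_size) {
  hits <- normalize_gene_ids(hits)
  set <- normalize_gene_ids(set)
  if (universe_size < length(hits) || universe_size < length(set))
    stop("universe smaller than a gene list")
  q <- length(intersect(hits, set))
  list(overlap = q,
       p_value = hyper_upper_tail(q, length(set),
                                  universe_size - length(set), length(hits)),
       method = "hypergeometric_overrepresentation")
}
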