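#' Differential expression between two sample classes
#'
#' Per-gene mean difference on the log2 scale (group_b minus group_a, so
#' a positive log2fc means higher in `group_b`) with Welch's two-sample
#' t-test and Benjamini-Hochberg adjustment. Genes for which both groups
#' have zero within-group variance get a missing p-value (the statistic is
#' undefined) but the fold change is still reported — unless the means
#' differ, in which case separation is perfect and p is 0.
#'
#' @param m an [expr_matrix()] (log2 scale).
#' @param ann sample annotation (see [validate_annotation()]).
#' @param group_a,group_b disease classes to contrast; both need >= 2
#'   samples.
#' @return a DEG table: data.frame with columns `gene_id`, `log2fc`,
#'   `p_value`, `p_adj`, `direction` (`up` iff log2fc > 0; `down`
#'   otherwise; genes with log2fc exactly 0 are tagged `down` by the sign
#'   convention and carry p ~ 1).
#' @export
differential_expression <- function(m, ann, group_a, group_b) {
  ann <- align_annotation(m, ann)
  ia <- which(ann$disease_class == group_a)
  ib <- which(ann$disease_class == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples (got ",
         length(ia), " and ", length(ib), ")")
  va <- m$values[, ia, drop = FALSE]
  vb <- m$values[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sa2 <- rowSums((va - ma)^2) / (na - 1)
  sb2 <- rowSums((vb - mb)^2) / (nb - 1)
  log2fc <- mb - ma
  se2 <- sa2 / na + sb2 / nb
  t <- log2fc / sqrt(se2)
  df <- se2^2 / ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(log2fc[degenerate] == 0, NA_real_, 0)
  deg_table(gene_id = gene_ids(m), log2fc = log2fc, p_value = p,
            p_adj = bh_adjust(p))
}

# Construct/validate a DEG table with the direction-from-sign convention.
deg_table <- function(gene_id, log2fc, p_value, p_adj = NULL) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in DEG table")
  data.frame(gene_id = gene_id, log2fc = log2fc, p_value = p_value,
             p_adj = if (is.null(p_adj)) bh_adjust(p_value) else p_adj,
             direction = ifelse(log2fc > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a DEG TSV (columns gene_id, log2fc, p_value[, p_adj, direction])
#' @param path file path.
#' @return DEG data.frame with the direction column recomputed from the
#'   sign of log2fc (the table invariant).
#' @export
read_deg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  for (col in c("gene_id", "log2fc", "p_value"))
    if (!col %in% names(df)) stop("DEG table lacks column '", col, "'")
  deg_table(df$gene_id, df$log2fc, df$p_value,
            if ("p_adj" %in% names(df)) df$p_adj else NULL)
}

#' Write a DEG table as TSV
#' @param deg DEG data.frame.
#' @param path output path.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
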