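#' Expression matrix container
#'
#' A thin S3 container for a genes x samples matrix of log2-scale
#' expression values, tagged with the normalization state it is in.
#' Every downstream stage (differential expression, PCA signature
#' discovery, classification, survival dichotomization) consumes this
#' container, so its invariants are checked eagerly: unique gene and
#' sample identifiers, dimnames consistent with the matrix, and no
#' non-finite values.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param scale_tag one of `"raw_log2"`, `"quantile_normalized"`,
#'   `"gene_standardized"` recording which normalizations have been applied.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale_tag = c("raw_log2", "quantile_normalized",
                                              "gene_standardized")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite and non-missing")
  structure(list(values = values, scale_tag = scale_tag), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Subset an expression matrix by gene and/or sample identifiers
#'
#' @param m an [expr_matrix()].
#' @param genes,samples character vectors of identifiers to keep (order
#'   preserved as given); `NULL` keeps all.
#' @return an `expr_matrix` with the same `scale_tag`.
#' @export
subset_expr <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("samples absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expr_matrix(v, m$scale_tag)
}

#' Read a gene x sample expression table
#'
#' Expects a tab- or comma-delimited file whose first column (`gene_id`)
#' holds gene identifiers and whose remaining header names are sample
#' identifiers. Duplicate gene rows are collapsed by a configurable rule;
#' the default keeps the row with the highest mean expression, the common
#' probe-collapse convention for microarray data.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param collapse rule for duplicated gene ids: `"max_mean"` keeps the
#'   highest-mean row, `"error"` rejects the file.
#' @param impute if `TRUE`, missing cells are replaced by the per-gene mean
#'   of the observed values; by default missing cells are rejected.
#' @return an [expr_matrix()] with `scale_tag = "raw_log2"`; file row and
#'   column order preserved.
#' @export
read_expression_table <- function(path, dialect = c("tsv", "csv"),
                                  collapse = c("max_mean", "error"),
                                  impute = FALSE) {
  dialect <- match.arg(dialect)
  collapse <- match.arg(collapse)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2)
    stop("expression table must have a gene id column and at least one sample column")
  header <- colnames(df)
  if (anyDuplicated(header[-1]))
    stop("duplicate sample id in header: ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  genes <- trimws(df[[1]])
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(NULL, header[-1]))
  bad <- which(is.na(num) & !(is.na(vals) | vals == "NA"), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(num)[bad[1, 2]]))
  if (anyNA(num)) {
    if (!impute) {
      miss <- which(is.na(num), arr.ind = TRUE)
      stop(sprintf("missing value at gene '%s', sample '%s' (set impute = TRUE to mean-impute)",
                   genes[miss[1, 1]], colnames(num)[miss[1, 2]]))
    }
    for (i in which(rowSums(is.na(num)) > 0)) {
      mu <- mean(num[i, ], na.rm = TRUE)
      if (!is.finite(mu)) stop(sprintf("gene '%s' has no observed values", genes[i]))
      num[i, is.na(num[i, ])] <- mu
    }
  }
  if (anyDuplicated(genes)) {
    if (collapse == "error")
      stop("duplicate gene ids: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    keep <- rep(TRUE, length(genes))
    means <- rowMeans(num)
    for (g in unique(genes[duplicated(genes)])) {
      idx <- which(genes == g)
      keep[idx] <- FALSE
      keep[idx[which.max(means[idx])]] <- TRUE
    }
    num <- num[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(num) <- genes
  expr_matrix(num, "raw_log2")
}

#' Write an expression matrix as TSV
#'
#' @param m an [expr_matrix()].
#' @param path output path; first column header is `gene_id`.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share one empirical distribution: the
#' value at each rank is replaced by the cross-sample mean of that rank's
#' values, ties within a column receiving the mean of the reference values
#' across the ranks they span. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`, whose tie rule
#' matches this contract.
#'
#' @param m an [expr_matrix()] with `scale_tag = "raw_log2"` and at least
#'   two samples.
#' @return an `expr_matrix` with `scale_tag = "quantile_normalized"`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale_tag == "gene_standardized")
    stop("cannot quantile-normalize gene-standardized data")
  if (ncol(m$values) < 2)
    stop("quantile normalization needs at least two samples")
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  expr_matrix(v, "quantile_normalized")
}

#' Standardize each gene to mean 0, standard deviation 1
#'
#' Per-gene z-scores using the sample (n - 1 denominator) standard
#' deviation. Genes with zero variance are undefined under z-scoring and
#' are dropped with a warning.
#'
#' @param m an [expr_matrix()] with at least two samples.
#' @return an `expr_matrix` with `scale_tag = "gene_standardized"`;
#'   constant genes removed.
#' @export
standardize_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2)
    stop("standardization needs at least two samples")
  v <- m$values
  mu <- rowMeans(v)
  sd <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1))
  constant <- sd == 0
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant gene(s): ",
            paste(utils::head(rownames(v)[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")
    v <- v[!constant, , drop = FALSE]
    mu <- mu[!constant]
    sd <- sd[!constant]
  }
  if (!nrow(v)) stop("no genes left after dropping constant rows")
  expr_matrix((v - mu) / sd, "gene_standardized")
}
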