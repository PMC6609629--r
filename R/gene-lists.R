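#' Normalize gene identifiers for set operations
#'
#' Identifiers are upper-cased and whitespace-stripped before any set
#' operation, so `" hspb8 "` and `"HSPB8"` denote the same gene. No alias
#' or ortholog resolution is attempted: identity is by symbol string.
#'
#' @param genes character vector.
#' @return normalized, de-duplicated character vector (first-occurrence
#'   order).
#' @export
normalize_gene_ids <- function(genes) {
  unique(toupper(trimws(as.character(genes))))
}

#' Read a one-symbol-per-line gene list
#' @param path file path; blank lines and lines starting with `#` skipped.
#' @return normalized character vector.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  normalize_gene_ids(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Intersect two gene lists with Venn accounting
#'
#' The integrative step of the pipeline: overlap a binding-site-proximal
#' DEG list with a knockdown DEG list. Identifiers are normalized first;
#' the result reports the intersection plus the exclusive counts, so the
#' conservation identity `n_intersection + n_a_only + n_b_only = |union|`
#' always holds.
#'
#' @param a,b nonempty character vectors (or DEG tables, whose `gene_id`
#'   column is used).
#' @return list with `genes` (the intersection, in `a`'s order), `n_a`,
#'   `n_b`, `n_intersection`, `n_a_only`, `n_b_only`.
#' @export
intersect_gene_lists <- function(a, b) {
  if (is.data.frame(a)) a <- a$gene_id
  if (is.data.frame(b)) b <- b$gene_id
  if (!length(a) || !length(b)) stop("both gene lists must be nonempty")
  a <- normalize_gene_ids(a)
  b <- normalize_gene_ids(b)
  inter <- a[a %in% b]
  list(genes = inter,
       n_a = length(a), n_b = length(b),
       n_intersection = length(inter),
       n_a_only = length(a) - length(inter),
       n_b_only = length(b) - length(inter))
}

#' Direction concordance between two DEG tables
#'
#' For the genes shared by both tables, counts the four direction
#' quadrants (up/up, up/down, down/up, down/down) and the discordant
#' fraction — the proportion of shared genes whose directions disagree.
#' A high discordant fraction is the pattern expected when one contrast is
#' a knockdown (gene up after removing its repressor) and the other is a
#' tumor-vs-normal contrast.
#'
#' @param a,b DEG tables (data.frames with `gene_id` and `direction`).
#' @return list with `quadrants` (named counts `up_up`, `up_down`,
#'   `down_up`, `down_down`), `n_shared`, `discordant_fraction`.
#' @export
direction_concordance <- function(a, b) {
  ga <- normalize_gene_ids(a$gene_id)
  gb <- normalize_gene_ids(b$gene_id)
  shared <- intersect(ga, gb)
  if (!length(shared)) stop("no shared genes between the two DEG tables")
  da <- a$direction[match(shared, ga)]
  db <- b$direction[match(shared, gb)]
  quad <- c(up_up = sum(da == "up" & db == "up"),
            up_down = sum(da == "up" & db == "down"),
            down_up = sum(da == "down" & db == "up"),
            down_down = sum(da == "down" & db == "down"))
  list(quadrants = quad, n_shared = length(shared),
       discordant_fraction = unname((quad["up_down"] + quad["down_up"]) / length(shared)))
}
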