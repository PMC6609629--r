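#' Greedy backward elimination of low-loading genes
#'
#' The signature-refinement loop: starting from a candidate panel, PCA is
#' refit on the current panel (standardized, on the primary + metastatic
#' samples unless `include_normals` is set), genes are ranked by their
#' |loading| on the first component, and the smallest-loading gene is
#' tentatively removed. The removal is accepted only if the first
#' component's variance-explained fraction does not drop (beyond a
#' tolerance `epsilon`) and — unless `paper_strict` disables the extra
#' constraint — the first component's class-separation AUC does not drop
#' either. On rejection the next-smallest candidate is tried; the loop
#' stops when no gene is removable or the panel has shrunk to `min_size`.
#'
#' The separation constraint is an extension of the variance-only rule:
#' without it, pruning can converge to a high-variance panel that no
#' longer separates the classes. `paper_strict = TRUE` recovers the
#' variance-only behaviour.
#'
#' @param m an [expr_matrix()] on the raw or quantile-normalized log2
#'   scale (standardization happens internally on the fit samples).
#' @param ann sample annotation.
#' @param panel character vector of candidate gene ids (must be in `m`),
#'   length >= `min_size`.
#' @param min_size smallest panel size pruning may reach (default 2).
#' @param epsilon acceptance tolerance on variance-explained and on the
#'   separation metric (default 1e-6).
#' @param separation_metric metric protected by the separation
#'   constraint: `"auc"` (default; rank AUC of PC1 scores vs class) or
#'   `"t"` (|Welch t| of PC1 scores between classes). The AUC saturates
#'   at 1 for strongly separated cohorts, in which case the constraint
#'   cannot veto removals; the t statistic degrades smoothly as
#'   informative genes are removed and is the stricter guard.
#' @param paper_strict if TRUE, only the variance-explained constraint is
#'   enforced.
#' @param rerank if TRUE (default) candidates are re-ranked by |loading|
#'   after every accepted removal; if FALSE the initial ranking is used
#'   throughout.
#' @param include_normals if TRUE normal samples participate in the PCA
#'   fit (they never enter separation scoring).
#' @param class_a,class_b classes whose separation is protected.
#' @return list with `signature` (list: `genes` ordered by decreasing
#'   final |PC1 loading|, `final_variance_explained`, `final_separation`)
#'   and `trace` (data.frame of tentative removals: `removed_gene`,
#'   `abs_loading`, `variance_explained_1`, `separation_auc`, `accepted`).
#' @export
greedy_prune <- function(m, ann, panel, min_size = 2, epsilon = 1e-6,
                         paper_strict = FALSE, rerank = TRUE,
                         include_normals = FALSE,
                         separation_metric = c("auc", "t"),
                         class_a = "primary", class_b = "metastatic") {
  separation_metric <- match.arg(separation_metric)
  panel <- normalize_gene_ids(panel)
  if (length(panel) < min_size)
    stop("panel (", length(panel), ") smaller than min_size (", min_size, ")")
  if (min_size < 2) stop("min_size must be >= 2 (PCA needs 2 genes)")
  ann2 <- align_annotation(m, ann)
  keep_classes <- c(class_a, class_b, if (include_normals) "normal")
  fit_samples <- sample_ids(m)[ann2$disease_class %in% keep_classes]
  z <- standardize_genes(subset_expr(m, genes = panel, samples = fit_samples))
  panel <- gene_ids(z)                    # constant genes dropped with warning
  if (length(panel) < min_size) stop("too few non-constant panel genes")

  fit_state <- function(genes) {
    model <- pca_fit(subset_expr(z, genes = genes))
    sep <- separation_statistic(model, ann2, 1, class_a, class_b)
    list(model = model, ve1 = model$variance_explained[1],
         metric = if (separation_metric == "auc") sep$auc else sep$statistic,
         sep = sep)
  }

  state <- fit_state(panel)
  trace <- list()
  initial_order <- NULL
  if (!rerank) {
    l <- abs(state$model$loadings[, 1])
    initial_order <- names(l)[order(l, names(l))]
  }
  repeat {
    if (length(panel) <= min_size) break
    cand <- if (rerank) {
      l <- abs(state$model$loadings[, 1])
      names(l)[order(l, names(l))]
    } else {
      initial_order[initial_order %in% panel]
    }
    removed <- FALSE
    for (g in cand) {
      if (length(panel) - 1 < min_size) break
      trial <- fit_state(setdiff(panel, g))
      ok <- trial$ve1 >= state$ve1 - epsilon &&
        (paper_strict || trial$metric >= state$metric - epsilon)
      trace[[length(trace) + 1]] <- data.frame(
        removed_gene = g,
        abs_loading = unname(abs(state$model$loadings[g, 1])),
        variance_explained_1 = trial$ve1,
        separation_auc = trial$sep$auc,
        separation_statistic = trial$sep$statistic,
        accepted = ok, stringsAsFactors = FALSE)
      if (ok) {
        panel <- setdiff(panel, g)
        state <- trial
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  l1 <- abs(state$model$loadings[, 1])
  genes <- names(l1)[order(-l1, names(l1))]
  list(signature = list(genes = genes,
                        final_variance_explained = unname(state$ve1),
                        final_separation = state$sep),
       trace = rbind_rows(trace))
}

#' Discover a compact class-separating gene signature
#'
#' The full discovery recipe over a candidate panel: (1) PCA on the
#' standardized panel and identification of the component that best
#' separates the two classes among the leading `k_max`; (2) pre-selection
#' of the `k_extreme` genes with the most extreme loadings on that
#' component; (3) greedy backward elimination ([greedy_prune()]) of
#' low-loading genes under the variance-explained (and separation)
#' constraint, after which the separation concentrates in the first
#' component of the reduced panel.
#'
#' @inheritParams greedy_prune
#' @param k_extreme pre-selection size; default half the panel (rounded
#'   up), since no principled size is implied by "most extreme".
#' @param k_max leading components scanned for separation (default 3).
#' @return list with `signature`, `trace`, and `details` (chosen
#'   component, its separation, panel sizes at each stage).
#' @export
discover_signature <- function(m, ann, panel, k_extreme = NULL, k_max = 3,
                               min_size = 2, epsilon = 1e-6,
                               paper_strict = FALSE, rerank = TRUE,
                               include_normals = FALSE,
                               separation_metric = c("auc", "t"),
                               class_a = "primary", class_b = "metastatic") {
  separation_metric <- match.arg(separation_metric)
  panel <- normalize_gene_ids(panel)
  ann2 <- align_annotation(m, ann)
  keep_classes <- c(class_a, class_b, if (include_normals) "normal")
  fit_samples <- sample_ids(m)[ann2$disease_class %in% keep_classes]
  z <- standardize_genes(subset_expr(m, genes = panel, samples = fit_samples))
  model <- pca_fit(z)
  sep <- select_separating_component(model, ann2, k_max, class_a, class_b)
  if (is.null(k_extreme)) k_extreme <- ceiling(nrow(model$loadings) / 2)
  k_extreme <- min(k_extreme, nrow(model$loadings))
  pre <- select_extreme_loadings(model, sep$component, k_extreme)
  pruned <- greedy_prune(m, ann, pre, min_size = min_size, epsilon = epsilon,
                         paper_strict = paper_strict, rerank = rerank,
                         include_normals = include_normals,
                         separation_metric = separation_metric,
                         class_a = class_a, class_b = class_b)
  c(pruned,
    list(details = list(separating_component = sep$component,
                        initial_separation = sep,
                        panel_size = nrow(model$loadings),
                        preselected = pre,
                        k_extreme = k_extreme)))
}
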