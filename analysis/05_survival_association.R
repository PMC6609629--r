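#!/usr/bin/env Rscript
# Stage 5 — survival association of the signature.
#
# For primary-tumor patients: per-gene Kaplan-Meier curves and log-rank
# tests on median-dichotomized expression, then univariate screening and
# multivariable Cox regression with backward selection (removal at
# alpha = 0.05) over the standardized signature genes.

suppressMessages(library(metasig))
dir.create("results/survival", recursive = TRUE, showWarnings = FALSE)

expr <- read_expression_table("results/data/discovery_expr.tsv")
ann <- read_annotation("results/data/discovery_ann.tsv")
sig <- jsonlite::read_json("results/signature.json", simplifyVector = TRUE)

prim <- ann[ann$disease_class == "primary" & !is.na(ann$os_time), ]
logrank <- do.call(rbind, lapply(sig$genes, function(g) {
  grp <- dichotomize_expression(expr, g, prim$sample_id)
  km_low <- km_estimate(prim$os_time[grp == "low"],
                        prim$os_event[grp == "low"])
  km_high <- km_estimate(prim$os_time[grp == "high"],
                         prim$os_event[grp == "high"])
  write.table(rbind(cbind(group = "low", km_low),
                    cbind(group = "high", km_high)),
              sprintf("results/survival/km_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lr <- log_rank_test(prim$os_time, prim$os_event, grp)
  data.frame(gene_id = g, chi_square = lr$chi_square, p_value = lr$p_value)
}))
write.table(logrank, "results/survival/logrank.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

v <- expr$values[sig$genes, prim$sample_id, drop = FALSE]
z <- as.data.frame(t((v - rowMeans(v)) / apply(v, 1, sd)))
sel <- cox_backward_select(prim$os_time, prim$os_event, z, alpha = 0.05,
                           univariate_alpha = 0.05)
write.table(sel$univariate, "results/survival/cox_univariate.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(sel$model))
  write.table(sel$model$table, "results/survival/cox_multivariable.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d signature genes reach log-rank p < 0.05 in %d primaries (%d events)\n",
            sum(logrank$p_value < 0.05), nrow(logrank), nrow(prim),
            sum(prim$os_event)))
if (!is.null(sel$model)) {
  kept <- sel$model$table
  cat("multivariable model after backward selection:\n")
  for (i in seq_len(nrow(kept)))
    cat(sprintf("  %s: HR %.2f (%.2f, %.2f), p = %.3g\n", kept$term[i],
                kept$hr[i], kept$ci_lower[i], kept$ci_upper[i],
                kept$p_value[i]))
} else cat("backward selection removed every covariate\n")
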