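#!/usr/bin/env Rscript
# Stage 4 — metastasis stratification and cross-cohort transfer.
#
# Trains a stepwise-AIC logistic model on the signature genes
# (within-cohort standardized expression, normals excluded), picks the
# balanced-accuracy-optimal probability threshold from the training ROC
# curve, then applies the frozen coefficients + threshold to the
# independently simulated transfer cohort.

suppressMessages(library(metasig))
dir.create("results/classifier", recursive = TRUE, showWarnings = FALSE)

expr <- read_expression_table("results/data/discovery_expr.tsv")
ann <- read_annotation("results/data/discovery_ann.tsv")
t_expr <- read_expression_table("results/data/transfer_expr.tsv")
t_ann <- read_annotation("results/data/transfer_ann.tsv")
sig <- jsonlite::read_json("results/signature.json", simplifyVector = TRUE)

model <- suppressWarnings(
  train_classifier(standardize_genes(expr), ann, sig$genes,
                   cohort = "discovery"))
train_rep <- attr(model, "training_report")
transfer_rep <- evaluate_on_cohort(model, standardize_genes(t_expr), t_ann)

jsonlite::write_json(
  list(intercept = model$intercept,
       coefficients = as.list(model$coefficients), aic = model$aic,
       threshold = model$threshold, ridge = model$ridge,
       training_cohort = model$training_cohort),
  "results/classifier/model.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
jsonlite::write_json(train_rep, "results/classifier/evaluation_training.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
jsonlite::write_json(transfer_rep,
                     "results/classifier/evaluation_transfer.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("stepwise kept %d of %d genes: %s (AIC %.1f%s)\n",
            length(model$genes), length(sig$genes),
            paste(model$genes, collapse = ", "), model$aic,
            if (model$ridge) ", ridge fallback" else ""))
cat(sprintf("threshold %.4f; training balanced accuracy %.3f (resubstitution AUC %.3f)\n",
            model$threshold, train_rep$balanced_accuracy, train_rep$auc))
cat(sprintf("transfer balanced accuracy %.3f (AUC %.3f; sens %.3f, spec %.3f)\n",
            transfer_rep$balanced_accuracy, transfer_rep$auc,
            transfer_rep$sensitivity, transfer_rep$specificity))
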