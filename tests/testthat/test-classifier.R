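test_that("logistic fit recovers planted log-odds and flags null genes", {
  # planted beta = (-1, +2) on one gene, n = 2000
  sim <- simulate_logistic_cohort(2000, 1, c(GENE1 = 2), intercept = -1,
                                  seed = 101)
  fit <- fit_logistic(sim$expr, sim$annotation, "GENE1")
  expect_lt(abs(fit$coefficients[["GENE1"]] - 2), 0.2)
  expect_lt(abs(fit$intercept - (-1)), 0.2)
  expect_false(fit$ridge)

  # null gene: coefficient near 0, AIC near intercept-only AIC + 2
  simn <- simulate_logistic_cohort(2000, 1, c(GENE1 = 0), seed = 102)
  fitn <- fit_logistic(simn$expr, simn$annotation, "GENE1")
  fit0 <- fit_logistic(simn$expr, simn$annotation, character(0))
  expect_lt(abs(fitn$coefficients[["GENE1"]]), 0.15)
  expect_lt(abs(fitn$aic - (fit0$aic + 2)), 2)
})

test_that("complete separation triggers the ridge fallback with finite coefficients", {
  v <- matrix(c(rep(0, 6), rep(3, 6)) + rep(seq(0, 0.5, 0.1), 2), 1, 12,
              dimnames = list("G1", paste0("S", 1:12)))
  m <- expr_matrix(v, "raw_log2")
  ann <- make_ann(rep(c("primary", "metastatic"), each = 6),
                  samples = colnames(v))
  expect_warning(fit <- fit_logistic(m, ann, "G1"), "ridge")
  expect_true(fit$ridge)
  expect_true(is.finite(fit$coefficients[["G1"]]))
  expect_gt(fit$coefficients[["G1"]], 0)
  scores <- predict_scores(fit, m)
  expect_true(all(scores > 0 & scores < 1))
})

test_that("probability scores are monotone in each gene with the coefficient sign", {
  sim <- simulate_logistic_cohort(300, 2, c(GENE1 = 1.5, GENE2 = -1), seed = 7)
  fit <- fit_logistic(sim$expr, sim$annotation, c("GENE1", "GENE2"))
  base <- sim$expr$values
  bump <- base; bump["GENE1", ] <- bump["GENE1", ] + 1
  s0 <- predict_scores(fit, expr_matrix(base, "raw_log2"))
  s1 <- predict_scores(fit, expr_matrix(bump, "raw_log2"))
  expect_true(all((s1 - s0) * sign(fit$coefficients[["GENE1"]]) > 0))
  bump2 <- base; bump2["GENE2", ] <- bump2["GENE2", ] + 1
  s2 <- predict_scores(fit, expr_matrix(bump2, "raw_log2"))
  expect_true(all((s2 - s0) * sign(fit$coefficients[["GENE2"]]) > 0))
})

test_that("stepwise AIC selection finds planted effects and respects the null model", {
  sim <- simulate_logistic_cohort(1000, 9, c(GENE1 = 2, GENE2 = -2), seed = 7)
  fit <- stepwise_aic_select(sim$expr, sim$annotation, gene_ids(sim$expr))
  expect_true(all(c("GENE1", "GENE2") %in% fit$genes))
  fit0 <- fit_logistic(sim$expr, sim$annotation, character(0))
  expect_lte(fit$aic, fit0$aic)

  # all-noise candidates: intercept-only model in the majority of seeds
  # (each null candidate clears the AIC bar with probability ~0.16, so the
  # candidate pool is kept small for the majority claim to hold)
  empty <- sapply(1:10, function(s) {
    simn <- simulate_logistic_cohort(500, 2, c(GENE1 = 0), seed = 200 + s)
    f <- stepwise_aic_select(simn$expr, simn$annotation, gene_ids(simn$expr))
    length(f$genes) == 0
  })
  expect_gte(sum(empty), 6)
})

test_that("ROC curve and AUC match brute-force pair counting", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc(c(0.9, 0.4, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))$auc,
               0.5)
  set.seed(55)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    curve <- roc_auc(scores, labels)
    expect_equal(curve$auc, auc_by_pairs(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(curve$tpr) >= 0) && all(diff(curve$fpr) >= 0))
    # trapezoid area equals the concordance statistic by construction
    expect_equal(curve$auc,
                 sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("threshold choice maximizes balanced accuracy (exhaustive oracle)", {
  scores <- c(0.95, 0.6, 0.55, 0.5, 0.3, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  ch <- choose_threshold(roc_auc(scores, labels))
  # oracle: scan a fine grid of candidate thresholds
  grid <- sort(unique(c(scores - 1e-9, scores + 1e-9, seq(0, 1, 0.001))))
  ba <- vapply(grid, function(t)
    classification_report(scores, labels, t)$balanced_accuracy, numeric(1))
  expect_equal(ch$report$balanced_accuracy, max(ba), tolerance = 1e-12)
  rep <- classification_report(scores, labels, ch$threshold)
  expect_equal(rep$balanced_accuracy, ch$report$balanced_accuracy)
  expect_equal(rep$balanced_accuracy,
               (rep$sensitivity + rep$specificity) / 2, tolerance = 1e-12)

  # perfectly separated scores: gap midpoint, balanced accuracy 1
  sep <- choose_threshold(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                                  c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(sep$report$balanced_accuracy, 1.0)
  expect_equal(sep$threshold, 0.5)
  # class-ignorant scores: balanced accuracy ~ 0.5
  set.seed(3)
  rand <- choose_threshold(roc_auc(runif(40), rep(c(TRUE, FALSE), 20)))
  expect_lt(abs(rand$report$balanced_accuracy - 0.5), 0.25)
})

test_that("training evaluation is consistent and transfer succeeds on a twin cohort", {
  stA <- simulate_expression_cohort(simulation_config(seed = 61, cohort = "A"))
  stB <- simulate_expression_cohort(
    simulation_config(seed = 62, n_normal = 0, n_primary = 191,
                      n_metastatic = 29, cohort = "B"))
  planted <- stA$truth$gene_id[stA$truth$shift != 0]
  zA <- standardize_genes(stA$expr); zB <- standardize_genes(stB$expr)
  model <- suppressWarnings(train_classifier(zA, stA$annotation, planted,
                                             cohort = "A"))
  expect_false(is.na(model$threshold))
  expect_identical(model$training_cohort, "A")
  # evaluating on the training cohort reproduces the training report
  self_eval <- evaluate_on_cohort(model, zA, stA$annotation)
  train_rep <- attr(model, "training_report")
  expect_equal(self_eval$balanced_accuracy, train_rep$balanced_accuracy)
  expect_equal(self_eval$auc, train_rep$auc)
  # transfer to the independently seeded twin cohort
  transfer <- evaluate_on_cohort(model, zB, stB$annotation)
  expect_gte(transfer$balanced_accuracy, 0.9)

  # missing model genes are reported by name
  reduced <- subset_expr(zB, genes = setdiff(gene_ids(zB), model$genes[1]))
  expect_error(evaluate_on_cohort(model, reduced, stB$annotation),
               model$genes[1])
})
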