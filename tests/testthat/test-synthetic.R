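test_that("generation is bit-identical under a fixed seed", {
  cfg <- simulation_config(seed = 9)
  s1 <- simulate_clinical_covariates(
    simulate_survival_times(simulate_expression_cohort(cfg)))
  s2 <- simulate_clinical_covariates(
    simulate_survival_times(simulate_expression_cohort(cfg)))
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$annotation, s2$annotation)
  d1 <- simulate_deg_lists(cfg)
  expect_identical(d1, simulate_deg_lists(cfg))
})

test_that("planted shifts hit their target within moment tolerance", {
  st <- simulate_expression_cohort(simulation_config(seed = 15))
  ann <- st$annotation
  prim <- ann$sample_id[ann$disease_class == "primary"]
  met <- ann$sample_id[ann$disease_class == "metastatic"]
  for (i in which(st$truth$shift != 0)) {
    g <- st$truth$gene_id[i]
    pooled_sd <- sqrt((var(st$expr$values[g, prim]) +
                       var(st$expr$values[g, met])) / 2)
    smd <- (mean(st$expr$values[g, met]) - mean(st$expr$values[g, prim])) /
      pooled_sd
    expect_lt(abs(smd - st$truth$shift[i]), 0.3 * abs(st$truth$shift[i]) + 0.3)
  }
  # ground truth covers every gene and the study passes validation cleanly
  expect_setequal(st$truth$gene_id, gene_ids(st$expr))
  expect_silent(validate_annotation(st$annotation))
})

test_that("correlated noise blocks realize the configured within-block correlation", {
  spec <- metasig:::default_signature_spec(n_noise = 10, n_cor_blocks = 2,
                                           block_size = 5, block_cor = 0.5)
  st <- simulate_expression_cohort(
    simulation_config(seed = 37, n_normal = 0, n_primary = 300,
                      n_metastatic = 50, signature_spec = spec))
  blk <- st$truth$gene_id[which(!is.na(st$truth$block) & st$truth$block == 1)]
  cors <- cor(t(st$expr$values[blk, ]))
  off <- cors[upper.tri(cors)]
  expect_lt(abs(mean(off) - 0.5), 0.1)
  indep <- st$truth$gene_id[st$truth$role == "noise"][1:5]
  cors2 <- cor(t(st$expr$values[indep, ]))
  expect_lt(max(abs(cors2[upper.tri(cors2)])), 0.25)
})

test_that("zero-shift cohorts give a calibrated differential-expression null", {
  spec <- data.frame(gene_id = sprintf("N%04d", 1:1000), role = "noise",
                     shift = 0, block = NA_integer_, block_cor = NA_real_,
                     driver_cor = NA_real_)
  st <- simulate_expression_cohort(
    simulation_config(seed = 52, signature_spec = spec))
  deg <- differential_expression(st$expr, st$annotation, "primary",
                                 "metastatic")
  rate <- mean(deg$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("DEG-list construction hits exact sizes, overlap, and direction mix", {
  cfg <- simulation_config(seed = 3)
  degs <- simulate_deg_lists(cfg)   # paper-shaped spec (536, 2677, 87, 0.8)
  expect_equal(nrow(degs$a), 536L)
  expect_equal(nrow(degs$b), 2677L)
  venn <- intersect_gene_lists(degs$a, degs$b)
  expect_equal(venn$n_intersection, 87L)
  conc <- direction_concordance(degs$a, degs$b)
  expect_equal(unname(conc$discordant_fraction), round(0.8 * 87) / 87)

  ident <- simulate_deg_lists(simulation_config(
    seed = 4, deg_spec = list(n_a = 10, n_b = 10, n_intersection = 10,
                              discordant_fraction = 0)))
  expect_identical(sort(ident$a$gene_id), sort(ident$b$gene_id))
  expect_equal(direction_concordance(ident$a, ident$b)$discordant_fraction, 0)

  disj <- simulate_deg_lists(simulation_config(
    seed = 5, deg_spec = list(n_a = 5, n_b = 5, n_intersection = 0,
                              discordant_fraction = 0)))
  expect_equal(intersect_gene_lists(disj$a, disj$b)$n_intersection, 0L)

  expect_error(simulation_config(
    seed = 6, deg_spec = list(n_a = 5, n_b = 5, n_intersection = 9,
                              discordant_fraction = 0)), "intersection")
})

test_that("survival generator honors censoring targets and degenerate cases", {
  cfg0 <- simulation_config(seed = 18)
  cfg0$survival_spec$censoring_rate <- 0
  st0 <- simulate_survival_times(simulate_expression_cohort(cfg0))
  expect_true(all(st0$annotation$os_event == 1))

  cfg3 <- simulation_config(seed = 18)   # default censoring 0.3
  st3 <- simulate_survival_times(simulate_expression_cohort(cfg3))
  expect_lt(abs(mean(st3$annotation$os_event == 0) - 0.3), 0.1)
  expect_true(all(st3$annotation$os_time > 0))

  # planted log-HR on a signature gene is visible to the Cox fit
  g <- names(cfg3$survival_spec$log_hr)[1]
  v <- st3$expr$values[g, ]
  fit <- cox_fit(st3$annotation$os_time, st3$annotation$os_event,
                 data.frame(z = (v - mean(v)) / sd(v)))
  expect_gt(fit$table$beta[1], 0.2)
  expect_lt(fit$table$p_value[1], 0.01)
})

test_that("clinical covariates follow class-conditional probabilities", {
  cfg <- simulation_config(seed = 25)
  cfg$clinical_spec <- list(
    grade = list(levels = c("lo", "hi"), normal = c(1, 0),
                 primary = c(1, 0), metastatic = c(0, 1)))
  st <- simulate_clinical_covariates(simulate_expression_cohort(cfg))
  expect_true(all(st$annotation$grade[st$annotation$disease_class != "metastatic"] == "lo"))
  expect_true(all(st$annotation$grade[st$annotation$disease_class == "metastatic"] == "hi"))

  bad <- simulation_config(seed = 26)
  bad$clinical_spec$age_group$primary <- c(0.5, 0.6)
  expect_error(metasig:::validate_sim_config(bad), "sum to 1")
})

test_that("Table-1-shaped age preset gives Fisher p calibrated to the analytic value", {
  # expected 2x2 under the preset at the cohort sizes: compare the p of
  # the expected table with the average simulated p over replicates
  cfg <- simulation_config(seed = 47)
  expected <- fisher_exact_2x2(8, 13, 130, 63)$p_value
  ps <- sapply(1:40, function(i) {
    cfg$seed <- 1000L + i
    st <- simulate_clinical_covariates(simulate_expression_cohort(cfg))
    ann <- st$annotation[st$annotation$disease_class != "normal", ]
    tab <- table(factor(ann$disease_class, c("metastatic", "primary")),
                 factor(ann$age_group, c("<64", ">=64")))
    fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value
  })
  # simulated tables scatter around the preset's expectation: the median
  # simulated p must sit within an order of magnitude of the analytic one
  expect_lt(abs(log10(median(ps)) - log10(expected)), 1)
})

test_that("a simulated study round-trips through its TSV artifacts", {
  st <- simulate_clinical_covariates(
    simulate_survival_times(simulate_expression_cohort(
      simulation_config(seed = 58))))
  ep <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(st$expr, ep)
  write_annotation(st$annotation, ap)
  back_e <- read_expression_table(ep)
  back_a <- read_annotation(ap)
  expect_equal(back_e$values, st$expr$values, tolerance = 1e-12)
  expect_equal(back_a$disease_class, st$annotation$disease_class)
  expect_equal(back_a$os_time, st$annotation$os_time, tolerance = 1e-6)
})
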