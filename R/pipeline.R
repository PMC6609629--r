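#' Default end-to-end pipeline configuration
#'
#' Assembles the resolved configuration for [run_full_pipeline()]: the
#' simulation preset (discovery cohort + an independently seeded transfer
#' cohort with the same planted structure), stage toggles, and all stage
#' parameters.
#'
#' @param seed master integer seed; every stage derives its own substream
#'   from it.
#' @param out_dir output directory for artifacts.
#' @param stages character vector of enabled stages, in pipeline order;
#'   subset of `c("simulate", "intersect", "discover", "classify",
#'   "survival", "enrichment")`.
#' @param n_transfer_primary,n_transfer_metastatic transfer-cohort class
#'   sizes (default 191 + 29 = 220).
#' @param k_extreme,k_max,min_size,epsilon,paper_strict signature
#'   discovery parameters (see [discover_signature()]).
#' @param n_perm enrichment permutations.
#' @param cox_alpha backward-selection removal level.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed = 42, out_dir = tempfile("metasig_run_"),
                            stages = c("simulate", "intersect", "discover",
                                       "classify", "survival", "enrichment"),
                            n_transfer_primary = 191,
                            n_transfer_metastatic = 29,
                            k_extreme = NULL, k_max = 3, min_size = 2,
                            epsilon = 1e-6, paper_strict = FALSE,
                            n_perm = 1000, cox_alpha = 0.05) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 n_transfer_primary = n_transfer_primary,
                 n_transfer_metastatic = n_transfer_metastatic,
                 k_extreme = k_extreme, k_max = k_max, min_size = min_size,
                 epsilon = epsilon, paper_strict = paper_strict,
                 n_perm = n_perm, cox_alpha = cox_alpha),
            class = "run_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in order — simulate the discovery and
#' transfer cohorts, intersect the paired DEG lists into the candidate
#' panel, discover the signature by PCA-loading pruning, train and
#' transfer-evaluate the stepwise-AIC classifier, run the survival
#' association (per-gene KM/log-rank and Cox with backward selection),
#' and the phenotype-permutation enrichment of the planted gene set —
#' persisting every intermediate artifact under `cfg$out_dir` plus a
#' single `run_report.json`. Re-running with an identical configuration
#' reproduces byte-identical artifacts. A stage whose inputs were toggled
#' off fails fast naming the missing stage.
#'
#' @param cfg a [pipeline_config()].
#' @return the run report, invisibly; artifacts on disk.
#' @export
run_full_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                 package_version = as.character(utils::packageVersion("metasig")),
                 stages = list())
  state <- new.env(parent = emptyenv())
  need <- function(what, from) {
    if (!exists(what, state))
      stop("stage requires '", what, "' from disabled/failed stage '", from, "'")
    get(what, state)
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  if ("simulate" %in% cfg$stages) {
    degs <- simulate_deg_lists(simulation_config(seed = cfg$seed))
    panel_genes <- degs$shared_genes
    spec <- default_signature_spec()
    # carry the intersection's identifiers into the cohort so the panel
    # discovered downstream is literally the intersected gene list
    stopifnot(length(panel_genes) == nrow(spec))
    spec$gene_id <- panel_genes
    sim_cfg <- simulation_config(seed = cfg$seed, signature_spec = spec,
                                 survival_spec = list(
                                   baseline_hazard = 0.01,
                                   log_hr = stats::setNames(
                                     c(0.5, -0.5), panel_genes[c(2, 9)]),
                                   censoring_rate = 0.3),
                                 cohort = "discovery")
    study <- simulate_clinical_covariates(
      simulate_survival_times(simulate_expression_cohort(sim_cfg)))
    tr_cfg <- simulation_config(seed = substream_seed(cfg$seed, "transfer"),
                                n_normal = 0,
                                n_primary = cfg$n_transfer_primary,
                                n_metastatic = cfg$n_transfer_metastatic,
                                signature_spec = spec, cohort = "transfer")
    transfer <- simulate_expression_cohort(tr_cfg)
    assign("degs", degs, state); assign("study", study, state)
    assign("transfer", transfer, state)
    write_expression_table(study$expr, out("discovery_expr.tsv"))
    write_annotation(study$annotation, out("discovery_ann.tsv"))
    write_expression_table(transfer$expr, out("transfer_expr.tsv"))
    write_annotation(transfer$annotation, out("transfer_ann.tsv"))
    write_deg_table(degs$a, out("deg_list_a.tsv"))
    write_deg_table(degs$b, out("deg_list_b.tsv"))
    write_json_artifact(
      list(planted = study$truth[study$truth$shift != 0,
                                 c("gene_id", "role", "shift")]),
      out("truth.json"))
    report$stages$simulate <- list(
      n_discovery = ncol(study$expr$values),
      n_transfer = ncol(transfer$expr$values),
      n_genes = nrow(study$expr$values))
  }

  if ("intersect" %in% cfg$stages) {
    degs <- need("degs", "simulate")
    venn <- intersect_gene_lists(degs$a, degs$b)
    conc <- direction_concordance(degs$a, degs$b)
    assign("panel", venn$genes, state)
    write_json_artifact(c(venn[c("n_a", "n_b", "n_intersection",
                                 "n_a_only", "n_b_only")],
                          list(genes = venn$genes,
                               discordant_fraction = conc$discordant_fraction)),
                        out("intersection.json"))
    report$stages$intersect <- venn[c("n_a", "n_b", "n_intersection")]
  }

  if ("discover" %in% cfg$stages) {
    study <- need("study", "simulate")
    panel <- need("panel", "intersect")
    disc <- discover_signature(study$expr, study$annotation, panel,
                               k_extreme = cfg$k_extreme, k_max = cfg$k_max,
                               min_size = cfg$min_size, epsilon = cfg$epsilon,
                               paper_strict = cfg$paper_strict)
    assign("signature", disc$signature, state)
    write_json_artifact(list(
      genes = disc$signature$genes,
      final_variance_explained = disc$signature$final_variance_explained,
      final_separation_auc = disc$signature$final_separation$auc,
      separating_component = disc$details$separating_component,
      k_extreme = disc$details$k_extreme), out("signature.json"))
    utils::write.table(disc$trace, out("prune_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$discover <- list(
      signature_size = length(disc$signature$genes),
      final_variance_explained = disc$signature$final_variance_explained,
      final_separation_auc = disc$signature$final_separation$auc)
  }

  if ("classify" %in% cfg$stages) {
    study <- need("study", "simulate")
    signature <- need("signature", "discover")
    transfer <- need("transfer", "simulate")
    # classifier operates on within-cohort standardized expression so the
    # frozen coefficients and threshold transfer across platforms/cohorts
    model <- train_classifier(standardize_genes(study$expr),
                              study$annotation, signature$genes,
                              cohort = "discovery")
    eval_train <- attr(model, "training_report")
    eval_transfer <- evaluate_on_cohort(model, standardize_genes(transfer$expr),
                                        transfer$annotation)
    assign("model", model, state)
    write_json_artifact(list(
      intercept = model$intercept,
      coefficients = as.list(model$coefficients),
      aic = model$aic, threshold = model$threshold,
      training_cohort = model$training_cohort, ridge = model$ridge),
      out("model.json"))
    write_json_artifact(eval_train, out("evaluation_training.json"))
    write_json_artifact(eval_transfer, out("evaluation_transfer.json"))
    report$stages$classify <- list(
      genes = model$genes, aic = model$aic, threshold = model$threshold,
      training_balanced_accuracy = eval_train$balanced_accuracy,
      transfer_balanced_accuracy = eval_transfer$balanced_accuracy,
      transfer_auc = eval_transfer$auc)
  }

  if ("survival" %in% cfg$stages) {
    study <- need("study", "simulate")
    signature <- need("signature", "discover")
    ann <- study$annotation
    keep <- ann$disease_class == "primary" & !is.na(ann$os_time)
    ann <- ann[keep, , drop = FALSE]
    lr <- do.call(rbind, lapply(signature$genes, function(g) {
      grp <- dichotomize_expression(study$expr, g, ann$sample_id)
      t <- log_rank_test(ann$os_time, ann$os_event, grp)
      data.frame(gene_id = g, chi_square = t$chi_square, df = t$df,
                 p_value = t$p_value, stringsAsFactors = FALSE)
    }))
    utils::write.table(lr, out("survival_logrank.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    v <- study$expr$values[signature$genes, ann$sample_id, drop = FALSE]
    z <- as.data.frame(t((v - rowMeans(v)) / apply(v, 1, stats::sd)))
    sel <- cox_backward_select(ann$os_time, ann$os_event, z,
                               alpha = cfg$cox_alpha, univariate_alpha = 0.05)
    if (!is.null(sel$model))
      utils::write.table(sel$model$table, out("cox_multivariable.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_artifact(list(selected = sel$selected,
                             removed = sel$removal_trace,
                             univariate = sel$univariate),
                        out("cox_selection.json"))
    report$stages$survival <- list(
      n_logrank_significant = sum(lr$p_value < 0.05),
      cox_selected = sel$selected)
  }

  if ("enrichment" %in% cfg$stages) {
    study <- need("study", "simulate")
    planted <- study$truth$gene_id[study$truth$shift > 0]
    res <- nes_permutation_test(study$expr, study$annotation, planted,
                                class_a = "metastatic", class_b = "primary",
                                n_perm = cfg$n_perm,
                                seed = substream_seed(cfg$seed, "enrichment"))
    write_json_artifact(res, out("enrichment.json"))
    report$stages$enrichment <- res[c("es", "nes", "nominal_p")]
  }

  write_json_artifact(report, out("run_report.json"))
  invisible(report)
}
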