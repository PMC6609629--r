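#' Simulation configuration for a synthetic expression study
#'
#' Describes the cohort the generator produces: class sizes mirroring the
#' primary/metastatic study design, a planted signature block (a set of
#' genes shifted up in the metastatic class and a smaller set shifted
#' down, emulating over-expressed mitotic kinases plus a down-regulated
#' channel gene and a down-regulated suppressor gene), correlated and
#' independent noise genes, a survival model whose hazard depends on a
#' subset of the planted genes, class-conditional clinical covariates,
#' and a pair of DEG lists with a known intersection.
#'
#' @param seed integer RNG seed; every draw derives from it.
#' @param n_normal,n_primary,n_metastatic class sizes. Defaults mirror
#'   the discovery cohort shape (194 primary + 29 metastatic) plus 29
#'   normals.
#' @param signature_spec data.frame with columns `gene_id`, `role`
#'   (`up_kinase`, `down_channel`, `down_suppressor`, `noise`,
#'   `correlated_noise`), `shift` (mean shift in the metastatic class, in
#'   within-class sd units), `block` (integer id for correlated blocks, NA
#'   for independent genes), `block_cor` (within-block correlation), and
#'   `driver_cor` (correlation of a gene's residual with the first
#'   up-gene's residual; used for the down-suppressor gene, default -0.6).
#'   `NULL` uses the default 9-planted-in-87 panel.
#' @param survival_spec list(`baseline_hazard`, `log_hr` named vector of
#'   per-gene log hazard ratios on standardized expression,
#'   `censoring_rate` in \[0, 1)).
#' @param clinical_spec named list; each covariate is a list of per-class
#'   probability vectors (`normal`, `primary`, `metastatic`) over named
#'   levels, each summing to 1.
#' @param deg_spec list(`n_a`, `n_b`, `n_intersection`,
#'   `discordant_fraction`).
#' @param cohort label stored in the annotation.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 42, n_normal = 29, n_primary = 194,
                              n_metastatic = 29, signature_spec = NULL,
                              survival_spec = NULL, clinical_spec = NULL,
                              deg_spec = NULL, cohort = "synthetic") {
  if (is.null(signature_spec)) signature_spec <- default_signature_spec()
  if (is.null(survival_spec))
    survival_spec <- list(
      baseline_hazard = 0.01,
      log_hr = c(UPK2 = 0.5, DSUP1 = -0.5),
      censoring_rate = 0.3)
  if (is.null(clinical_spec)) clinical_spec <- default_clinical_spec()
  if (is.null(deg_spec))
    deg_spec <- list(n_a = 536, n_b = 2677, n_intersection = 87,
                     discordant_fraction = 0.8)
  cfg <- structure(list(seed = as.integer(seed), n_normal = n_normal,
                        n_primary = n_primary, n_metastatic = n_metastatic,
                        signature_spec = signature_spec,
                        survival_spec = survival_spec,
                        clinical_spec = clinical_spec,
                        deg_spec = deg_spec, cohort = cohort),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# The default ("hotpam_like") panel: 7 up-shifted "kinase" genes, one
# down-shifted "channel" gene, one down-shifted "suppressor" gene
# negatively correlated (-0.6) with the first up gene, embedded among 78
# independent noise genes (87 total). Correlated-noise blocks are
# available for custom configs via n_cor_blocks/block_size/block_cor.
default_signature_spec <- function(shift = 2, n_noise = 78,
                                   n_cor_blocks = 0, block_size = 6,
                                   block_cor = 0.5, driver_cor = -0.6) {
  planted <- data.frame(
    gene_id = c(paste0("UPK", 1:7), "DCH1", "DSUP1"),
    role = c(rep("up_kinase", 7), "down_channel", "down_suppressor"),
    shift = c(rep(shift, 7), -shift, -shift),
    block = NA_integer_, block_cor = NA_real_,
    driver_cor = c(rep(NA_real_, 8), driver_cor),
    stringsAsFactors = FALSE)
  corr <- if (n_cor_blocks > 0) data.frame(
    gene_id = sprintf("CNOI%03d", seq_len(n_cor_blocks * block_size)),
    role = "correlated_noise", shift = 0,
    block = rep(seq_len(n_cor_blocks), each = block_size),
    block_cor = block_cor, driver_cor = NA_real_,
    stringsAsFactors = FALSE)
  noise <- data.frame(
    gene_id = sprintf("NOIS%03d", seq_len(n_noise)),
    role = "noise", shift = 0, block = NA_integer_,
    block_cor = NA_real_, driver_cor = NA_real_,
    stringsAsFactors = FALSE)
  rbind(planted, corr, noise)
}

default_clinical_spec <- function() {
  # age preset follows the discovery cohort's non-missing margins
  # (metastatic 8:13, primary 130:63); lymph node likewise (1:1, 172:1)
  list(
    age_group = list(
      levels = c("<64", ">=64"),
      normal = c(0.5, 0.5),
      primary = c(130, 63) / 193,
      metastatic = c(8, 13) / 21),
    lymph_node = list(
      levels = c("N0", "N1"),
      normal = c(1, 0),
      primary = c(172, 1) / 173,
      metastatic = c(0.5, 0.5)))
}

validate_sim_config <- function(cfg) {
  problems <- character(0)
  if (cfg$n_normal < 0 || cfg$n_primary < 0 || cfg$n_metastatic < 0)
    problems <- c(problems, "cohort sizes must be >= 0")
  ss <- cfg$signature_spec
  need <- c("gene_id", "role", "shift")
  if (!all(need %in% names(ss)))
    problems <- c(problems, "signature_spec needs gene_id/role/shift columns")
  else {
    if (anyDuplicated(ss$gene_id))
      problems <- c(problems, "duplicate gene ids in signature_spec")
    bad <- setdiff(ss$role, c("up_kinase", "down_channel", "down_suppressor",
                              "noise", "correlated_noise"))
    if (length(bad)) problems <- c(problems, paste("unknown role:", bad[1]))
  }
  dg <- cfg$deg_spec
  if (dg$n_intersection > min(dg$n_a, dg$n_b))
    problems <- c(problems, "deg_spec intersection exceeds a list size")
  if (!is.null(dg$discordant_fraction) &&
      (dg$discordant_fraction < 0 || dg$discordant_fraction > 1))
    problems <- c(problems, "discordant_fraction must be in [0, 1]")
  if (cfg$survival_spec$baseline_hazard <= 0)
    problems <- c(problems, "baseline hazard must be positive")
  if (cfg$survival_spec$censoring_rate < 0 || cfg$survival_spec$censoring_rate >= 1)
    problems <- c(problems, "censoring_rate must be in [0, 1)")
  for (v in names(cfg$clinical_spec)) {
    sp <- cfg$clinical_spec[[v]]
    for (cls in c("normal", "primary", "metastatic"))
      if (abs(sum(sp[[cls]]) - 1) > 1e-9)
        problems <- c(problems,
                      paste0("clinical_spec$", v, "$", cls, " does not sum to 1"))
  }
  if (length(problems))
    stop("invalid simulation config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

# Derive a deterministic child seed (< 2^31) for a named substream, so
# toggling one stage never perturbs another stage's draws.
substream_seed <- function(seed, stream) {
  offsets <- c(expression = 1L, survival = 2L, clinical = 3L, deg = 4L,
               enrichment = 5L, transfer = 6L, classifier = 7L)
  if (!stream %in% names(offsets)) stop("unknown stream '", stream, "'")
  (as.integer(seed) %% 1000000L) * 2011L + offsets[[stream]]
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Simulate an expression cohort with a planted signature
#'
#' Gene values are class-conditional Gaussians on the log2 scale: each
#' gene has a random baseline level, unit within-class standard
#' deviation, a mean shift (in sd units) applied to metastatic samples
#' for planted genes, within-block correlation via a shared latent factor
#' for `correlated_noise` blocks, and an optional residual correlation
#' with the first up-gene (the "driver") for the suppressor-like gene.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `sim_study`: `expr` (an [expr_matrix()],
#'   `raw_log2`), `annotation` (sample_id, cohort, disease_class),
#'   `truth` (the signature_spec with per-gene roles), `config`.
#' @export
simulate_expression_cohort <- function(cfg) {
  validate_sim_config(cfg)
  ss <- cfg$signature_spec
  n <- cfg$n_normal + cfg$n_primary + cfg$n_metastatic
  if (n < 2) stop("need at least 2 samples")
  classes <- rep(c("normal", "primary", "metastatic"),
                 c(cfg$n_normal, cfg$n_primary, cfg$n_metastatic))
  sample_id <- sprintf("%s_S%03d", cfg$cohort, seq_len(n))
  with_seed(substream_seed(cfg$seed, "expression"), {
    baseline <- stats::runif(nrow(ss), 5, 9)
    resid <- matrix(stats::rnorm(nrow(ss) * n), nrow(ss), n)
    # correlated blocks share a latent per-sample factor
    for (b in unique(stats::na.omit(ss$block))) {
      idx <- which(!is.na(ss$block) & ss$block == b)
      rho <- ss$block_cor[idx[1]]
      f <- stats::rnorm(n)
      resid[idx, ] <- sqrt(rho) * matrix(f, length(idx), n, byrow = TRUE) +
        sqrt(1 - rho) * resid[idx, ]
    }
    driver <- which(ss$role == "up_kinase")[1]
    for (i in which(!is.na(ss$driver_cor))) {
      r <- ss$driver_cor[i]
      resid[i, ] <- r * resid[driver, ] + sqrt(1 - r^2) * resid[i, ]
    }
    vals <- baseline + resid +
      outer(ss$shift, as.numeric(classes == "metastatic"))
    dimnames(vals) <- list(ss$gene_id, sample_id)
    structure(list(expr = expr_matrix(vals, "raw_log2"),
                   annotation = data.frame(sample_id = sample_id,
                                           cohort = cfg$cohort,
                                           disease_class = classes,
                                           stringsAsFactors = FALSE),
                   truth = ss, config = cfg),
              class = "sim_study")
  })
}

#' Simulate survival outcomes for a study
#'
#' Exponential event times with per-sample hazard
#' `baseline * exp(sum(beta_g * z_g))`, where `z_g` is the gene's
#' cohort-standardized expression, and independent exponential censoring
#' whose rate is tuned (by root-finding) so the expected censoring
#' fraction matches `censoring_rate`; a rate of 0 yields no censoring.
#'
#' @param study a [simulate_expression_cohort()] result.
#' @return the study with `os_time`/`os_event` columns added to
#'   `annotation`.
#' @export
simulate_survival_times <- function(study) {
  cfg <- study$config
  sp <- cfg$survival_spec
  betas <- sp$log_hr
  missing <- setdiff(names(betas), gene_ids(study$expr))
  if (length(missing)) stop("log_hr genes absent: ", paste(missing, collapse = ", "))
  v <- study$expr$values[names(betas), , drop = FALSE]
  z <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
  hazard <- sp$baseline_hazard * exp(drop(crossprod(z, betas)))
  with_seed(substream_seed(cfg$seed, "survival"), {
    t_event <- stats::rexp(length(hazard), hazard)
    if (sp$censoring_rate > 0) {
      target <- sp$censoring_rate
      mu <- stats::uniroot(function(mu) mean(mu / (hazard + mu)) - target,
                           lower = 1e-10, upper = 1e6 * max(hazard))$root
      t_cens <- stats::rexp(length(hazard), mu)
    } else t_cens <- rep(Inf, length(hazard))
    study$annotation$os_time <- pmin(t_event, t_cens)
    study$annotation$os_event <- as.integer(t_event <= t_cens)
    study
  })
}

#' Simulate class-conditional clinical covariates
#'
#' Draws each configured categorical covariate per sample from its
#' class-conditional probability vector; a degenerate (probability 1)
#' spec yields exact counts.
#'
#' @param study a [simulate_expression_cohort()] result.
#' @return the study with covariate columns added to `annotation`.
#' @export
simulate_clinical_covariates <- function(study) {
  cfg <- study$config
  with_seed(substream_seed(cfg$seed, "clinical"), {
    for (v in names(cfg$clinical_spec)) {
      sp <- cfg$clinical_spec[[v]]
      study$annotation[[v]] <- vapply(study$annotation$disease_class,
        function(cls) sample(sp$levels, 1, prob = sp[[cls]]), character(1))
    }
    study
  })
}

#' Simulate a pair of DEG lists with an exact intersection
#'
#' Constructs two gene lists of exactly the configured sizes sharing
#' exactly `n_intersection` symbols; directions on the overlap realize
#' the configured discordant fraction (rounded to the nearest achievable
#' count). Fold-change magnitudes and p-values are drawn to be
#' "significant-looking" but carry no further structure.
#'
#' @param cfg a [simulation_config()].
#' @return list of two DEG data.frames `a` and `b` plus
#'   `shared_genes`.
#' @export
simulate_deg_lists <- function(cfg) {
  validate_sim_config(cfg)
  dg <- cfg$deg_spec
  shared <- sprintf("SHRD%04d", seq_len(dg$n_intersection))
  a_only <- sprintf("AONL%04d", seq_len(dg$n_a - dg$n_intersection))
  b_only <- sprintf("BONL%04d", seq_len(dg$n_b - dg$n_intersection))
  with_seed(substream_seed(cfg$seed, "deg"), {
    mk <- function(genes, sign) deg_table(
      gene_id = genes,
      log2fc = sign * stats::runif(length(genes), 0.5, 4),
      p_value = stats::runif(length(genes), 0, 0.01))
    sign_a <- sample(c(-1, 1), dg$n_a, replace = TRUE)
    a <- mk(c(shared, a_only), sign_a)
    n_disc <- round(dg$discordant_fraction * dg$n_intersection)
    flip <- seq_len(dg$n_intersection) %in%
      sample(dg$n_intersection, n_disc)
    sign_b_shared <- ifelse(flip, -sign_a[seq_len(dg$n_intersection)],
                            sign_a[seq_len(dg$n_intersection)])
    b <- mk(c(shared, b_only),
            c(sign_b_shared, sample(c(-1, 1), length(b_only), replace = TRUE)))
    list(a = a, b = b, shared_genes = shared)
  })
}

#' Simulate a two-cohort stratification problem with planted log-odds
#'
#' Expression for `n_genes` independent standard-normal genes; the class
#' label (primary vs metastatic) is drawn from a logistic model whose
#' linear predictor uses the configured per-gene coefficients. This is
#' the generator behind the classifier-recovery checks, where the ground
#' truth is the log-odds model itself rather than a mean shift.
#'
#' @param n number of samples.
#' @param n_genes number of candidate genes.
#' @param beta named numeric vector of planted log-odds coefficients
#'   (names must be within the generated `GENE1..GENEk` ids).
#' @param intercept logistic intercept (controls class balance).
#' @param seed integer seed.
#' @param cohort cohort label.
#' @return list with `expr`, `annotation`, `truth` (the beta vector).
#' @export
simulate_logistic_cohort <- function(n, n_genes, beta, intercept = -1,
                                     seed = 1, cohort = "logit") {
  genes <- sprintf("GENE%d", seq_len(n_genes))
  if (length(setdiff(names(beta), genes)))
    stop("beta names outside the generated genes")
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * n), n_genes, n,
                dimnames = list(genes, sprintf("%s_S%04d", cohort, seq_len(n))))
    eta <- intercept + drop(crossprod(x[names(beta), , drop = FALSE], beta))
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    list(expr = expr_matrix(x, "raw_log2"),
         annotation = data.frame(
           sample_id = colnames(x), cohort = cohort,
           disease_class = ifelse(y == 1, "metastatic", "primary"),
           stringsAsFactors = FALSE),
         truth = beta)
  })
}
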