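#' Dichotomize a gene's expression at the cohort median
#'
#' Samples at or below the median are labelled `low`, those above `high`;
#' a value exactly at the median therefore goes to `low`. With no ties
#' the two groups differ in size by at most one.
#'
#' @param m an [expr_matrix()].
#' @param gene gene id present in `m`.
#' @param samples optional sample ids (default all).
#' @return factor of `low`/`high` labels named by sample, with attribute
#'   `"sizes"` giving the group sizes and `"cutpoint"` the median used.
#' @export
dichotomize_expression <- function(m, gene, samples = NULL) {
  gene <- normalize_gene_ids(gene)
  if (length(gene) != 1 || !gene %in% gene_ids(m))
    stop("gene '", gene, "' not present in the matrix")
  if (is.null(samples)) samples <- sample_ids(m)
  v <- m$values[gene, samples]
  if (stats::sd(v) == 0) stop("gene '", gene, "' is constant; cannot dichotomize")
  med <- stats::median(v)
  g <- factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
  names(g) <- samples
  attr(g, "sizes") <- table(g)
  attr(g, "cutpoint") <- med
  g
}

# Validate (time, event) pairs shared by the estimators below.
check_survival <- function(time, event) {
  if (!length(time)) stop("empty survival data")
  if (length(time) != length(event)) stop("time and event differ in length")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; censored subjects leave the risk set
#' after their censoring time.
#'
#' @param time positive event/censoring times.
#' @param event 0 = censored, 1 = event.
#' @return data.frame with `time` (distinct observed times, ascending),
#'   `n_risk`, `n_event`, `n_censor`, `survival` (non-increasing from 1).
#' @export
km_estimate <- function(time, event) {
  check_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected chi-square with hypergeometric variance at
#' each distinct event time ([survival::survdiff()] with `rho = 0`).
#'
#' @param time positive times.
#' @param event 0/1 event indicators; at least one event required.
#' @param group group labels (>= 2 groups).
#' @return list with `chi_square`, `df` (groups - 1), `p_value`.
#' @export
log_rank_test <- function(time, event, group) {
  check_survival(time, event)
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (sum(event) < 1) stop("need at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- nlevels(group) - 1
  list(chi_square = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression (Efron ties)
#'
#' Wraps [survival::coxph()] with the Efron tie correction (Breslow
#' available behind `ties`). Reports per-covariate log-hazard, hazard
#' ratio with normal-approximation 95% CI on the log scale, and Wald p.
#'
#' @param time positive times.
#' @param event 0/1 indicators.
#' @param covariates data.frame of numeric or factor covariates (no
#'   constant column; events >= number of estimated coefficients).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_model`: list with `table` (data.frame:
#'   `term, beta, hr, ci_lower, ci_upper, se, p_value`), `loglik`,
#'   `score_test`, `n_events`, `ties`, `converged`, `separation` flag.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival(time, event)
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("no covariates")
  const <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  df <- data.frame(.time = time, .event = event, covariates, check.names = FALSE)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = ties, control = survival::coxph.control(iter.max = 100))
  if (sum(event) < length(stats::coef(fit)))
    stop("fewer events (", sum(event), ") than coefficients (",
         length(stats::coef(fit)), ")")
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("Cox fit failed to estimate: ",
                        paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  separation <- any(abs(beta) > 15)      # monotone likelihood heuristic
  if (separation) warning("possible monotone likelihood (separation) in Cox fit")
  structure(list(
    table = data.frame(term = names(beta), beta = unname(beta),
                       hr = exp(unname(beta)),
                       ci_lower = exp(unname(beta) - 1.96 * se),
                       ci_upper = exp(unname(beta) + 1.96 * se),
                       se = se,
                       p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
                       row.names = NULL, stringsAsFactors = FALSE),
    loglik = fit$loglik[2], score_test = unname(fit$score),
    n_events = sum(event), ties = ties,
    converged = fit$iter < 100, separation = separation),
    class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("cox_model (%s ties, %d events):\n", x$ties, x$n_events))
  print(x$table, digits = 3)
  invisible(x)
}

#' Backward selection of Cox covariates by Wald p-value
#'
#' Iteratively removes the covariate with the largest Wald p while that p
#' exceeds `alpha`, refitting after each removal. With
#' `univariate_alpha` set, candidates are first screened by univariate
#' Cox p-value (two-sided) at that level, the conventional prelude to a
#' multivariable model. All covariates removed yields an empty model.
#'
#' @inheritParams cox_fit
#' @param alpha removal significance level (default 0.05).
#' @param univariate_alpha if non-`NULL`, pre-screen candidates by
#'   univariate p < `univariate_alpha`.
#' @return list with `model` (a `cox_model`, or `NULL` if everything was
#'   removed), `selected` covariate names, `removal_trace` (data.frame of
#'   `removed`, `p_value`, in order), and `univariate` (screening table or
#'   `NULL`).
#' @export
cox_backward_select <- function(time, event, covariates, alpha = 0.05,
                                univariate_alpha = NULL,
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  uni <- NULL
  if (!is.null(univariate_alpha)) {
    uni <- do.call(rbind, lapply(names(covariates), function(v) {
      f <- cox_fit(time, event, covariates[v], ties)
      data.frame(term = v, p_value = min(f$table$p_value),
                 stringsAsFactors = FALSE)
    }))
    covariates <- covariates[, uni$term[uni$p_value < univariate_alpha],
                             drop = FALSE]
  }
  trace <- list()
  fit <- NULL
  while (ncol(covariates)) {
    fit <- cox_fit(time, event, covariates, ties)
    # covariate-level p: smallest level p for factors
    pv <- vapply(names(covariates), function(v)
      min(fit$table$p_value[startsWith(fit$table$term, v)]), numeric(1))
    worst <- which.max(pv)
    if (pv[worst] > alpha) {
      trace[[length(trace) + 1]] <- data.frame(
        removed = names(covariates)[worst], p_value = unname(pv[worst]),
        stringsAsFactors = FALSE)
      covariates <- covariates[, -worst, drop = FALSE]
      fit <- NULL
    } else break
  }
  list(model = fit, selected = names(covariates),
       removal_trace = rbind_rows(trace),
       univariate = uni)
}
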