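# Design matrix (samples x genes) and 0/1 outcome for the two-class
# stratification problem; normals are excluded throughout.
stratification_data <- function(m, ann, genes,
                                class_a = "primary", class_b = "metastatic") {
  genes <- normalize_gene_ids(genes)
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing))
    stop("model genes absent from the cohort matrix: ",
         paste(missing, collapse = ", "))
  ann2 <- align_annotation(m, ann)
  keep <- ann2$disease_class %in% c(class_a, class_b)
  x <- t(m$values[genes, keep, drop = FALSE])
  y <- as.integer(ann2$disease_class[keep] == class_b)
  list(x = x, y = y, sample_id = ann2$sample_id[keep])
}

# Ridge-penalized logistic IRLS (intercept unpenalized): the fallback for
# complete separation, where the unpenalized MLE diverges.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 200, tol = 1e-10) {
  xx <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xx)
  pen <- diag(c(0, rep(lambda, p - 1)), p, p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xx %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    zres <- eta + (y - mu) / w
    fit <- solve(crossprod(xx, xx * w) + 2 * pen, crossprod(xx, w * zres))
    if (max(abs(fit - beta)) < tol) { beta <- drop(fit); break }
    beta <- drop(fit)
  }
  names(beta) <- colnames(xx)
  beta
}

logistic_loglik <- function(x, y, intercept, coef) {
  eta <- intercept + if (length(coef)) drop(x[, names(coef), drop = FALSE] %*% coef) else 0
  sum(y * eta - log1p(exp(eta)))
}

#' Fit a logistic stratification model on signature genes
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of metastatic-vs-primary class on gene
#' expression. The outcome is 1 for the metastatic class; normal samples
#' are excluded. When the classes are completely separable the MLE
#' diverges, so a small ridge penalty (`lambda = 1e-4`, intercept
#' unpenalized) is used instead, with a warning; the reported AIC then
#' uses the unpenalized log-likelihood at the ridge estimates.
#'
#' @param m an [expr_matrix()].
#' @param ann sample annotation.
#' @param genes character vector of predictor genes (may be empty for the
#'   intercept-only model).
#' @param class_a,class_b negative / positive outcome classes.
#' @return object of class `strat_model`: list with `intercept`,
#'   `coefficients` (named by gene), `aic`, `threshold` (`NA` until
#'   [choose_threshold()]), `training_cohort`, `genes`, `ridge` flag.
#' @export
fit_logistic <- function(m, ann, genes, class_a = "primary",
                         class_b = "metastatic") {
  d <- stratification_data(m, ann, genes, class_a, class_b)
  if (length(unique(d$y)) < 2) stop("outcome has a single class")
  if (min(table(d$y)) < 2) stop("each class needs at least 2 samples")
  if (!length(genes)) {
    fit <- stats::glm(d$y ~ 1, family = stats::binomial())
    return(new_strat_model(unname(stats::coef(fit)[1]), numeric(0),
                           stats::AIC(fit), ridge = FALSE))
  }
  df <- data.frame(.y = d$y, d$x, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || anyNA(stats::coef(fit))) {
    warning("complete separation detected; refitting with ridge penalty lambda = 1e-4")
    beta <- ridge_logistic(d$x, d$y)
    coef <- beta[-1]
    ll <- logistic_loglik(d$x, d$y, beta[1], coef)
    return(new_strat_model(unname(beta[1]), coef,
                           2 * (length(beta)) - 2 * ll, ridge = TRUE))
  }
  cf <- stats::coef(fit)
  new_strat_model(unname(cf[1]), cf[-1], stats::AIC(fit), ridge = FALSE)
}

new_strat_model <- function(intercept, coefficients, aic, ridge = FALSE,
                            threshold = NA_real_, training_cohort = NA_character_) {
  names(coefficients) <- sub("^`|`$", "", names(coefficients))
  structure(list(intercept = intercept, coefficients = coefficients,
                 aic = aic, threshold = threshold,
                 training_cohort = training_cohort,
                 genes = names(coefficients), ridge = ridge),
            class = "strat_model")
}

#' @export
print.strat_model <- function(x, ...) {
  cat(sprintf("strat_model: %d gene(s) [%s], AIC %.2f, threshold %s\n",
              length(x$coefficients),
              paste(x$genes, collapse = ", "), x$aic,
              if (is.na(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

#' Predicted metastasis probability scores
#'
#' @param model a `strat_model`.
#' @param m an [expr_matrix()] containing all model genes.
#' @param samples optional sample ids to score (default all).
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_scores <- function(model, m, samples = NULL) {
  missing <- setdiff(model$genes, gene_ids(m))
  if (length(missing))
    stop("model genes absent from the cohort matrix: ",
         paste(missing, collapse = ", "))
  if (is.null(samples)) samples <- sample_ids(m)
  eta <- model$intercept
  if (length(model$genes))
    eta <- eta + drop(crossprod(m$values[model$genes, samples, drop = FALSE],
                                model$coefficients))
  p <- stats::plogis(eta)
  names(p) <- samples
  p
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starts from the intercept-only model; each round evaluates every
#' single-gene addition and removal, applies the move with the lowest AIC
#' if it improves on the current model, and stops at a local minimum.
#' Candidate moves are evaluated in lexicographic gene order, so exact AIC
#' ties resolve to the alphabetically first gene. The returned model's
#' AIC never exceeds the intercept-only AIC.
#'
#' @inheritParams fit_logistic
#' @param candidate_genes nonempty character vector of candidate
#'   predictors.
#' @param direction `"both"` (default), `"forward"` (additions only) or
#'   `"backward"` (start from the full model, removals only).
#' @return the selected `strat_model`, with attribute `"search_trace"`
#'   recording each applied move.
#' @export
stepwise_aic_select <- function(m, ann, candidate_genes, direction = "both",
                                class_a = "primary", class_b = "metastatic") {
  direction <- match.arg(direction, c("both", "forward", "backward"))
  candidates <- sort(normalize_gene_ids(candidate_genes))
  if (!length(candidates)) stop("no candidate genes")
  current <- if (direction == "backward") candidates else character(0)
  fit <- fit_logistic(m, ann, current, class_a, class_b)
  trace <- list()
  repeat {
    moves <- list()
    if (direction %in% c("both", "forward"))
      for (g in setdiff(candidates, current))
        moves[[paste0("+", g)]] <- c(current, g)
    if (direction %in% c("both", "backward"))
      for (g in intersect(candidates, current))
        moves[[paste0("-", g)]] <- setdiff(current, g)
    if (!length(moves)) break
    fits <- lapply(moves, function(gs)
      suppressWarnings(fit_logistic(m, ann, gs, class_a, class_b)))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- which.min(aics)              # first minimum: lexicographic tie-break
    if (aics[best] < fit$aic) {
      trace[[length(trace) + 1]] <- data.frame(
        move = names(moves)[best], aic = aics[best], stringsAsFactors = FALSE)
      current <- sort(moves[[best]])
      fit <- fits[[best]]
    } else break
  }
  attr(fit, "search_trace") <- rbind_rows(trace)
  fit
}

#' ROC curve with tie-aware trapezoidal AUC
#'
#' The curve has one operating point per distinct score value (rule:
#' score >= threshold is called positive). Reported thresholds follow the
#' midpoint convention (as in the pROC package): +Inf (nothing called
#' positive), the midpoints between consecutive distinct scores, and
#' -Inf (everything called positive), so a chosen threshold sits in the
#' middle of the score gap it separates rather than on a training score.
#' Tied scores contribute diagonal segments, so the trapezoidal area
#' equals the tie-aware Mann-Whitney concordance (ties counting half).
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector; TRUE/1 = positive class.
#' @return list with `thresholds` (descending), `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  distinct <- !duplicated(s)
  cum_tp <- cumsum(y); cum_fp <- cumsum(!y)
  last <- c(which(distinct)[-1] - 1, length(s))   # last index of each tie block
  tpr <- c(0, cum_tp[last] / sum(labels))
  fpr <- c(0, cum_fp[last] / sum(!labels))
  sd <- s[distinct]
  thresholds <- c(Inf, (sd[-length(sd)] + sd[-1]) / 2, -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc)
}

#' Choose the balanced-accuracy-optimal decision threshold
#'
#' Scans the ROC curve's thresholds and returns the one maximizing
#' balanced accuracy (sensitivity + specificity)/2 — equivalently the
#' Youden J maximizer. Exact ties are broken toward the smaller
#' threshold.
#'
#' @param curve a [roc_auc()] result.
#' @return list with `threshold` and `report` (the training-cohort
#'   [classification_report()] quantities at that threshold).
#' @export
choose_threshold <- function(curve) {
  ba <- (curve$tpr + (1 - curve$fpr)) / 2
  finite <- is.finite(curve$thresholds)
  if (!any(finite)) finite <- rep(TRUE, length(ba))  # single distinct score
  best_ba <- max(ba[finite])
  idx <- which(finite & ba >= best_ba - 1e-12)
  threshold <- min(curve$thresholds[idx])
  i <- max(idx)                          # thresholds descend: max index = smallest
  list(threshold = threshold,
       report = list(balanced_accuracy = ba[i],
                     sensitivity = curve$tpr[i],
                     specificity = 1 - curve$fpr[i],
                     auc = curve$auc))
}

#' Confusion counts and summary metrics at a fixed threshold
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1; TRUE = positive.
#' @param threshold decision threshold (score >= threshold -> positive).
#' @return list with confusion counts `tp, fp, tn, fn`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `auc`.
#' @export
classification_report <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       auc = roc_auc(scores, labels)$auc)
}

#' Train a stratification model with an optimal threshold
#'
#' Stepwise-AIC gene selection, then ROC analysis of the fitted
#' probabilities on the training cohort and balanced-accuracy-optimal
#' threshold selection. The training-cohort metrics are resubstitution
#' estimates.
#'
#' @inheritParams stepwise_aic_select
#' @param cohort label stored as `training_cohort`.
#' @return a `strat_model` with `threshold` set, plus attributes
#'   `"training_report"` and `"search_trace"`.
#' @export
train_classifier <- function(m, ann, candidate_genes, cohort = "training",
                             direction = "both",
                             class_a = "primary", class_b = "metastatic") {
  model <- stepwise_aic_select(m, ann, candidate_genes, direction,
                               class_a, class_b)
  d <- stratification_data(m, ann, model$genes, class_a, class_b)
  scores <- predict_scores(model, m, d$sample_id)
  curve <- roc_auc(scores, d$y == 1)
  ch <- choose_threshold(curve)
  model$threshold <- ch$threshold
  model$training_cohort <- cohort
  attr(model, "training_report") <-
    c(classification_report(scores, d$y == 1, ch$threshold),
      list(resubstitution = TRUE))
  model
}

#' Evaluate a frozen model on a cohort
#'
#' Applies the model's coefficients and threshold without refitting;
#' errors if any model gene is absent from the cohort matrix.
#'
#' @param model a `strat_model` with its threshold set.
#' @param m cohort [expr_matrix()].
#' @param ann cohort annotation (must contain both classes).
#' @return [classification_report()] list.
#' @export
evaluate_on_cohort <- function(model, m, ann,
                               class_a = "primary", class_b = "metastatic") {
  if (is.na(model$threshold))
    stop("model threshold not set; run train_classifier/choose_threshold first")
  d <- stratification_data(m, ann, model$genes, class_a, class_b)
  if (length(unique(d$y)) < 2) stop("cohort must contain both classes")
  scores <- predict_scores(model, m, d$sample_id)
  classification_report(scores, d$y == 1, model$threshold)
}
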