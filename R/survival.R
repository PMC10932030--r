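# Survival evaluation of raw features vs embeddings:
# LASSO selection -> multivariate Cox PH -> significant-coefficient risk
# score -> median split -> Kaplan-Meier / log-rank / hazard ratio.

#' LASSO predictor selection against observed survival time
#'
#' L1-penalised linear regression of the observed follow-up time on the
#' predictors (censoring enters only at the later Cox/KM stages). The
#' penalty is chosen by cross-validated grid search over
#' `alpha_grid` (default {0.001, 0.002, 0.005, 0.01, 0.05, 1.0}); the
#' predictors with nonzero coefficients at the selected penalty are
#' returned.
#'
#' @param features numeric sample-by-predictor matrix (z-scored or binary),
#'   sample IDs as rownames matching `survival`.
#' @param survival a [survival_table()].
#' @param alpha_grid positive penalty values to search.
#' @param nfolds cross-validation folds (default 5).
#' @return character vector of selected predictor names (possibly empty).
#' @export
lasso_select <- function(features, survival,
                         alpha_grid = default_config()$lasso_alpha_grid,
                         nfolds = 5) {
  X <- unclass(features)
  if (nrow(X) < 10) stop("lasso_select: fewer than 10 samples")
  if (any(alpha_grid <= 0)) {
    stop("lasso_select: penalty values must be > 0 (0 is not in the grid)")
  }
  rows <- match(rownames(X), survival$sample_id)
  if (anyNA(rows)) stop("lasso_select: samples missing from survival table")
  y <- survival$time[rows]
  lambda <- sort(unique(alpha_grid), decreasing = TRUE)
  if (length(lambda) < 2) lambda <- c(lambda * 1.0001, lambda)
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, lambda = lambda, nfolds = nfolds,
                          standardize = FALSE)
  beta <- stats::coef(cv, s = "lambda.min")[-1, 1]
  names(beta)[beta != 0]
}

#' Fit a multivariate Cox proportional hazards model
#'
#' Maximises the Cox partial likelihood with Breslow tie handling and
#' reports per-predictor coefficients (log hazard ratios), hazard ratios
#' and Wald p-values.
#'
#' @param features numeric sample-by-predictor matrix (no constant
#'   columns), sample IDs as rownames.
#' @param survival a [survival_table()].
#' @return a `cox_model` list with `coef`, `hazard_ratio`, `p_value`,
#'   `predictors` and the underlying `survival::coxph` fit.
#' @export
fit_coxph <- function(features, survival) {
  X <- unclass(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  rows <- match(rownames(X), survival$sample_id)
  if (anyNA(rows)) stop("fit_coxph: samples missing from survival table")
  if (sum(survival$event[rows]) < 1) stop("fit_coxph: no observed events")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("fit_coxph: constant predictor(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  nm <- colnames(X)
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_along(nm))   # shield arbitrary predictor names
  df$.time <- survival$time[rows]
  df$.event <- survival$event[rows]
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(df)[seq_along(nm)], collapse = "+")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        stop("fit_coxph: ", conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(survival::coxph(fml, data = df, ties = "breslow"))
    })
  cf <- stats::coef(fit)
  names(cf) <- nm[match(names(cf), paste0("v", seq_along(nm)))]
  if (anyNA(cf)) {
    stop("fit_coxph: singular information matrix; offending predictor(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  s <- summary(fit)
  pv <- s$coefficients[, "Pr(>|z|)"]
  names(pv) <- names(cf)
  structure(list(coef = cf, hazard_ratio = exp(cf), p_value = pv,
                 predictors = names(cf), fit = fit), class = "cox_model")
}

#' Risk scores from significant Cox predictors, with median split
#'
#' Keeps the predictors with Wald p-value below `p_threshold` (default
#' 0.05) and scores each sample as `sum_i X_i * Coef_i` over the kept
#' predictors. Samples with score less than or equal to the median form
#' the low-risk group, the rest the high-risk group.
#'
#' @param model a `cox_model` from [fit_coxph()].
#' @param features the predictor matrix the model was fitted on (or new
#'   samples with the same columns).
#' @param p_threshold significance threshold for keeping predictors.
#' @return a data.frame `risk_scores` (sample_id, score, group) with
#'   attribute `kept` (predictor names).
#' @export
compute_risk_scores <- function(model, features, p_threshold = 0.05) {
  kept <- model$predictors[model$p_value < p_threshold]
  if (!length(kept)) {
    stop("compute_risk_scores: no predictor significant at p < ", p_threshold,
         "; consider relaxing the threshold")
  }
  X <- unclass(features)
  score <- drop(X[, kept, drop = FALSE] %*% model$coef[kept])
  med <- stats::median(score)
  group <- ifelse(score <= med, "low", "high")
  if (all(group == "low")) {
    warning("compute_risk_scores: all scores at/below the median; degenerate split")
  }
  structure(data.frame(sample_id = rownames(X), score = score, group = group,
                       stringsAsFactors = FALSE),
            kept = kept, class = c("risk_scores", "data.frame"))
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) is the product over distinct event times up to t of
#' (1 - d_i / n_i); censored-only times reduce the risk set without a
#' factor.
#'
#' @param survival a [survival_table()].
#' @return a `km_curve` data.frame (time, n_risk, n_event, surv) at the
#'   distinct observed times, plus the `survfit` object as an attribute.
#' @export
km_estimate <- function(survival) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            survfit = fit, class = c("km_curve", "data.frame"))
}

#' Survival probability of a KM curve at given times
#' @param curve a `km_curve`.
#' @param times evaluation times.
#' @return numeric survival probabilities (S(0) = 1).
#' @export
km_surv_at <- function(curve, times) {
  vapply(times, function(tt) {
    past <- curve$surv[curve$time <= tt & curve$n_event > 0]
    if (length(past)) min(past) else 1
  }, 0)
}

#' Two-group log-rank test with hazard ratio
#'
#' At each distinct event time, observed events per group are compared
#' with their hypergeometric expectation; the chi-square statistic (1 df)
#' and p-value are reported, together with the hazard ratio of group B vs
#' group A from a univariate Cox fit on the group indicator.
#'
#' @param group_a,group_b [survival_table()]s for the two groups.
#' @return list with `chi_square`, `p_value`, `hazard_ratio` (B vs A),
#'   `n` per group.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b)) stop("logrank_test: empty group")
  if (sum(group_a$event) + sum(group_b$event) == 0) {
    stop("logrank_test: no events in either group")
  }
  df <- data.frame(time = c(group_a$time, group_b$time),
                   event = c(group_a$event, group_b$event),
                   grp = rep(c("A", "B"), c(nrow(group_a), nrow(group_b))))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  chi <- sd_$chisq
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  hr <- tryCatch({
    cf <- survival::coxph(survival::Surv(time, event) ~ grp, data = df,
                          ties = "breslow")
    unname(exp(stats::coef(cf)))
  }, error = function(e) NA_real_, warning = function(w) {
    suppressWarnings(unname(exp(stats::coef(
      survival::coxph(survival::Surv(time, event) ~ grp, data = df,
                      ties = "breslow")))))
  })
  list(chi_square = chi, p_value = p, hazard_ratio = hr,
       n = c(A = nrow(group_a), B = nrow(group_b)))
}

#' Full risk-stratification chain on one feature matrix
#'
#' LASSO selection, multivariate Cox, significant-coefficient risk scores,
#' median split, per-group KM curves, and the low- vs high-risk log-rank
#' test.
#'
#' @param features numeric sample-by-predictor matrix.
#' @param survival a [survival_table()] covering the samples.
#' @param alpha_grid LASSO penalty grid.
#' @param p_threshold Cox significance threshold.
#' @return list with `selected`, `cox`, `risk`, `km_low`, `km_high`,
#'   `logrank`.
#' @export
risk_stratify <- function(features, survival,
                          alpha_grid = default_config()$lasso_alpha_grid,
                          p_threshold = 0.05) {
  if (is.null(dim(features)) || ncol(features) == 0 || nrow(features) == 0) {
    stop("risk_stratify: empty feature matrix")
  }
  selected <- lasso_select(features, survival, alpha_grid)
  if (!length(selected)) stop("risk_stratify: LASSO selected no predictors")
  cox <- fit_coxph(unclass(features)[, selected, drop = FALSE], survival)
  risk <- compute_risk_scores(cox, unclass(features)[, selected, drop = FALSE],
                              p_threshold)
  rows <- match(risk$sample_id, survival$sample_id)
  surv_aligned <- survival[rows, ]
  low <- surv_aligned[risk$group == "low", ]
  high <- surv_aligned[risk$group == "high", ]
  list(selected = selected, cox = cox, risk = risk,
       km_low = km_estimate(low), km_high = km_estimate(high),
       logrank = logrank_test(low, high))
}

#' Side-by-side survival evaluation of raw features vs embeddings
#'
#' Runs the full LASSO -> Cox -> risk score -> median split -> KM/log-rank
#' chain independently on the raw feature matrix and on the embedding
#' matrix, and reports both results. A chain that fails on one input (e.g.
#' no significant predictor) yields `NA` for that side rather than
#' aborting the comparison.
#'
#' @param raw,embeddings numeric matrices over the same samples.
#' @param survival a [survival_table()].
#' @param ... passed to [risk_stratify()].
#' @return list with `raw`, `embeddings` (each a [risk_stratify()] result
#'   or an error condition) and `p_values` (named numeric, NA on failure).
#' @export
compare_feature_sets <- function(raw, embeddings, survival, ...) {
  if (is.null(dim(embeddings)) || ncol(embeddings) == 0) {
    stop("compare_feature_sets: empty embedding matrix")
  }
  if (!setequal(rownames(raw), rownames(embeddings))) {
    stop("compare_feature_sets: sample sets differ")
  }
  run_arm <- function(X) tryCatch(risk_stratify(X, survival, ...),
                                  error = function(e) e)
  res_raw <- run_arm(raw)
  res_emb <- run_arm(embeddings)
  pv <- function(r) if (inherits(r, "error")) NA_real_ else r$logrank$p_value
  list(raw = res_raw, embeddings = res_emb,
       p_values = c(raw = pv(res_raw), embeddings = pv(res_emb)))
}
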