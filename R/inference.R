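#' Nagelkerke pseudo-R-squared
#'
#' \deqn{R^2_N = \frac{1 - (L_0 / L_1)^{2/n}}{1 - L_0^{2/n}}}
#' computed from log-likelihoods: `ll0` of the intercept-only model and
#' `ll1` of the model of interest.
#'
#' @param ll1 log-likelihood of the model.
#' @param ll0 log-likelihood of the intercept-only model.
#' @param n number of observations.
#' @return pseudo-R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(ll1, ll0, n) {
  r2cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2cs / (1 - exp(2 * ll0 / n))
}

#' Change in Nagelkerke pseudo-R-squared between nested models
#'
#' `delta = R2_N(full) - R2_N(null)`, both computed against the same
#' intercept-only likelihood; the full and null fits must be on identical
#' rows.
#'
#' @param ll_intercept log-likelihood of the intercept-only model.
#' @param ll_null log-likelihood of the covariates-only (null) model.
#' @param ll_full log-likelihood of the full model (covariates + score).
#' @param n number of observations (must be common to all three fits).
#' @return the change in pseudo-R-squared (a fraction; multiply by 100 for
#'   percent).
#' @export
nagelkerke_delta <- function(ll_intercept, ll_null, ll_full, n) {
  nagelkerke_r2(ll_full, ll_intercept, n) - nagelkerke_r2(ll_null, ll_intercept, n)
}

# quote non-syntactic column names for formulas
.bt <- function(x) paste0("`", x, "`")

.complete_rows <- function(data, cols) {
  used <- data[, cols, drop = FALSE]
  stats::complete.cases(used)
}

.assoc_result <- function(score, model, n, estimate, se, p, ll_intercept,
                          ll_null, ll_full, tau2 = NA_real_,
                          converged = TRUE, flag = NA_character_,
                          n_dropped = 0L) {
  structure(list(
    score = score, model = model, n = n,
    estimate = estimate, se = se,
    aOR = exp(estimate),
    ci_lower = exp(estimate - 1.96 * se),
    ci_upper = exp(estimate + 1.96 * se),
    p = p,
    ll_intercept = ll_intercept, ll_null = ll_null, ll_full = ll_full,
    delta_r2 = nagelkerke_delta(ll_intercept, ll_null, ll_full, n),
    tau2 = tau2, converged = converged, flag = flag, n_dropped = n_dropped
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: aOR = %.3f (95%% CI %.3f-%.3f), p = %.3g, delta pseudo-R2 = %.4f, n = %d%s\n",
    x$score, x$model, x$aOR, x$ci_lower, x$ci_upper, x$p, x$delta_r2, x$n,
    ifelse(is.na(x$flag), "", paste0(" [", x$flag, "]"))
  ))
  invisible(x)
}

#' Logistic association of a risk score with onset class
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' z-scored risk score plus covariates. Rows with missing values in any
#' used column are dropped listwise (count recorded). Reports the adjusted
#' odds ratio per SD of the score with Wald 95% CI and p, and the change in
#' Nagelkerke pseudo-R-squared between the covariates-only model and the
#' full model. Perfect separation is flagged rather than reported as a
#' finite estimate.
#'
#' @param data data frame holding outcome, score and covariate columns
#'   (e.g. a phenotype table merged with [scores_wide()]).
#' @param score name of the score column of interest.
#' @param covariates character vector of adjustment columns (may include
#'   other score columns, as in joint models).
#' @param outcome name of the binary outcome column (default `"onset"`).
#' @param model label stored in the result.
#' @return an `association_result`.
#' @export
fit_logistic <- function(data, score, covariates = character(),
                         outcome = "onset", model = "logistic") {
  cols <- c(outcome, score, covariates)
  keep <- .complete_rows(data, cols)
  d <- data[keep, cols, drop = FALSE]
  n <- nrow(d)
  rhs_null <- if (length(covariates) == 0) "1" else paste(.bt(covariates), collapse = " + ")
  f_full <- stats::as.formula(paste(.bt(outcome), "~", .bt(score), "+", rhs_null))
  f_null <- stats::as.formula(paste(.bt(outcome), "~", rhs_null))
  f_int <- stats::as.formula(paste(.bt(outcome), "~ 1"))
  fit_full <- stats::glm(f_full, data = d, family = stats::binomial())
  fit_null <- stats::glm(f_null, data = d, family = stats::binomial())
  fit_int <- stats::glm(f_int, data = d, family = stats::binomial())
  co <- summary(fit_full)$coefficients
  rn <- rownames(co)[grepl(score, rownames(co), fixed = TRUE)][1]
  est <- co[rn, 1]; se <- co[rn, 2]; p <- co[rn, 4]
  mu <- stats::fitted(fit_full)
  # separation shows up as boundary fitted probabilities / runaway coefs,
  # usually together with an IRLS convergence failure: check it first
  flag <- if (abs(est) > 15 || any(mu < 1e-10) || any(mu > 1 - 1e-10)) "separation"
          else if (!fit_full$converged) "nonconvergence"
          else NA_character_
  .assoc_result(score, model, n, est, se, p,
                ll_intercept = as.numeric(stats::logLik(fit_int)),
                ll_null = as.numeric(stats::logLik(fit_null)),
                ll_full = as.numeric(stats::logLik(fit_full)),
                converged = fit_full$converged, flag = flag,
                n_dropped = sum(!keep))
}

#' Mixed-effects logistic association with a family random intercept
#'
#' Random-intercept logistic regression fitted by Laplace-approximated
#' (`nAGQ = 1`, default) or adaptive Gauss-Hermite (`nAGQ > 1`) marginal
#' likelihood via [lme4::glmer()]. Reports the fixed-effect adjusted odds
#' ratio per SD of the score, Wald CI and p, the estimated random-intercept
#' variance, and the change in Nagelkerke pseudo-R-squared computed by
#' default from the integrated (marginal) likelihoods of the fitted models
#' (`r2_likelihood = "conditional"` instead plugs the conditional
#' Bernoulli likelihoods at the fitted probabilities into the same formula).
#'
#' @inheritParams fit_logistic
#' @param family_col name of the family-index column.
#' @param nAGQ quadrature order passed to [lme4::glmer()].
#' @param r2_likelihood likelihood used in the pseudo-R-squared:
#'   `"marginal"` (default) or `"conditional"`.
#' @param pseudo_r2 when `FALSE`, skip the covariates-only and
#'   intercept-only refits and report `delta_r2 = NA` (used by replicate
#'   studies that only need the score estimate).
#' @return an `association_result` (with `tau2` filled).
#' @export
fit_mixed_logistic <- function(data, score, covariates = character(),
                               outcome = "onset", family_col = "family",
                               nAGQ = 1L, r2_likelihood = c("marginal", "conditional"),
                               model = "mixed logistic", pseudo_r2 = TRUE) {
  r2_likelihood <- match.arg(r2_likelihood)
  if (length(unique(data[[family_col]])) < 2) stop("need at least 2 families")
  cols <- c(outcome, score, covariates, family_col)
  keep <- .complete_rows(data, cols)
  d <- data[keep, cols, drop = FALSE]
  n <- nrow(d)
  re <- sprintf("(1 | %s)", .bt(family_col))
  rhs_cov <- if (length(covariates) == 0) "" else
    paste("+", paste(.bt(covariates), collapse = " + "))
  f_full <- stats::as.formula(paste(.bt(outcome), "~", .bt(score), rhs_cov, "+", re))
  f_null <- stats::as.formula(paste(.bt(outcome), "~ 1", rhs_cov, "+", re))
  f_int <- stats::as.formula(paste(.bt(outcome), "~ 1 +", re))
  # bobyqa throughout; the post-hoc Richardson derivative check is skipped
  # (it only feeds the gradient warning, not the vcov) and singular fits
  # (tau2 -> 0) are legitimate here
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  forms <- if (pseudo_r2) list(f_full, f_null, f_int) else list(f_full)
  fits <- lapply(forms, function(f) {
    withCallingHandlers(
      lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = nAGQ,
                  control = ctrl),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  fit_full <- fits[[1]]
  co <- stats::coef(summary(fit_full))
  rn <- rownames(co)[grepl(score, rownames(co), fixed = TRUE)][1]
  est <- co[rn, 1]; se <- co[rn, 2]; p <- co[rn, 4]
  conv <- fit_full@optinfo$conv$opt == 0 &&
    (length(fit_full@optinfo$conv$lme4$messages) == 0 ||
       all(grepl("singular", unlist(fit_full@optinfo$conv$lme4$messages))))
  ll <- if (!pseudo_r2) {
    rep(NA_real_, 3)
  } else if (r2_likelihood == "marginal") {
    vapply(fits, function(m) as.numeric(stats::logLik(m)), numeric(1))
  } else {
    vapply(fits, function(m) {
      sum(stats::dbinom(d[[outcome]], 1, stats::fitted(m), log = TRUE))
    }, numeric(1))
  }
  if (!pseudo_r2) ll[1] <- as.numeric(stats::logLik(fit_full))
  tau2 <- as.numeric(lme4::VarCorr(fit_full)[[1]][1, 1])
  .assoc_result(score, model, n, est, se, p,
                ll_intercept = ll[3], ll_null = ll[2], ll_full = ll[1],
                tau2 = tau2, converged = conv,
                flag = if (conv) NA_character_ else "nonconvergence",
                n_dropped = sum(!keep))
}

#' Best-performing PRS threshold
#'
#' Returns the threshold whose association result explains the most
#' variance (largest change in Nagelkerke pseudo-R-squared); ties go to the
#' smaller threshold.
#'
#' @param results list of `association_result`s for scores named
#'   `prs:<threshold>`.
#' @return the selected threshold (numeric), with the full ranking in the
#'   `ranking` attribute.
#' @export
best_threshold <- function(results) {
  if (length(results) == 0) stop("need at least one result")
  thr <- vapply(results, function(r) as.numeric(sub("^prs:", "", r$score)), numeric(1))
  d <- vapply(results, function(r) r$delta_r2, numeric(1))
  ord <- order(-d, thr)
  best <- thr[ord[1]]
  attr(best, "ranking") <- data.frame(threshold = thr[ord], delta_r2 = d[ord])
  best
}

#' Random-effects meta-analysis of study log-odds ratios
#'
#' Pools per-study estimates by inverse-variance weighting with
#' between-study variance estimated by restricted maximum likelihood, via
#' [metafor::rma()]. Weights are `1 / (SE_i^2 + tau^2)`; the Wald CI is
#' formed on the log scale and exponentiated to an odds ratio.
#'
#' @param estimates per-study log-odds ratios (length >= 2), or a list of
#'   `association_result`s.
#' @param ses per-study standard errors (ignored when `estimates` is a list
#'   of results).
#' @param labels optional study labels.
#' @param method `"REML"` (default) or `"FE"` (fixed-effect, for the
#'   tau^2 = 0 check).
#' @return a `meta_result`: pooled log-OR, SE, aOR, 95% CI, p, tau2,
#'   heterogeneity Q and its p, k, and the per-study inputs.
#' @export
meta_analyze <- function(estimates, ses = NULL, labels = NULL, method = "REML") {
  if (is.list(estimates) && !is.numeric(estimates)) {
    ses <- vapply(estimates, function(r) r$se, numeric(1))
    estimates <- vapply(estimates, function(r) r$estimate, numeric(1))
  }
  if (length(estimates) < 2) stop("need at least 2 studies")
  if (any(ses <= 0)) stop("standard errors must be positive")
  fit <- metafor::rma(yi = estimates, sei = ses, method = method,
                      control = list(threshold = 1e-8))
  structure(list(
    estimate = as.numeric(fit$beta), se = fit$se,
    aOR = exp(as.numeric(fit$beta)),
    ci_lower = exp(fit$ci.lb), ci_upper = exp(fit$ci.ub),
    p = fit$pval, tau2 = max(fit$tau2, 0),
    Q = fit$QE, Q_p = fit$QEp, k = fit$k,
    studies = data.frame(
      label = if (is.null(labels)) paste0("study", seq_along(estimates)) else labels,
      estimate = estimates, se = ses
    )
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "meta-analysis (k = %d): pooled aOR = %.3f (95%% CI %.3f-%.3f), p = %.3g, tau2 = %.4g\n",
    x$k, x$aOR, x$ci_lower, x$ci_upper, x$p, x$tau2
  ))
  invisible(x)
}

#' Run the standard model ladder
#'
#' Fits the five standard models against early- vs late-onset status:
#' Model 0 = PRS alone; Model 1 = module GeRS; Model 2 = hub GeRS;
#' Model 3 = module GeRS adjusted for PRS; Model 4 = hub GeRS adjusted for
#' PRS; all additionally adjusted for the covariates. Multiplex mode uses
#' the family random-intercept fit, simplex mode plain logistic. In the
#' joint models the reported effect and pseudo-R-squared change are those
#' of the GeRS term (its null model contains PRS and covariates).
#'
#' @param data merged phenotype + wide score data frame.
#' @param gers_sub,gers_hub,prs_score column names of the module GeRS, hub
#'   GeRS and (best-threshold) PRS z-scores.
#' @param covariates adjustment columns (default sex, education, PC1..PC4).
#' @param mode `"mixed"` (multiplex) or `"plain"` (simplex).
#' @param family_col family-index column (mixed mode).
#' @param nAGQ quadrature order (mixed mode).
#' @return named list of `association_result`s (`model0` .. `model4`).
#' @export
run_models <- function(data, gers_sub, gers_hub, prs_score,
                       covariates = c("sex", "education", paste0("PC", 1:4)),
                       mode = c("mixed", "plain"), family_col = "family",
                       nAGQ = 1L) {
  mode <- match.arg(mode)
  fit1 <- function(score, covs, label) {
    if (mode == "mixed") {
      fit_mixed_logistic(data, score, covs, family_col = family_col,
                         nAGQ = nAGQ, model = label)
    } else {
      fit_logistic(data, score, covs, model = label)
    }
  }
  list(
    model0 = fit1(prs_score, covariates, "Model 0: PRS"),
    model1 = fit1(gers_sub, covariates, "Model 1: module GeRS"),
    model2 = fit1(gers_hub, covariates, "Model 2: hub GeRS"),
    model3 = fit1(gers_sub, c(prs_score, covariates), "Model 3: module GeRS + PRS"),
    model4 = fit1(gers_hub, c(prs_score, covariates), "Model 4: hub GeRS + PRS")
  )
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(score = x$score, model = x$model, n = x$n,
             estimate = x$estimate, se = x$se, aOR = x$aOR,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper, p = x$p,
             delta_r2 = x$delta_r2, tau2 = x$tau2,
             flag = ifelse(is.na(x$flag), "", x$flag),
             stringsAsFactors = FALSE)
}

#' Collect association results into a forest-plot-ready table
#'
#' @param results list of `association_result`s (e.g. from [run_models()]).
#' @return data frame with one row per result.
#' @export
association_table <- function(results) {
  do.call(rbind, lapply(results, as.data.frame))
}
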