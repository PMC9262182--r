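#' Age- and sex-adjusted linear regression of an LDI on PFT predictors
#'
#' Ordinary least squares with age and sex always included as covariates.
#' Three modes:
#' \describe{
#'   \item{`univariate`}{one PFT predictor at a time (plus covariates), each
#'     fit on the complete cases of that predictor;}
#'   \item{`backward`}{all predictors entered, then stepwise backward
#'     elimination of the largest-p predictor until every retained predictor
#'     has p below `stay_threshold` (covariates are never removed);}
#'   \item{`all_subset`}{every subset of the predictors fitted (covariates
#'     always present) and the subset with the smallest AIC reported.}
#' }
#' Coefficients are unstandardized, with 95\% Wald confidence intervals.
#'
#' @param table cohort data.frame with `age_years` and `sex` columns.
#' @param outcome name of the LDI outcome column.
#' @param predictors character vector of predictor columns (e.g. PFTs).
#' @param selection `"univariate"`, `"backward"` or `"all_subset"`.
#' @param stay_threshold p-value needed to stay in the backward model.
#' @return A data.frame (one row per reported predictor coefficient) with
#'   columns `outcome`, `predictor`, `estimate`, `lwr`, `upr`, `p_value`,
#'   `n`, `mode`, `covariates`.
#' @export
adjusted_linear_fit <- function(table, outcome, predictors,
                                selection = c("univariate", "backward",
                                              "all_subset"),
                                stay_threshold = 0.05) {
  selection <- match.arg(selection)
  stopifnot(outcome %in% names(table), all(predictors %in% names(table)),
            all(c("age_years", "sex") %in% names(table)))

  fit_one <- function(preds, data) {
    fml <- stats::reformulate(c(preds, "age_years", "sex"), response = outcome)
    data <- data[stats::complete.cases(data[, c(outcome, preds,
                                                "age_years", "sex")]), ]
    if (nrow(data) < length(preds) + 3)
      stop(sprintf("too few complete cases (%d) for %d predictor(s)",
                   nrow(data), length(preds)))
    fit <- stats::lm(fml, data = data)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop(sprintf("rank-deficient design; aliased column(s): %s",
                   paste(bad, collapse = ", ")))
    }
    list(fit = fit, n = nrow(data))
  }

  rows <- function(fitinfo, preds, mode) {
    cf <- summary(fitinfo$fit)$coefficients
    ci <- stats::confint(fitinfo$fit, level = 0.95)
    out <- lapply(preds, function(p) {
      data.frame(outcome = outcome, predictor = p,
                 estimate = cf[p, "Estimate"],
                 lwr = ci[p, 1], upr = ci[p, 2],
                 p_value = cf[p, "Pr(>|t|)"], n = fitinfo$n,
                 mode = mode, covariates = "age_years+sex",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  if (selection == "univariate") {
    out <- lapply(predictors, function(p) rows(fit_one(p, table), p, "univariate"))
    return(do.call(rbind, out))
  }

  # multivariate modes use the common complete cases of all predictors
  data <- table[stats::complete.cases(table[, c(outcome, predictors,
                                                "age_years", "sex")]), ]
  if (selection == "backward") {
    preds <- predictors
    repeat {
      fi <- fit_one(preds, data)
      cf <- summary(fi$fit)$coefficients
      pv <- cf[preds, "Pr(>|t|)", drop = TRUE]
      if (length(preds) == 0 || max(pv) < stay_threshold) break
      preds <- preds[-which.max(pv)]
      if (length(preds) == 0) break
    }
    if (length(preds) == 0)
      return(data.frame(outcome = character(0), predictor = character(0),
                        estimate = numeric(0), lwr = numeric(0),
                        upr = numeric(0), p_value = numeric(0),
                        n = integer(0), mode = character(0),
                        covariates = character(0)))
    return(rows(fit_one(preds, data), preds, "backward"))
  }

  # all_subset by AIC
  if (length(predictors) > 15)
    stop("all-subset selection supports at most 15 predictors")
  subsets <- unlist(lapply(0:length(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  aics <- vapply(subsets, function(s)
    stats::AIC(fit_one(if (length(s)) s else character(0), data)$fit),
    numeric(1))
  best <- subsets[[which.min(aics)]]
  if (length(best) == 0)
    return(data.frame(outcome = character(0), predictor = character(0),
                      estimate = numeric(0), lwr = numeric(0),
                      upr = numeric(0), p_value = numeric(0), n = integer(0),
                      mode = character(0), covariates = character(0)))
  rows(fit_one(best, data), best, "all_subset")
}

#' Age- and sex-adjusted logistic regression odds ratio for BO diagnosis
#'
#' Fits a maximum-likelihood logistic regression of BO status on one
#' predictor plus covariates (age and sex by default, the published model)
#' and reports the odds ratio per unit of the predictor with a 95\% Wald
#' interval. Non-convergence and (quasi-)complete separation are diagnosed
#' and raised as errors rather than silently returning unstable estimates.
#'
#' @param table cohort data.frame with a `group` column (`control`/`BO`).
#' @param predictor column whose odds ratio is reported.
#' @param covariates always-included adjustment columns.
#' @return A one-row data.frame: `predictor`, `or`, `lcl`, `ucl`, `p_value`,
#'   `n`, `covariates`.
#' @export
adjusted_logistic_or <- function(table, predictor,
                                 covariates = c("age_years", "sex")) {
  stopifnot(predictor %in% names(table), all(covariates %in% names(table)),
            "group" %in% names(table))
  cols <- c("group", predictor, covariates)
  data <- table[stats::complete.cases(table[, cols]), cols]
  if (nrow(data) < 10) stop("fewer than 10 complete cases")
  data$.y <- as.integer(data$group == "BO")
  if (length(unique(data$.y)) < 2) stop("both outcome classes must be present")
  fml <- stats::reformulate(c(predictor, covariates), response = ".y")
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  # diverging slope (|log-OR| > 10 per unit) under a 0/1-fitted-probability
  # warning or failed IRLS is the signature of (quasi-)complete separation
  if ((sep_warned || !fit$converged) && abs(cf[predictor, "Estimate"]) > 10)
    stop(sprintf("separation: '%s' (quasi-)perfectly separates BO from control",
                 predictor))
  if (!fit$converged)
    stop(sprintf("logistic model for '%s' did not converge", predictor))
  est <- cf[predictor, "Estimate"]; se <- cf[predictor, "Std. Error"]
  data.frame(predictor = predictor, or = exp(est),
             lcl = exp(est - stats::qnorm(0.975) * se),
             ucl = exp(est + stats::qnorm(0.975) * se),
             p_value = cf[predictor, "Pr(>|z|)"], n = nrow(data),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}
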