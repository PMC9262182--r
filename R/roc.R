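#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity, specificity, positive and negative predictive value in
#' percent, from integer confusion counts. A metric whose margin is zero is
#' undefined: it is returned as `NA` and listed in the `undefined` element
#' rather than reported as a number.
#'
#' @param tp,fp,fn,tn confusion counts (non-negative).
#' @return A list of class `diagnostic_metrics` with elements `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent), the four counts, and
#'   `undefined` (character vector of metrics with zero margins).
#' @examples
#' diagnostic_metrics(25, 4, 4, 15)  # sens 86.2, spec 78.9
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              ppv = safe(tp, tp + fp),
              npv = safe(tn, tn + fn),
              tp = tp, fp = fp, fn = fn, tn = tn)
  out$undefined <- names(which(vapply(out[1:4], is.na, logical(1))))
  structure(out, class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("sens %s  spec %s  PPV %s  NPV %s  (TP %d FP %d FN %d TN %d)\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# Pair-counting AUC (Mann-Whitney estimator, ties count 0.5) for
# "higher score indicates disease".
auc_pair_count <- function(cases, controls) {
  r <- rank(c(cases, controls), ties.method = "average")
  n1 <- length(cases); n0 <- length(controls)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the pair-counting AUC via placement values.
auc_delong_var <- function(cases, controls) {
  psi_case <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), numeric(1))
  psi_ctrl <- vapply(controls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  stats::var(psi_case) / length(cases) + stats::var(psi_ctrl) / length(controls)
}

#' ROC analysis of a cohort variable for BO diagnosis
#'
#' Computes the area under the ROC curve with the rank (pair-counting)
#' estimator, ties counted 0.5. Orientation is chosen automatically so that
#' the oriented AUC is at least 0.5 and is recorded
#' (`higher_indicates_BO` or `lower_indicates_BO`; at exactly 0.5 the
#' higher-indicates orientation is kept). The optimal cutoff is the observed
#' value maximising sensitivity + specificity (Youden), with the decision
#' rule "predict BO when the oriented score passes the cutoff inclusively";
#' ties on the Youden index are broken toward the cutoff with higher
#' specificity, then toward the more extreme cutoff — both deterministic.
#' The 95\% AUC confidence interval uses the DeLong method by default, or a
#' seeded stratified bootstrap.
#'
#' @param table cohort data.frame with a `group` column (`control`/`BO`).
#' @param variable score column to evaluate.
#' @param ci `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap resamples (when `ci = "bootstrap"`).
#' @param seed bootstrap seed.
#' @return A list of class `roc_result`: `variable`, `orientation`, `auc`,
#'   `auc_lcl`, `auc_ucl`, `p_value` (AUC vs 0.5), `cutoff` (original
#'   scale), `rule` (human-readable decision rule), `metrics` (a
#'   [diagnostic_metrics()] object) and `n_used`.
#' @export
roc_analysis <- function(table, variable, ci = c("delong", "bootstrap"),
                         boot_n = 2000, seed = 1) {
  ci <- match.arg(ci)
  stopifnot(variable %in% names(table), "group" %in% names(table))
  keep <- !is.na(table[[variable]]) & !is.na(table$group)
  x <- table[[variable]][keep]
  y <- table$group[keep] == "BO"
  if (!any(y) || !any(!y)) stop("both classes must be present")
  if (length(unique(x)) < 2) stop("need at least 2 distinct score values")

  auc_raw <- auc_pair_count(x[y], x[!y])
  orientation <- if (auc_raw >= 0.5) "higher_indicates_BO" else "lower_indicates_BO"
  s <- if (orientation == "higher_indicates_BO") x else -x
  auc <- auc_pair_count(s[y], s[!y])

  # Youden scan over all observed thresholds, rule: BO if oriented score >= c
  cand <- sort(unique(s))
  best <- NULL
  for (cutoff in cand) {
    pred <- s >= cutoff
    m <- diagnostic_metrics(sum(pred & y), sum(pred & !y),
                            sum(!pred & y), sum(!pred & !y))
    j <- m$sensitivity + m$specificity
    if (is.na(j)) next
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && m$specificity > best$m$specificity + 1e-12) ||
        (abs(j - best$j) <= 1e-12 &&
         abs(m$specificity - best$m$specificity) <= 1e-12 && cutoff > best$s_cut))
      best <- list(j = j, m = m, s_cut = cutoff)
  }

  if (ci == "delong") {
    se <- sqrt(auc_delong_var(s[y], s[!y]))
    lcl <- max(0, auc - stats::qnorm(0.975) * se)
    ucl <- min(1, auc + stats::qnorm(0.975) * se)
    p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else NA_real_
  } else {
    aucs <- with_seed(substream_seed(seed, "roc_boot"), {
      vapply(seq_len(boot_n), function(i) {
        bc <- sample(which(y), sum(y), replace = TRUE)
        bn <- sample(which(!y), sum(!y), replace = TRUE)
        auc_pair_count(s[bc], s[bn])
      }, numeric(1))
    })
    qs <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
    lcl <- qs[1]; ucl <- qs[2]
    p <- 2 * min(mean(aucs <= 0.5), mean(aucs >= 0.5))
  }

  cutoff <- if (orientation == "higher_indicates_BO") best$s_cut else -best$s_cut
  rule <- if (orientation == "higher_indicates_BO")
    sprintf("predict BO when %s >= %g", variable, cutoff)
  else sprintf("predict BO when %s <= %g", variable, cutoff)

  structure(list(variable = variable, orientation = orientation,
                 auc = auc, auc_lcl = lcl, auc_ucl = ucl, p_value = p,
                 ci_method = ci, cutoff = cutoff, rule = rule,
                 metrics = best$m, n_used = length(x)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC for %s (%s): AUC %.3f [%.3f, %.3f], n = %d\n",
              x$variable, x$orientation, x$auc, x$auc_lcl, x$auc_ucl, x$n_used))
  cat(sprintf("  cutoff %g (%s)\n  ", x$cutoff, x$rule))
  print(x$metrics)
  invisible(x)
}
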