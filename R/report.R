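#' Build the full diagnostic report for a cohort
#'
#' Produces the four tables of the diagnostic evaluation:
#' \describe{
#'   \item{group_comparison}{per-variable group descriptives (mean, SD,
#'     median, IQR, per-group n) with Mann-Whitney / chi-square p-values;}
#'   \item{linear_regression}{age/sex-adjusted univariate and backward-
#'     selected multivariate linear regressions of each LDI on the PFT
#'     predictors;}
#'   \item{logistic_or}{age/sex-adjusted per-predictor logistic odds ratios
#'     for BO diagnosis;}
#'   \item{roc}{AUC with 95\% CI, Youden cutoff and confusion metrics per
#'     variable.}
#' }
#' Variables that cannot be analysed (all missing, degenerate, separated)
#' are reported as explicit gaps with the failure message, never silently
#' dropped, and every row carries the complete-case n it used.
#'
#' @param table a `cohort_table` data.frame.
#' @param ldi_vars,pft_vars variable panels; defaults [ldi_variables()] and
#'   [pft_variables()].
#' @param regression_pfts PFT predictors used in the LDI regressions
#'   (default FEV1, FEV1/FVC, FEF25-75, RV, sRaw — the airflow-limitation
#'   panel).
#' @param roc_ci CI method passed to [roc_analysis()].
#' @param seed seed for any resampling-based CI.
#' @return A list of class `ldi_report` with the four data.frames plus
#'   `gaps` (a data.frame of skipped analyses and reasons).
#' @export
build_report <- function(table, ldi_vars = ldi_variables(),
                         pft_vars = pft_variables(),
                         regression_pfts = c("FEV1_pct", "FEV1_FVC_pct",
                                             "FEF2575_pct", "RV_pct",
                                             "sRaw_pct"),
                         roc_ci = c("delong", "bootstrap"), seed = 1) {
  roc_ci <- match.arg(roc_ci)
  gaps <- data.frame(analysis = character(0), variable = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  note_gap <- function(analysis, variable, e) {
    gaps <<- rbind(gaps, data.frame(analysis = analysis, variable = variable,
                                    reason = conditionMessage(e),
                                    stringsAsFactors = FALSE))
    NULL
  }

  present <- function(vars) vars[vars %in% names(table)]
  absent <- setdiff(unique(c(pft_vars, ldi_vars, regression_pfts)),
                    names(table))
  if (length(absent))
    gaps <- rbind(gaps, data.frame(analysis = "all",
                                   variable = absent,
                                   reason = "variable not present in cohort table",
                                   stringsAsFactors = FALSE))
  cont_vars <- c(present(pft_vars), present(ldi_vars))

  t1 <- do.call(rbind, c(
    list({
      cg <- tryCatch(compare_groups(table, "sex"),
                     error = function(e) note_gap("group_comparison", "sex", e))
      if (is.null(cg)) NULL else
        data.frame(variable = "sex_male",
                   control = sprintf("%d (%.1f%%)", cg$groups["control", "male"],
                                     100 * cg$groups["control", "male"] /
                                       sum(cg$groups["control", ])),
                   bo = sprintf("%d (%.1f%%)", cg$groups["BO", "male"],
                                100 * cg$groups["BO", "male"] /
                                  sum(cg$groups["BO", ])),
                   n_control = sum(cg$groups["control", ]),
                   n_bo = sum(cg$groups["BO", ]),
                   p_value = cg$p_value, stringsAsFactors = FALSE)
    }),
    lapply(c("age_years", cont_vars), function(v) {
      cg <- tryCatch(compare_groups(table, v),
                     error = function(e) note_gap("group_comparison", v, e))
      if (is.null(cg)) return(NULL)
      g <- cg$groups
      fmt <- function(r) sprintf("%.1f ± %.1f", g$mean[r], g$sd[r])
      data.frame(variable = v, control = fmt(1), bo = fmt(2),
                 n_control = g$n[1], n_bo = g$n[2], p_value = cg$p_value,
                 stringsAsFactors = FALSE)
    })))

  reg_ldis <- present(c("EXP_MLD_HU", "MLDD_HU", "EI_MLD_pct", "EI_Volume_pct",
                        "E950_pct", "E900_pct", "E850_pct", "E650_pct",
                        "E600_pct"))
  reg_pfts <- present(regression_pfts)
  t2 <- do.call(rbind, lapply(reg_ldis, function(ldi) {
    uni <- tryCatch(adjusted_linear_fit(table, ldi, reg_pfts, "univariate"),
                    error = function(e) note_gap("linear_regression", ldi, e))
    multi <- tryCatch(adjusted_linear_fit(table, ldi, reg_pfts, "backward"),
                      error = function(e) note_gap("linear_regression", ldi, e))
    rbind(uni, multi)
  }))

  t3 <- do.call(rbind, lapply(c(reg_pfts, present(c(
    "INS_MLD_HU", "EXP_MLD_HU", "MLDD_HU", "EI_MLD_pct", "EI_Volume_pct",
    "E950_pct", "E900_pct", "E850_pct", "E650_pct", "E600_pct"))),
    function(v) {
      tryCatch(adjusted_logistic_or(table, v),
               error = function(e) note_gap("logistic_or", v, e))
    }))

  t4 <- do.call(rbind, lapply(c(reg_pfts, present(ldi_vars)), function(v) {
    r <- tryCatch(roc_analysis(table, v, ci = roc_ci, seed = seed),
                  error = function(e) note_gap("roc", v, e))
    if (is.null(r)) return(NULL)
    data.frame(variable = v, orientation = r$orientation, cutoff = r$cutoff,
               sensitivity = r$metrics$sensitivity,
               specificity = r$metrics$specificity,
               ppv = r$metrics$ppv, npv = r$metrics$npv,
               auc = r$auc, auc_lcl = r$auc_lcl, auc_ucl = r$auc_ucl,
               p_value = r$p_value, n_used = r$n_used,
               stringsAsFactors = FALSE)
  }))

  structure(list(group_comparison = t1, linear_regression = t2,
                 logistic_or = t3, roc = t4, gaps = gaps),
            class = "ldi_report")
}

#' @export
print.ldi_report <- function(x, ...) {
  cat("<ldi_report>\n")
  for (nm in c("group_comparison", "linear_regression", "logistic_or", "roc"))
    cat(sprintf("  %s: %d rows\n", nm,
                if (is.null(x[[nm]])) 0L else nrow(x[[nm]])))
  if (nrow(x$gaps)) {
    cat("  gaps:\n")
    for (i in seq_len(nrow(x$gaps)))
      cat(sprintf("    %s / %s: %s\n", x$gaps$analysis[i], x$gaps$variable[i],
                  x$gaps$reason[i]))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per table, a JSON with the whole bundle, and a plain-text
#' summary; a provenance block (software version, seed, config echo) is
#' embedded in the JSON.
#'
#' @param report an `ldi_report`.
#' @param dir output directory (created if needed).
#' @param provenance optional named list added to the JSON provenance block.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, provenance = list()) {
  stopifnot(inherits(report, "ldi_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("group_comparison", "linear_regression", "logistic_or", "roc",
               "gaps")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  prov <- c(list(package = "lungdens",
                 version = as.character(utils::packageVersion("lungdens")),
                 written = format(Sys.time(), tz = "UTC")), provenance)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(c(list(provenance = prov), unclass(report)), jp,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  paths <- c(paths, jp)
  tp <- file.path(dir, "summary.txt")
  writeLines(utils::capture.output(print(report)), tp)
  invisible(c(paths, tp))
}
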