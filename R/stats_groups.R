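#' Compare a variable between the BO and control groups
#'
#' Continuous variables are compared with the two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test; categorical variables with the chi-square test
#' (with Yates continuity correction on 2x2 tables — the convention that
#' reproduces the published gender comparison). Summaries report mean and SD
#' and, for continuous variables, median and IQR; analysis is complete-case
#' per variable and the per-group n used is always returned.
#'
#' @param table a `cohort_table` (data.frame with a `group` column with
#'   levels `control` and `BO`).
#' @param variable name of the column to compare.
#' @return A list of class `group_comparison`: `variable`, `type`,
#'   `statistic`, `p_value`, and a `groups` data.frame with per-group `n`,
#'   `mean`, `sd`, `median`, `q1`, `q3` (continuous) or level counts
#'   (categorical).
#' @export
compare_groups <- function(table, variable) {
  stopifnot(is.data.frame(table), "group" %in% names(table),
            variable %in% names(table))
  x <- table[[variable]]
  g <- factor(table$group, levels = c("control", "BO"))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  n_by <- table(g)
  if (any(n_by < 2))
    stop(sprintf("variable '%s' has fewer than 2 non-missing values in a group",
                 variable))
  if (is.numeric(x)) {
    # exact p where feasible; with ties R falls back to the normal
    # approximation with continuity correction (warning suppressed)
    ht <- suppressWarnings(
      stats::wilcox.test(x[g == "control"], x[g == "BO"],
                         alternative = "two.sided"))
    summ <- do.call(rbind, lapply(levels(g), function(lev) {
      xi <- x[g == lev]
      data.frame(group = lev, n = length(xi), mean = mean(xi), sd = stats::sd(xi),
                 median = stats::median(xi),
                 q1 = unname(stats::quantile(xi, 0.25)),
                 q3 = unname(stats::quantile(xi, 0.75)))
    }))
    out <- list(variable = variable, type = "continuous",
                test = "Mann-Whitney", statistic = unname(ht$statistic),
                p_value = ht$p.value, groups = summ)
  } else {
    tab <- table(g, factor(x))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    out <- list(variable = variable, type = "categorical",
                test = "chi-square", statistic = unname(ht$statistic),
                p_value = ht$p.value, groups = as.data.frame.matrix(tab))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s, %s test): p = %.4g\n", x$variable, x$type, x$test,
              x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation between two cohort variables
#'
#' Complete-case Spearman's rho with mid-ranks for ties; requires at least
#' three complete pairs.
#'
#' @param table a cohort data.frame.
#' @param var_x,var_y column names.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(table, var_x, var_y) {
  stopifnot(var_x %in% names(table), var_y %in% names(table))
  x <- table[[var_x]]; y <- table[[var_y]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
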