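#' Default per-variable group means and SDs for the cohort simulator
#'
#' One row per continuous variable of the study cohort: pulmonary function
#' test (PFT) parameters as percent predicted (except VA, in litres) and the
#' lung-density index (LDI) panel. The default means/SDs are the published
#' group summaries of the paediatric bronchiolitis obliterans cohort this
#' package's analysis reproduces (30 controls, 51 BO patients). Bounds give
#' the truncation range applied after sampling: percent-predicted PFTs and
#' volumes are non-negative; E/I ratios and threshold fractions live in
#' \[0, 100\]; MLD values are bounded below by the HU floor.
#'
#' @return A data.frame with columns `variable`, `set` (`"spirometry"`,
#'   `"plethysmography"`, `"diffusion"` or `"ldi"`), `control_mean`,
#'   `control_sd`, `bo_mean`, `bo_sd`, `lower`, `upper`.
#' @export
cohort_variable_defaults <- function() {
  utils::read.csv(text = "
variable,set,control_mean,control_sd,bo_mean,bo_sd,lower,upper
FVC_pct,spirometry,95.3,12.2,73.7,23.3,0,NA
FEV1_pct,spirometry,88.4,12.3,53.2,21.8,0,NA
FEV1_FVC_pct,spirometry,86.2,6.0,66.7,18.8,0,100
FEF2575_pct,spirometry,86.1,19.3,36.6,32.1,0,NA
TLC_pct,plethysmography,95.0,10.8,99.5,24.4,0,NA
RV_pct,plethysmography,91.0,32.6,172.8,84.0,0,NA
DLCO_pct,diffusion,77.6,15.4,67.0,21.2,0,NA
VA_L,diffusion,3.6,1.1,2.5,1.0,0,NA
sRaw_pct,plethysmography,134.5,48.9,277.4,253.0,0,NA
INS_V_mL,ldi,2868.4,1367.1,2393.3,1308.7,0,NA
EXP_V_mL,ldi,1558.2,761.4,1674.9,823.4,0,NA
INS_MLD_HU,ldi,-788.0,74.5,-794.6,71.0,-1024,NA
EXP_MLD_HU,ldi,-659.0,61.6,-731.4,69.6,-1024,NA
MLDD_HU,ldi,129.0,54.3,63.8,47.2,NA,NA
EI_Volume_pct,ldi,57.6,15.0,73.3,18.3,0,100
EI_MLD_pct,ldi,83.9,6.2,92.2,5.9,0,100
E950_pct,ldi,0.0,0.0,0.8,1.7,0,100
E900_pct,ldi,0.4,1.0,7.7,11.3,0,100
E850_pct,ldi,3.9,9.7,22.6,21.6,0,100
E650_pct,ldi,20.7,10.2,10.9,7.5,0,100
E600_pct,ldi,26.2,13.8,13.8,9.2,0,100
", stringsAsFactors = FALSE, strip.white = TRUE)
}

default_correlation_pairs <- function() {
  data.frame(var1 = c("MLDD_HU", "EI_MLD_pct", "E900_pct", "E850_pct", "E900_pct"),
             var2 = c("FEV1_pct", "FEV1_pct", "sRaw_pct", "sRaw_pct", "E850_pct"),
             rho  = c(0.5, -0.5, 0.6, 0.6, 0.5),
             stringsAsFactors = FALSE)
}

#' Parameters of the subject-level cohort simulator
#'
#' @param n_control,n_bo group sizes; defaults 30 and 51, the study's.
#' @param variables variable table as from [cohort_variable_defaults()]
#'   (means, SDs, truncation bounds per group).
#' @param correlation_pairs data.frame (`var1`, `var2`, `rho`) of latent
#'   Gaussian-copula correlations; all unlisted pairs are independent. The
#'   induced Spearman correlation is `(6/pi) * asin(rho / 2)`.
#' @param age_median,age_iqr named lists (`control`, `bo`) giving the group
#'   age medians and IQR endpoints in years; defaults 12.5 (9-15) and
#'   9 (6-15). Ages are drawn from a normal matching median and IQR,
#'   rejection-truncated to \[3, 18\] (the study's age window).
#' @param p_male per-group probability of male sex (defaults 18/30, 32/51).
#' @param missingness named per-set probabilities that a subject lacks the
#'   measurement set entirely: defaults `spirometry` 20% (controls) / 25.5%
#'   (BO), `plethysmography` and `diffusion` 20% / 37.3%, matching the
#'   study's completion rates. LDIs are never missing (every subject was
#'   scanned).
#' @param seed default seed used when [generate_cohort_table()] is not given
#'   one.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_control = 30, n_bo = 51,
                              variables = cohort_variable_defaults(),
                              correlation_pairs = default_correlation_pairs(),
                              age_median = list(control = 12.5, bo = 9),
                              age_iqr = list(control = c(9, 15), bo = c(6, 15)),
                              p_male = list(control = 18 / 30, bo = 32 / 51),
                              missingness = list(
                                control = c(spirometry = 0.20,
                                            plethysmography = 0.20,
                                            diffusion = 0.20),
                                bo = c(spirometry = 0.255,
                                       plethysmography = 0.373,
                                       diffusion = 0.373)),
                              seed = 1) {
  stopifnot(n_control >= 1, n_bo >= 1,
            all(c("variable", "control_mean", "control_sd", "bo_mean",
                  "bo_sd", "lower", "upper") %in% names(variables)),
            all(variables$control_sd >= 0), all(variables$bo_sd >= 0))
  R <- build_correlation_matrix(variables$variable, correlation_pairs)
  structure(list(n_control = n_control, n_bo = n_bo, variables = variables,
                 correlation = R, age_median = age_median, age_iqr = age_iqr,
                 p_male = p_male, missingness = missingness,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

# Assembles and validates the latent correlation matrix.
build_correlation_matrix <- function(vars, pairs) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
      if (!v1 %in% vars || !v2 %in% vars)
        stop(sprintf("correlation pair references unknown variable: %s / %s", v1, v2))
      R[v1, v2] <- R[v2, v1] <- pairs$rho[i]
    }
  }
  if (!isSymmetric(R)) stop("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(paste0("correlation matrix is not positive semi-definite ",
                        "(min eigenvalue %.3g); consider projecting to the ",
                        "nearest PSD matrix by clipping negative eigenvalues ",
                        "to zero and renormalising the diagonal"), min(ev)))
  R
}

#' Simulate a subject-level cohort table
#'
#' Draws `n_control + n_bo` subject records from group-specific
#' distributions: continuous variables from a Gaussian copula (multivariate
#' normal on the latent scale, scaled by each group's mean/SD, then
#' truncated to the variable's valid range); age from a normal matched to
#' each group's median and IQR, rejection-truncated to \[3, 18\] years; sex
#' Bernoulli with each group's male fraction. Measurement-set missingness is
#' applied per subject (a subject who did not perform spirometry lacks all
#' spirometry variables). Reproducible under `seed`.
#'
#' @param params a [cohort_sim_params()].
#' @param seed overrides `params$seed`.
#' @return A `cohort_table`: a data.frame with columns `id`, `group`
#'   (factor, levels `control`, `BO`), `age_years`, `sex` (factor `male`,
#'   `female`) and one column per simulated variable.
#' @export
generate_cohort_table <- function(params = cohort_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  seed <- seed %||% params$seed
  vars <- params$variables
  L <- chol(params$correlation + diag(1e-10, nrow(params$correlation)))

  draw_group <- function(n, group) {
    mean_col <- if (group == "control") "control_mean" else "bo_mean"
    sd_col <- if (group == "control") "control_sd" else "bo_sd"
    z <- matrix(stats::rnorm(n * nrow(vars)), nrow = n) %*% L
    x <- sweep(sweep(z, 2, vars[[sd_col]], `*`), 2, vars[[mean_col]], `+`)
    colnames(x) <- vars$variable
    for (j in seq_len(nrow(vars)))
      x[, j] <- clamp(x[, j],
                      if (is.na(vars$lower[j])) NULL else vars$lower[j],
                      if (is.na(vars$upper[j])) NULL else vars$upper[j])
    x
  }

  draw_ages <- function(n, group) {
    med <- params$age_median[[group]]
    iqr <- params$age_iqr[[group]]
    sd <- (iqr[2] - iqr[1]) / (2 * stats::qnorm(0.75))
    out <- numeric(0)
    while (length(out) < n) {
      a <- stats::rnorm(2 * n, med, sd)
      out <- c(out, a[a >= 3 & a <= 18])
    }
    round(out[seq_len(n)], 1)
  }

  tab <- with_seed(substream_seed(seed, "cohort"), {
    n <- c(control = params$n_control, bo = params$n_bo)
    rows <- lapply(c("control", "bo"), function(g) {
      x <- draw_group(n[[g]], g)
      df <- data.frame(
        id = character(n[[g]]),
        group = factor(if (g == "control") "control" else "BO",
                       levels = c("control", "BO")),
        age_years = draw_ages(n[[g]], g),
        sex = factor(ifelse(stats::rbinom(n[[g]], 1, params$p_male[[g]]) == 1,
                            "male", "female"), levels = c("male", "female")),
        stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(x))
      # per-subject measurement-set missingness
      miss <- params$missingness[[g]]
      for (set_name in names(miss)) {
        drop <- stats::runif(n[[g]]) < miss[[set_name]]
        set_vars <- vars$variable[vars$set == set_name]
        df[drop, set_vars] <- NA_real_
      }
      df
    })
    out <- rbind(rows[[1]], rows[[2]])
    out$id <- sprintf("S%03d", seq_len(nrow(out)))
    out
  })
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Variables of the lung-density index panel
#'
#' Column names of the LDI block of a cohort table, in report order.
#' @return Character vector.
#' @export
ldi_variables <- function() {
  c("INS_V_mL", "EXP_V_mL", "INS_MLD_HU", "EXP_MLD_HU", "MLDD_HU",
    "EI_Volume_pct", "EI_MLD_pct", "E950_pct", "E900_pct", "E850_pct",
    "E650_pct", "E600_pct")
}

#' Variables of the pulmonary function test panel
#' @return Character vector.
#' @export
pft_variables <- function() {
  c("FVC_pct", "FEV1_pct", "FEV1_FVC_pct", "FEF2575_pct", "TLC_pct",
    "RV_pct", "DLCO_pct", "VA_L", "sRaw_pct")
}
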