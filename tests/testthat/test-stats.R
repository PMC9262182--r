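make_table <- function(...) {
  df <- data.frame(...)
  df$group <- factor(df$group, levels = c("control", "BO"))
  df
}

test_that("Mann-Whitney comparison matches the exact permutation p-value", {
  tab <- make_table(group = rep(c("control", "BO"), each = 3),
                    x = c(1, 2, 3, 4, 5, 6))
  cg <- compare_groups(tab, "x")
  # all 20 assignments of ranks, two of which are at least as extreme
  expect_equal(cg$p_value, 0.1)
  expect_equal(cg$groups$n, c(3, 3))

  same <- make_table(group = rep(c("control", "BO"), each = 3),
                     x = rep(c(1, 2, 3), 2))
  expect_gte(compare_groups(same, "x")$p_value, 0.99)

  allna <- make_table(group = rep(c("control", "BO"), each = 3),
                      x = NA_real_)
  expect_error(compare_groups(allna, "x"), "fewer than 2")
})

test_that("categorical comparison uses the continuity-corrected chi-square", {
  # 18/30 vs 32/51 male: frozen from stats::chisq.test with Yates correction
  tab <- make_table(group = c(rep("control", 30), rep("BO", 51)),
                    sex = c(rep("male", 18), rep("female", 12),
                            rep("male", 32), rep("female", 19)))
  cg <- compare_groups(tab, "sex")
  expect_equal(cg$type, "categorical")
  expect_equal(cg$p_value, 0.9930055, tolerance = 1e-6)
  expect_gt(cg$p_value, 0.05)
})

test_that("Spearman rho handles monotone, reversed and tied data", {
  tab <- data.frame(x = 1:6, y = c(2, 4, 9, 16, 30, 100))
  expect_equal(spearman_rho(tab, "x", "y")$rho, 1)
  tab$y2 <- -tab$y
  expect_equal(spearman_rho(tab, "x", "y2")$rho, -1)

  # 5 given pairs (with a tie) vs the mid-rank correlation formula
  tab5 <- data.frame(x = c(3, 1, 4, 1, 5), y = c(9, 2, 6, 5, 3))
  oracle <- stats::cor(rank(tab5$x), rank(tab5$y))
  expect_equal(spearman_rho(tab5, "x", "y")$rho, oracle)

  expect_error(spearman_rho(data.frame(x = 1:2, y = 2:1), "x", "y"),
               "fewer than 3")
})

test_that("adjusted linear fit recovers noiseless and planted coefficients", {
  set.seed(101)
  n <- 120
  df <- data.frame(age_years = runif(n, 4, 18),
                   sex = factor(sample(c("male", "female"), n, TRUE)),
                   pft = rnorm(n, 80, 15))
  df$y <- 2.5 * df$pft + 3 * df$age_years +
    5 * (df$sex == "male")  # exact linear function, zero noise
  fit <- suppressWarnings(  # lm warns about the deliberately perfect fit
    adjusted_linear_fit(df, "y", "pft", "univariate"))
  expect_equal(fit$estimate, 2.5, tolerance = 1e-10)
  expect_equal(fit$n, n)

  # planted coefficient with noise, n = 500: within 3 SE
  set.seed(202)
  n <- 500
  df2 <- data.frame(age_years = runif(n, 4, 18),
                    sex = factor(sample(c("male", "female"), n, TRUE)),
                    pft = rnorm(n, 80, 15))
  df2$y <- 0.5 * df2$pft + 1.5 * df2$age_years + rnorm(n, 0, 10)
  fit2 <- adjusted_linear_fit(df2, "y", "pft", "univariate")
  se <- (fit2$upr - fit2$lwr) / (2 * qt(0.975, n - 4))
  expect_lt(abs(fit2$estimate - 0.5), 3 * se)

  # rank deficiency is diagnosed with the offending column
  df2$pft_dup <- df2$pft
  expect_error(adjusted_linear_fit(df2, "y", c("pft", "pft_dup"), "backward"),
               "rank-deficient.*pft_dup")
})

test_that("backward elimination discards pure-noise predictors", {
  # the last survivor of max-p elimination is the min-p predictor, so the
  # retain-nothing rate is about (1 - stay)^k; with k = 2 that is ~90%
  set.seed(303)
  retained_nothing <- vapply(1:60, function(i) {
    n <- 100
    df <- data.frame(age_years = runif(n, 4, 18),
                     sex = factor(sample(c("male", "female"), n, TRUE)))
    for (j in 1:2) df[[paste0("p", j)]] <- rnorm(n)
    df$y <- rnorm(n)
    fit <- adjusted_linear_fit(df, "y", paste0("p", 1:2), "backward")
    nrow(fit) == 0
  }, logical(1))
  expect_gte(mean(retained_nothing), 0.85)
})

test_that("all-subset selection keeps a strong predictor, drops pure noise", {
  set.seed(404)
  n <- 200
  df <- data.frame(age_years = runif(n, 4, 18),
                   sex = factor(sample(c("male", "female"), n, TRUE)),
                   signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  df$y <- 3 * df$signal + rnorm(n)
  fit <- adjusted_linear_fit(df, "y", c("signal", "noise1", "noise2"),
                             "all_subset")
  expect_true("signal" %in% fit$predictor)
  expect_equal(fit$estimate[fit$predictor == "signal"], 3, tolerance = 0.2)
})

test_that("logistic OR recovers null and planted effects, flags separation", {
  set.seed(505)
  n <- 600
  df <- data.frame(age_years = runif(n, 4, 18),
                   sex = factor(sample(c("male", "female"), n, TRUE)),
                   x = rnorm(n, 100, 20))
  df$group <- factor(ifelse(runif(n) < 0.5, "BO", "control"),
                     levels = c("control", "BO"))
  null_fit <- adjusted_logistic_or(df, "x")
  expect_true(null_fit$lcl <= 1 && 1 <= null_fit$ucl)

  # planted log-OR 0.05 per unit
  set.seed(606)
  df$group <- factor(ifelse(runif(n) < plogis(0.05 * (df$x - 100)),
                            "BO", "control"), levels = c("control", "BO"))
  fit <- adjusted_logistic_or(df, "x")
  se <- (log(fit$ucl) - log(fit$lcl)) / (2 * qnorm(0.975))
  expect_lt(abs(log(fit$or) - 0.05), 3 * se)

  # perfectly separating predictor
  df$sep <- ifelse(df$group == "BO", 1, 0) + rnorm(n, 0, 1e-4)
  expect_error(adjusted_logistic_or(df, "sep"), "separation")
})

test_that("report builder covers all panels and flags gaps explicitly", {
  tab <- generate_cohort_table(cohort_sim_params(), seed = 77)
  rep <- build_report(tab)
  expect_s3_class(rep, "ldi_report")
  expect_true(all(ldi_variables() %in% rep$group_comparison$variable))
  expect_true(all(ldi_variables() %in% rep$roc$variable))
  expect_true(all(c("n_control", "n_bo") %in% names(rep$group_comparison)))

  # a cohort without PFT columns: tables 2-3 PFT rows become explicit gaps
  noft <- tab[, !(names(tab) %in% pft_variables())]
  rep2 <- build_report(noft)
  expect_true(all(pft_variables() %in% rep2$gaps$variable))
  expect_true(all(ldi_variables() %in% rep2$roc$variable))
})
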