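test_that("FI grouping follows the literature boundaries exactly", {
  g <- classify_fi_group(c(5, 10, 49.999, 50, 99))
  expect_equal(as.character(g$group3),
               c("low", "medium", "medium", "high", "high"))
  expect_equal(as.character(g$collapsed),
               c("low_moderate", "low_moderate", "low_moderate", "high", "high"))
  expect_error(classify_fi_group(c(20, 101)), "\\[0, 100\\]")
  expect_error(classify_fi_group(-0.5), "\\[0, 100\\]")
})

test_that("grouping is an exhaustive partition with consistent collapse", {
  set.seed(12)
  fi <- runif(500, 0, 100)
  g <- classify_fi_group(fi)
  expect_false(any(is.na(g$group3)))
  expect_identical(g$collapsed == "low_moderate",
                   g$group3 %in% c("low", "medium"))
})

test_that("the normality gate picks t for normal and U for skewed data", {
  set.seed(4)
  t_picks <- mw_picks <- 0
  for (i in 1:20) {
    g <- normality_gate(rnorm(80), rnorm(80, 1))
    t_picks <- t_picks + (g$choice == "t")
    g2 <- normality_gate(rexp(50), rnorm(50))
    mw_picks <- mw_picks + (g2$choice == "mann_whitney")
  }
  expect_gt(t_picks / 20, 0.9)
  expect_gt(mw_picks / 20, 0.9)
})

test_that("the gate is symmetric in group order and guards small samples", {
  set.seed(8)
  x <- 5 + rnorm(30); y <- 5 + rnorm(30)
  expect_identical(normality_gate(x, y)$choice, normality_gate(y, x)$choice)
  expect_error(normality_gate(c(1, 2), rnorm(10)), "at least 3")
  # constant sample counts as non-normal
  expect_identical(normality_gate(rep(1, 10), rnorm(10))$choice, "mann_whitney")
})

test_that("Mann-Whitney statistic equals exhaustive pair counting", {
  set.seed(19)
  for (i in 1:8) {
    nx <- sample(5:30, 1); ny <- sample(5:30, 1)
    x <- sample(1:50, nx, replace = TRUE)   # ties included
    y <- sample(1:50, ny, replace = TRUE)
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(unname(w$statistic), brute_force_u(x, y))
  }
})

test_that("group comparison reports the U statistic and sensible summaries", {
  tab <- toy_cohort(60, seed = 2)
  # force strong skew so the gate picks Mann-Whitney
  tab$FI_Psoas <- exp(tab$FI_Psoas / 3)
  gc <- compare_groups(tab, "FI_Psoas", "female")
  expect_identical(gc$test, "mann_whitney")
  lo <- tab$FI_Psoas[tab$sex == "female" & tab$FI_group == "low_moderate"]
  hi <- tab$FI_Psoas[tab$sex == "female" & tab$FI_group == "high"]
  expect_equal(gc$statistic, brute_force_u(lo, hi))
  expect_match(gc$summary_low, "\\[")   # median [IQR] formatting
  expect_true(gc$p_value >= 0 && gc$p_value <= 1)
})

test_that("identical groups give p = 1 under the rank test", {
  v <- c(1, 3, 6, 10, 15, 21, 28, 36)
  w <- suppressWarnings(wilcox.test(v, v, exact = FALSE, correct = FALSE))
  expect_equal(w$p.value, 1)
})

test_that("p-values fall as the group separation grows", {
  set.seed(23)
  base <- rnorm(60)
  ps <- vapply(c(0.2, 0.8, 1.6), function(shift)
    suppressWarnings(wilcox.test(base, base + shift, exact = FALSE)$p.value),
    numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Spearman rho matches monotone expectations and the rank formula", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  expect_equal(spearman_rho(1:5, c(3, 1, 2, 5, 4))$rho, 0.6)
  set.seed(31)
  for (i in 1:5) {
    a <- sample(1000, 25); b <- sample(1000, 25)   # tie-free
    r <- spearman_rho(a, b)
    expect_equal(r$rho, rank_formula_spearman(a, b))
    ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(r$rho, unname(ct$estimate))
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("constant inputs yield a flagged missing correlation", {
  r <- spearman_rho(rep(2, 10), rnorm(10))
  expect_true(r$degenerate)
  expect_true(is.na(r$rho))
})

test_that("the stratified matrix covers all measure pairs symmetrically", {
  tab <- toy_cohort(80, seed = 6)
  cm <- spearman_matrix(tab, "female")
  expect_identical(dim(cm$rho), c(4L, 4L))
  expect_true(all(abs(cm$rho) <= 1))
  expect_equal(cm$n, sum(tab$sex == "female"))
  # rho is symmetric under swapping the pair's arguments
  d <- tab[tab$sex == "female", ]
  expect_equal(cm$rho["FI", "FI"],
               spearman_rho(d$FI_PPM, d$FI_Psoas)$rho)
  expect_equal(spearman_rho(d$FI_PPM, d$FI_Psoas)$rho,
               spearman_rho(d$FI_Psoas, d$FI_PPM)$rho)
})

test_that("a noiseless linear outcome is recovered with unit R-squared", {
  tab <- toy_cohort(100, seed = 10)
  tab$FI_Psoas <- 1 + 2 * tab$FI_PPM - 3 * tab$age
  rep <- suppressWarnings(fit_regression(tab))   # perfect-fit summary notice
  b <- setNames(rep$coefficients$b, rep$coefficients$term)
  expect_equal(unname(b[c("(Intercept)", "FI_PPM", "age")]), c(1, 2, -3))
  expect_equal(unname(b[c("bmi", "sex_female", "race_other")]), c(0, 0, 0),
               tolerance = 1e-10)
  expect_equal(rep$r_squared, 1)
})

test_that("regression report satisfies its internal identities", {
  tab <- suppressWarnings(generate_cohort(calibrate_defaults(), seed = 21))
  rep <- fit_regression(tab)
  cf <- rep$coefficients
  tc <- qt(0.975, rep$n - 6)
  expect_equal(cf$ci_low, cf$b - tc * cf$se)
  expect_equal(cf$ci_high, cf$b + tc * cf$se)
  expect_true(all(cf$vif[-1] >= 1))
  expect_lte(rep$adj_r_squared, rep$r_squared)
  expect_gte(rep$durbin_watson, 0); expect_lte(rep$durbin_watson, 4)
  # residuals orthogonal to every predictor
  X <- model.matrix(rep$fit)
  expect_lt(max(abs(crossprod(X, residuals(rep$fit)))), 1e-7)
  # standardized Beta definition
  sdy <- sd(tab$FI_Psoas)
  expect_equal(cf$beta[cf$term == "FI_PPM"],
               cf$b[cf$term == "FI_PPM"] * sd(tab$FI_PPM) / sdy)
})

test_that("VIF and Durbin-Watson agree with the reference implementations", {
  tab <- suppressWarnings(generate_cohort(calibrate_defaults(), seed = 14))
  rep <- fit_regression(tab)
  cf <- rep$coefficients
  ref_vif <- car::vif(rep$fit)
  expect_equal(setNames(cf$vif[-1], cf$term[-1]), ref_vif[names(ref_vif)])
  expect_equal(rep$durbin_watson,
               unname(lmtest::dwtest(rep$fit)$statistic))
  # independent predictors drive VIF toward 1
  set.seed(40)
  X <- matrix(rnorm(5000 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(abs(variance_inflation(X) - 1) < 0.01))
})

test_that("alternating residuals drive the Durbin-Watson statistic toward 4", {
  expect_equal(durbin_watson(rep(c(1, -1), 5)), 3.6)   # n = 10: 36/10
  expect_equal(durbin_watson(rep(c(1, -1), 500)), 4, tolerance = 0.01)
})

test_that("degenerate designs are rejected with the offending columns named", {
  tab <- toy_cohort(40, seed = 3)
  tab$race_other <- 0L
  expect_error(fit_regression(tab), "race_other")
  tab2 <- toy_cohort(40, seed = 3)
  tab2$sex <- "female"
  expect_error(fit_regression(tab2), "sex_female")
})

test_that("the full analysis bundle carries all five report tables", {
  tab <- suppressWarnings(generate_cohort(calibrate_defaults(), seed = 2))
  rep <- analyze_cohort(tab)
  expect_identical(rep$demographics$stratum, c("all", "female", "male"))
  expect_equal(sum(rep$demographics$n[2:3]), nrow(tab))
  expect_identical(nrow(rep$muscle_comparison), 16L)  # 8 measures x 2 sexes
  expect_named(rep$correlations, c("female", "male"))
  expect_s3_class(rep$regression, "regression_report")
  expect_identical(nrow(rep$lordosis), 2L)
  # the log records one gated choice per comparison (16 measures + 2 LL)
  expect_identical(nrow(rep$test_log), 18L)
  expect_true(all(rep$test_log$test %in% c("t", "mann_whitney")))
})
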