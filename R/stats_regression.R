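#' Durbin-Watson statistic of a residual sequence
#'
#' \eqn{DW = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2}, computed in the given
#' order. Around 2 under independence; reported as a diagnostic only, since
#' cohort rows are exchangeable.
#'
#' @param residuals numeric vector.
#' @return scalar in \eqn{[0, 4]} (asymptotically).
#' @export
durbin_watson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Variance inflation factors by direct definition
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} comes from regressing
#' predictor j on the remaining predictors (with intercept).
#'
#' @param X numeric matrix of predictors (no intercept column).
#' @return named numeric vector of VIFs.
#' @export
variance_inflation <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Multiple linear regression of psoas fat infiltration, fully reported
#'
#' OLS of FI_Psoas on FI_PPM, age, BMI, sex (female = 1) and race (non-
#' reference = 1), with per-predictor b, 95\% CI, SE, standardized Beta
#' (\eqn{b \cdot sd(x)/sd(y)}, n-1 denominators), t, two-sided p and VIF, and
#' model-level corrected (adjusted) R^2, overall F p-value, Durbin-Watson
#' statistic over residuals in row order, and n. No multiple-testing
#' adjustment is applied anywhere in the reporting.
#'
#' @param table a `cohort_table` with columns `FI_Psoas`, `FI_PPM`, `age`,
#'   `bmi`, `sex`, `race_other`.
#' @return object of class `regression_report` with a per-term `coefficients`
#'   data.frame and model-level fields.
#' @export
fit_regression <- function(table) {
  d <- data.frame(FI_Psoas = table$FI_Psoas, FI_PPM = table$FI_PPM,
                  age = table$age, bmi = table$bmi,
                  sex_female = as.integer(table$sex == "female"),
                  race_other = table$race_other)
  p <- 5L
  if (nrow(d) <= p + 1) stop("too few records for the regression model")
  const <- vapply(d[-1], function(v) stats::sd(v) == 0, logical(1))
  fit <- stats::lm(FI_Psoas ~ FI_PPM + age + bmi + sex_female + race_other, d)
  if (any(const) || fit$rank < p + 1) {
    bad <- unique(c(names(const)[const],
                    names(which(is.na(stats::coef(fit))))))
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  ci <- stats::confint(fit)
  b <- stats::coef(fit)
  sdy <- stats::sd(d$FI_Psoas)
  sdx <- c(NA, vapply(d[-1], stats::sd, numeric(1)))
  vif <- c(NA, variance_inflation(as.matrix(d[-1])))
  coefs <- data.frame(
    term = names(b), b = unname(b),
    ci_low = ci[, 1], ci_high = ci[, 2],
    se = s$coefficients[, 2],
    beta = unname(b * sdx / sdy),
    t = s$coefficients[, 3], p = s$coefficients[, 4],
    vif = unname(vif), row.names = NULL, stringsAsFactors = FALSE)
  fstat <- s$fstatistic
  structure(list(
    coefficients = coefs,
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    f_p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE)),
    durbin_watson = durbin_watson(stats::residuals(fit)),
    n = nrow(d), fit = fit),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Multiple linear regression, n = %d: R^2 = %.3f, corrected R^2 = %.3f, F p = %.3g, DW = %.3f\n",
              x$n, x$r_squared, x$adj_r_squared, x$f_p_value, x$durbin_watson))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
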