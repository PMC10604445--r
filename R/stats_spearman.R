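#' Spearman rank correlation with mid-rank ties and t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom (standard
#' for n > 10; exact permutation p-values are out of scope).
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return list with `rho`, `p_value`, `n`; `rho` is NA with `degenerate =
#'   TRUE` when either input is constant.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Sex-stratified Spearman matrix of psoas vs paraspinal measures
#'
#' Correlates each psoas measure (CSA, fCSA, FAT, FI) with each posterior
#' paraspinal (PPM) measure within one sex stratum.
#'
#' @param table a `cohort_table`.
#' @param sex_stratum `"female"` or `"male"`.
#' @return object of class `correlation_matrix`: 4x4 matrices `rho` and `p`
#'   (rows = psoas measures, cols = PPM measures), scalar `n`, logical matrix
#'   `degenerate` flagging constant columns.
#' @export
spearman_matrix <- function(table, sex_stratum) {
  d <- table[table$sex == sex_stratum, ]
  if (nrow(d) < 4) stop("need at least 4 records in stratum ", sex_stratum)
  meas <- c("CSA", "fCSA", "FAT", "FI")
  rho <- p <- matrix(NA_real_, 4, 4, dimnames = list(
    psoas = meas, PPM = meas))
  deg <- matrix(FALSE, 4, 4, dimnames = dimnames(rho))
  for (i in seq_along(meas)) for (j in seq_along(meas)) {
    r <- spearman_rho(d[[paste0(meas[i], "_Psoas")]],
                      d[[paste0(meas[j], "_PPM")]])
    rho[i, j] <- r$rho; p[i, j] <- r$p_value; deg[i, j] <- r$degenerate
  }
  structure(list(rho = rho, p = p, n = nrow(d), degenerate = deg,
                 stratum = sex_stratum),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman matrix (", x$stratum, ", n = ", x$n,
      "): rows psoas, cols PPM\n", sep = "")
  print(round(x$rho, 3))
  invisible(x)
}
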