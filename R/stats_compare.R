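#' Normality-gated choice of two-sample test
#'
#' Shapiro-Wilk at level `alpha` in each group; the t-test is chosen iff the
#' null of normality is retained (p >= alpha) in BOTH groups, otherwise the
#' Mann-Whitney U test. A constant sample is treated as non-normal.
#'
#' @param x,y the two groups (each n >= 3).
#' @param alpha gate level (default 0.05).
#' @return list with `choice` (`"t"` or `"mann_whitney"`) and the two
#'   Shapiro-Wilk p-values `p_x`, `p_y`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 observations for the normality gate")
  sw <- function(v) if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  p_x <- sw(x); p_y <- sw(y)
  list(choice = if (p_x >= alpha && p_y >= alpha) "t" else "mann_whitney",
       p_x = p_x, p_y = p_y)
}

summary_stats <- function(v, parametric) {
  if (parametric) {
    list(text = sprintf("%.1f ± %.1f", mean(v), stats::sd(v)),
         center = mean(v), spread = stats::sd(v))
  } else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(text = sprintf("%.1f [%.1f;%.1f]", q[2], q[1], q[3]),
         center = q[2], spread = q[3] - q[1])
  }
}

#' Compare a variable between collapsed FI groups within a sex stratum
#'
#' Applies [normality_gate()] then the chosen test (Welch t or Mann-Whitney U,
#' both two-sided). Summaries follow the test: mean +/- SD for t,
#' median [IQR] for Mann-Whitney.
#'
#' @param table a `cohort_table` (needs columns `sex`, `FI_group`, and the
#'   variable).
#' @param variable column name to compare.
#' @param sex_stratum `"female"` or `"male"`.
#' @param alpha normality-gate level.
#' @return object of class `group_comparison`: variable, stratum, per-group n
#'   and summary, test used, statistic, p-value, normality p-values.
#' @export
compare_groups <- function(table, variable, sex_stratum, alpha = 0.05) {
  stopifnot(variable %in% names(table))
  d <- table[table$sex == sex_stratum, ]
  if (!"FI_group" %in% names(d))
    d$FI_group <- classify_fi_group(d$FI_PPM)$collapsed
  lo <- d[[variable]][d$FI_group == "low_moderate"]
  hi <- d[[variable]][d$FI_group == "high"]
  if (!length(lo) || !length(hi))
    stop("empty group in stratum '", sex_stratum, "': ",
         if (!length(lo)) "low_moderate" else "high")
  gate <- normality_gate(lo, hi, alpha)
  if (gate$choice == "t") {
    ht <- stats::t.test(lo, hi)
    statistic <- unname(ht$statistic)
  } else {
    ht <- stats::wilcox.test(lo, hi, exact = FALSE, correct = FALSE)
    statistic <- unname(ht$statistic)
  }
  par <- gate$choice == "t"
  structure(list(variable = variable, stratum = sex_stratum,
                 test = gate$choice, statistic = statistic,
                 p_value = ht$p.value,
                 normality_p = c(low_moderate = gate$p_x, high = gate$p_y),
                 n = c(low_moderate = length(lo), high = length(hi)),
                 summary_low = summary_stats(lo, par)$text,
                 summary_high = summary_stats(hi, par)$text),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): <50%% FI_PPM %s vs >=50%% %s; %s p = %.3g\n",
              x$variable, x$stratum, x$summary_low, x$summary_high,
              if (x$test == "t") "t-test" else "Mann-Whitney U",
              x$p_value))
  invisible(x)
}
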