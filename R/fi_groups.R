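#' Kjaer fat-infiltration groups
#'
#' Three-level rule: low (< 10\%), medium (10--50\%), high (>= 50\%); plus the
#' collapsed two-level rule low-to-moderate (< 50\%) vs high (>= 50\%). Both
#' boundaries are handled so the partition is exhaustive and mutually
#' exclusive: FI = 10 is medium, FI = 50 is high.
#'
#' @param fi numeric vector of FI percentages in \eqn{[0, 100]}.
#' @return data.frame with factor columns `group3`
#'   (low/medium/high) and `collapsed` (low_moderate/high).
#' @export
classify_fi_group <- function(fi) {
  if (any(!is.finite(fi) | fi < 0 | fi > 100))
    stop("FI values must lie in [0, 100]")
  g3 <- cut(fi, breaks = c(-Inf, 10, 50, Inf), right = FALSE,
            labels = c("low", "medium", "high"))
  data.frame(
    group3 = g3,
    collapsed = factor(ifelse(fi < 50, "low_moderate", "high"),
                       levels = c("low_moderate", "high")))
}
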