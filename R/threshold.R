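#' Automatic intensity threshold (exact Otsu criterion)
#'
#' Returns the cut maximizing the between-class variance
#' \eqn{w_1 w_2 (m_1 - m_2)^2} over all splits of the sorted distinct values,
#' computed exactly on the supplied intensities (no histogram binning). The
#' returned threshold is the midpoint between the two distinct values
#' straddling the optimal split, so it lies strictly between the minimum and
#' maximum. When several splits tie, the lowest is taken.
#'
#' @param intensities numeric vector with at least two distinct values.
#' @return scalar threshold; pixels strictly above it are classified as fat by
#'   [classify_pixels()].
#' @export
select_threshold <- function(intensities) {
  v <- sort(as.numeric(intensities))
  u <- unique(v)
  if (length(u) < 2)
    stop("degenerate histogram: all intensities identical, no threshold exists")
  n <- length(v)
  cnt <- tabulate(findInterval(v, u), nbins = length(u))
  n1 <- cumsum(cnt)[-length(u)]
  s1 <- cumsum(cnt * u)[-length(u)]
  tot <- sum(v)
  m1 <- s1 / n1
  m2 <- (tot - s1) / (n - n1)
  bcv <- n1 * (n - n1) * (m1 - m2)^2
  k <- which.max(bcv)
  (u[k] + u[k + 1]) / 2
}

#' Classify pixels as fat or muscle at a threshold
#'
#' A pixel is fat iff its (bias-corrected) intensity is strictly above the
#' threshold; a pixel exactly at the threshold counts as muscle — the
#' conservative tie-break for a fat-infiltration measure.
#'
#' @param corrected_intensities numeric vector (or matrix) of intensities.
#' @param threshold finite scalar.
#' @return logical fat mask, same shape as the input.
#' @export
classify_pixels <- function(corrected_intensities, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  corrected_intensities > threshold
}
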