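#' Fit a multiplicative quadratic bias field over a region of interest
#'
#' Iterative scheme coupling the bias fit to the fat/muscle split:
#' \enumerate{
#'   \item provisional two-class split of the (current) corrected ROI
#'     intensities at the automatic threshold;
#'   \item least-squares fit of the six-coefficient quadratic surface to the
#'     original intensities of the muscle-class pixels (the muscle class is
#'     assumed spatially extensive and of constant underlying intensity, so
#'     its observed intensities trace the shading);
#'   \item division of the original ROI intensities by the fitted surface, so
#'     corrected muscle-class pixels sit near 1 and fat-class pixels near the
#'     fat/muscle intensity ratio.
#' }
#' The surface is determined up to a global scale, which cancels on division.
#' Steps repeat until the fat/muscle split is unchanged between iterations
#' (or, once both thresholds live on the corrected scale, the threshold moves
#' by less than `tol` times the corrected intensity range), or
#' `max_iterations` is reached. Coordinates are normalized to \eqn{[-1,1]^2}
#' over the full image extent.
#'
#' @param image a [slice_image()].
#' @param roi logical matrix (same shape) or integer pixel indices selecting
#'   the region; at least 12 pixels (twice the coefficient count).
#' @param max_iterations maximum threshold/fit cycles (default 25).
#' @param tol relative threshold-change tolerance (default 1e-6 of the
#'   corrected intensity range).
#' @return object of class `bias_model`: `coefficients` (length 6, in the
#'   normalized basis), `convention`,
#'   `fit_iterations`, `converged`, `threshold` (final threshold on the
#'   corrected scale), and `surface` (fitted values at the ROI pixels, in ROI
#'   index order).
#' @export
fit_bias_field <- function(image, roi, max_iterations = 25, tol = 1e-6) {
  stopifnot(inherits(image, "slice_image"))
  img <- image$intensities
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(idx) < 12)
    stop("ROI too small for quadratic bias fit: need at least 12 pixels, got ",
         length(idx))
  nc <- normalized_coords(nrow(img), ncol(img))
  x <- nc$x[idx]; y <- nc$y[idx]
  X <- cbind(1, x, y, x^2, x * y, y^2)
  vals <- img[idx]

  flat <- function(cf, surface, iterations, converged, threshold = NA_real_) {
    structure(list(coefficients = as.numeric(cf),
                   convention = "normalized [-1,1]^2 over image extent",
                   fit_iterations = iterations, converged = converged,
                   threshold = threshold, surface = surface,
                   roi_index = idx),
              class = "bias_model")
  }

  if (diff(range(vals)) == 0)    # flat field: constant surface, nothing to do
    return(flat(c(vals[1], 0, 0, 0, 0, 0), rep(vals[1], length(idx)), 0L, TRUE))

  th <- select_threshold(vals)
  corrected <- vals
  cf <- c(1, 0, 0, 0, 0, 0)
  surf <- rep(1, length(idx))
  converged <- FALSE
  it <- 0L
  prev_muscle <- NULL
  while (it < max_iterations) {
    it <- it + 1L
    muscle <- corrected <= th
    if (sum(muscle) < 6)
      stop("degenerate bias fit: fewer than 6 muscle-class pixels")
    fit <- stats::lm.fit(X[muscle, , drop = FALSE], vals[muscle])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    surf <- as.numeric(X %*% cf)
    if (any(surf <= 0))
      stop("fitted bias surface is non-positive within the ROI; fit rejected")
    corrected <- vals / surf
    if (diff(range(corrected)) == 0) { converged <- TRUE; break }
    th_new <- select_threshold(corrected)
    new_muscle <- corrected <= th_new
    if (identical(new_muscle, prev_muscle) || identical(new_muscle, muscle) ||
        (it > 1 && abs(th_new - th) < tol * diff(range(corrected)))) {
      th <- th_new; converged <- TRUE; break
    }
    prev_muscle <- muscle
    th <- th_new
  }
  flat(cf, surf, it, converged, th)
}

#' Apply a fitted bias model to ROI intensities
#'
#' @param image a [slice_image()].
#' @param model a `bias_model` from [fit_bias_field()].
#' @return corrected intensities at the model's ROI pixels (ROI index order).
#' @export
correct_bias <- function(image, model) {
  stopifnot(inherits(model, "bias_model"))
  image$intensities[model$roi_index] / model$surface
}

#' @export
print.bias_model <- function(x, ...) {
  cat("bias_model: coefficients",
      paste(sprintf("%.4g", x$coefficients), collapse = ", "), "\n")
  cat("  ", x$fit_iterations, "iteration(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}
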