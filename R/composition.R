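#' Configuration for muscle composition measurement
#'
#' @param bias_correction apply the iterative quadratic bias-field correction
#'   before thresholding (default TRUE).
#' @param max_iterations,tol passed to [fit_bias_field()].
#' @param min_roi_px minimum region size for a bias fit; smaller regions are
#'   measured without correction.
#' @return list of class `measure_config`.
#' @export
measure_config <- function(bias_correction = TRUE, max_iterations = 25,
                           tol = 1e-6, min_roi_px = 12) {
  structure(list(bias_correction = bias_correction,
                 max_iterations = max_iterations, tol = tol,
                 min_roi_px = min_roi_px),
            class = "measure_config")
}

new_composition <- function(CSA, FAT, FI = if (CSA > 0) 100 * FAT / CSA else 0,
                            threshold_used, n_pixels, muscle, side,
                            single_tissue = FALSE, converged = NA) {
  structure(list(CSA = CSA, fCSA = CSA - FAT, FAT = FAT, FI = FI,
                 threshold_used = threshold_used, n_pixels = n_pixels,
                 muscle = muscle, side = side,
                 single_tissue = single_tissue, converged = converged),
            class = "muscle_composition")
}

#' Measure the composition of one labeled muscle region
#'
#' Pipeline: quadratic bias-field fit and correction, automatic threshold on
#' the corrected intensities, fat/muscle pixel classification, then areas.
#' CSA is the full region area, FAT the fat-classified area, fCSA = CSA - FAT,
#' and FI = 100 * FAT / CSA (percent). Pixel areas are taken from the image
#' spacing (mm^2) and reported in cm^2.
#'
#' @param image a [slice_image()].
#' @param mask a [roi_mask()] aligned to the image.
#' @param label integer label of the region to measure.
#' @param config a [measure_config()].
#' @return object of class `muscle_composition` with fields `CSA`, `fCSA`,
#'   `FAT` (cm^2), `FI` (percent), `threshold_used`, `n_pixels`, `muscle`,
#'   `side`, `single_tissue` (TRUE when the region held a single intensity and
#'   FI was set to 0 with a warning) and `converged` (bias-fit flag).
#' @export
measure_muscle <- function(image, mask, label, config = measure_config()) {
  stopifnot(inherits(image, "slice_image"), inherits(mask, "roi_mask"))
  if (!all(dim(image$intensities) == dim(mask$labels)))
    stop("image and mask grids differ in shape")
  row <- mask$label_table[mask$label_table$label == label, ]
  if (nrow(row) == 0) stop("label ", label, " not present in label table")
  idx <- which(mask$labels == label)
  if (!length(idx)) stop("region for label ", label, " is empty")

  vals <- image$intensities[idx]
  px_cm2 <- prod(image$pixel_spacing_mm) / 100  # mm^2 -> cm^2
  CSA <- length(idx) * px_cm2

  distinct <- length(unique(vals)) > 1
  converged <- NA
  threshold <- NA_real_
  if (config$bias_correction && distinct && length(idx) >= config$min_roi_px) {
    model <- fit_bias_field(image, idx, config$max_iterations, config$tol)
    corrected <- correct_bias(image, model)
    converged <- model$converged
    threshold <- model$threshold
  } else {
    corrected <- vals
  }

  if (length(unique(corrected)) < 2) {
    warning("single-tissue region (label ", label,
            "): degenerate histogram, FI set to 0")
    return(new_composition(CSA, FAT = 0, FI = 0, threshold_used = NA_real_,
                           n_pixels = length(idx), muscle = row$muscle,
                           side = row$side, single_tissue = TRUE,
                           converged = converged))
  }
  if (is.na(threshold)) threshold <- select_threshold(corrected)
  fat <- classify_pixels(corrected, threshold)
  FAT <- sum(fat) * px_cm2
  new_composition(CSA, FAT, threshold_used = threshold,
                  n_pixels = length(idx), muscle = row$muscle,
                  side = row$side, converged = converged)
}

#' Combine left and right measurements of the same muscle
#'
#' Areas are summed; FI is recomputed from the summed areas,
#' \eqn{100 (FAT_L + FAT_R) / (CSA_L + CSA_R)} — the area-weighted value, not
#' the mean of the per-side percentages.
#'
#' @param left,right `muscle_composition` objects for the same muscle.
#' @return bilateral `muscle_composition`.
#' @export
combine_sides <- function(left, right) {
  stopifnot(inherits(left, "muscle_composition"),
            inherits(right, "muscle_composition"))
  if (!identical(left$muscle, right$muscle))
    stop("cannot combine different muscles: ", left$muscle, " vs ", right$muscle)
  new_composition(CSA = left$CSA + right$CSA, FAT = left$FAT + right$FAT,
                  threshold_used = NA_real_,
                  n_pixels = left$n_pixels + right$n_pixels,
                  muscle = left$muscle, side = "bilateral",
                  single_tissue = left$single_tissue && right$single_tissue,
                  converged = NA)
}

#' Normalize areas by the square of patient height
#'
#' Reported units are cm^2/m^2, so each area is divided by height in meters
#' squared; FI is a ratio and is unchanged.
#'
#' @param composition a `muscle_composition`.
#' @param height_m patient height in meters, in (1.0, 2.5).
#' @return object of class `normalized_composition` with `CSA`, `fCSA`, `FAT`
#'   in cm^2/m^2, `FI` (percent) and `height_m`.
#' @export
normalize_by_height <- function(composition, height_m) {
  stopifnot(inherits(composition, "muscle_composition"))
  if (!is.finite(height_m) || height_m <= 1.0 || height_m >= 2.5)
    stop("implausible height: ", height_m, " m (must be in (1.0, 2.5))")
  h2 <- height_m^2
  structure(list(CSA = composition$CSA / h2,
                 fCSA = composition$fCSA / h2,
                 FAT = composition$FAT / h2,
                 FI = composition$FI,
                 height_m = height_m,
                 muscle = composition$muscle, side = composition$side),
            class = "normalized_composition")
}

#' @export
print.muscle_composition <- function(x, ...) {
  cat(sprintf("%s (%s): CSA %.3f cm^2, fCSA %.3f, FAT %.3f, FI %.1f%% (%d px)\n",
              x$muscle, x$side, x$CSA, x$fCSA, x$FAT, x$FI, x$n_pixels))
  invisible(x)
}

#' @export
print.normalized_composition <- function(x, ...) {
  cat(sprintf("%s (%s): CSA %.3f cm^2/m^2, fCSA %.3f, FAT %.3f, FI %.1f%% (height %.2f m)\n",
              x$muscle, x$side, x$CSA, x$fCSA, x$FAT, x$FI, x$height_m))
  invisible(x)
}

#' Composition as a one-row data frame
#'
#' @param x a `muscle_composition` or `normalized_composition`.
#' @param ... unused.
#' @return one-row data.frame.
#' @export
as.data.frame.muscle_composition <- function(x, ...) {
  data.frame(muscle = x$muscle, side = x$side, CSA = x$CSA, fCSA = x$fCSA,
             FAT = x$FAT, FI = x$FI, threshold_used = x$threshold_used,
             n_pixels = x$n_pixels, stringsAsFactors = FALSE)
}
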