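#' Evaluate a 2D quadratic bias surface
#'
#' The multiplicative coil-shading model used throughout the package is a
#' six-coefficient quadratic surface evaluated on coordinates normalized to
#' \eqn{[-1,1]^2} over the image extent:
#' \deqn{S(x, y) = c_{00} + c_{10} x + c_{01} y + c_{20} x^2 + c_{11} x y + c_{02} y^2}
#'
#' @param coefficients numeric vector of length 6: (c00, c10, c01, c20, c11, c02).
#' @param x,y coordinates (vectorized), normalized to \eqn{[-1,1]}.
#' @return surface value(s), same length as `x`.
#' @export
evaluate_bias_surface <- function(coefficients, x, y) {
  stopifnot(length(coefficients) == 6, is.numeric(coefficients))
  c_ <- as.numeric(coefficients)
  c_[1] + c_[2] * x + c_[3] * y + c_[4] * x^2 + c_[5] * x * y + c_[6] * y^2
}

#' Normalized pixel coordinates
#'
#' Maps pixel indices of an `nrow x ncol` grid to \eqn{[-1,1]^2}; columns map
#' to x, rows to y. Used both when imposing a bias field on a phantom and when
#' fitting one, so the two share a coordinate convention.
#'
#' @param nrow,ncol grid dimensions.
#' @return list with matrices `x` and `y` of dimension `nrow x ncol`.
#' @keywords internal
normalized_coords <- function(nrow, ncol) {
  xs <- if (ncol > 1) 2 * (seq_len(ncol) - 1) / (ncol - 1) - 1 else rep(0, ncol)
  ys <- if (nrow > 1) 2 * (seq_len(nrow) - 1) / (nrow - 1) - 1 else rep(0, nrow)
  list(x = matrix(xs, nrow, ncol, byrow = TRUE),
       y = matrix(ys, nrow, ncol))
}

#' Default axial-slice region layout
#'
#' Four elliptical regions mimicking an L4-level slice: one posterior
#' paraspinal (PPM = erector spinae + multifidus, treated as one compartment)
#' and one psoas region per side. Purely a fixture convention, not anatomy.
#'
#' @param height_px,width_px image size the layout is designed for.
#' @return list of region descriptors, each with `label`, `muscle`, `side`,
#'   `center` (row, col) and `semi_axes` (row, col) in pixels.
#' @export
default_phantom_regions <- function(height_px = 160, width_px = 160) {
  sc <- c(height_px / 160, width_px / 160)
  reg <- function(label, muscle, side, center, axes) {
    list(label = label, muscle = muscle, side = side,
         center = center * sc, semi_axes = axes * sc)
  }
  list(
    reg(1L, "PPM",   "left",  c(112, 52),  c(20, 14)),
    reg(2L, "PPM",   "right", c(112, 108), c(20, 14)),
    reg(3L, "psoas", "left",  c(68, 56),   c(12, 9)),
    reg(4L, "psoas", "right", c(68, 104),  c(12, 9))
  )
}

#' Specification for a synthetic axial-slice phantom
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param pixel_spacing_mm length-2 positive numeric (row, col) spacing in mm.
#' @param regions list of region descriptors as produced by
#'   [default_phantom_regions()].
#' @param true_fat_fraction numeric in \eqn{[0,1]}, one per region (recycled if
#'   scalar): the ground-truth fraction of fat pixels in each region.
#' @param mu_muscle,mu_fat mean class intensities; `mu_fat` must exceed
#'   `mu_muscle`.
#' @param noise_sd additive Gaussian noise SD (>= 0), applied after the bias.
#' @param bias_coefficients length-6 quadratic surface coefficients (see
#'   [evaluate_bias_surface()]); `c(1, 0, 0, 0, 0, 0)` means no bias.
#' @param fat_mode `"count"` places exactly `round(f * N)` fat pixels at seeded
#'   positions so truth fractions are exact; `"bernoulli"` draws each pixel
#'   independently.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height_px = 160, image_width_px = 160,
                         pixel_spacing_mm = c(1, 1),
                         regions = default_phantom_regions(image_height_px, image_width_px),
                         true_fat_fraction = 0.3,
                         mu_muscle = 70, mu_fat = 100,
                         noise_sd = 0,
                         bias_coefficients = c(1, 0, 0, 0, 0, 0),
                         fat_mode = c("count", "bernoulli"),
                         seed = 1L) {
  fat_mode <- match.arg(fat_mode)
  true_fat_fraction <- rep_len(true_fat_fraction, length(regions))
  spec <- structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    regions = regions,
    true_fat_fraction = true_fat_fraction,
    mu_muscle = mu_muscle, mu_fat = mu_fat,
    noise_sd = noise_sd,
    bias_coefficients = as.numeric(bias_coefficients),
    fat_mode = fat_mode,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$image_height_px < 1 || spec$image_width_px < 1)
    stop("image dimensions must be positive")
  if (any(spec$pixel_spacing_mm <= 0))
    stop("pixel spacing must be positive")
  if (spec$mu_fat <= spec$mu_muscle)
    stop("mu_fat must exceed mu_muscle")
  if (spec$noise_sd < 0)
    stop("noise_sd must be nonnegative")
  bad <- which(spec$true_fat_fraction < 0 | spec$true_fat_fraction > 1)
  if (length(bad))
    stop("true_fat_fraction outside [0,1] for region(s): ",
         paste(vapply(spec$regions[bad], `[[`, 1L, "label"), collapse = ", "))
  if (length(spec$bias_coefficients) != 6)
    stop("bias_coefficients must have length 6")
  invisible(spec)
}

rasterize_ellipse <- function(region, nrow, ncol) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  c_ <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((r - region$center[1]) / region$semi_axes[1])^2 +
    ((c_ - region$center[2]) / region$semi_axes[2])^2 <= 1
}

#' Generate a synthetic axial-slice phantom with exact ground truth
#'
#' Each region's pixels are assigned fat or muscle according to its true fat
#' fraction, given the class mean intensity, then multiplied by the quadratic
#' bias surface and degraded with additive Gaussian noise. The truth mask and
#' per-region fractions are recorded before bias and noise, so measured FI can
#' be compared to an exact reference.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_slice` with elements `image`
#'   ([slice_image()]), `masks` ([roi_mask()]), `truth_fat_mask` (logical
#'   matrix), `truth_fat_fraction` (named per label), and `applied_bias`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$image_height_px; W <- spec$image_width_px
  labels <- matrix(0L, H, W)
  overlaps <- character(0)
  for (reg in spec$regions) {
    px <- rasterize_ellipse(reg, H, W)
    clash <- px & labels != 0L
    if (any(clash)) {
      others <- unique(labels[clash])
      overlaps <- c(overlaps, paste0(reg$label, "/", others))
    }
    labels[px] <- reg$label
  }
  if (length(overlaps))
    stop("overlapping regions: ", paste(overlaps, collapse = ", "))

  set.seed(spec$seed)
  truth <- matrix(FALSE, H, W)
  truth_frac <- numeric(length(spec$regions))
  names(truth_frac) <- vapply(spec$regions, `[[`, 1L, "label")
  for (i in seq_along(spec$regions)) {
    idx <- which(labels == spec$regions[[i]]$label)
    f <- spec$true_fat_fraction[i]
    if (spec$fat_mode == "count") {
      n_fat <- round(f * length(idx))
      fat_idx <- if (n_fat > 0) sample(idx, n_fat) else integer(0)
    } else {
      fat_idx <- idx[stats::runif(length(idx)) < f]
    }
    truth[fat_idx] <- TRUE
    truth_frac[i] <- length(fat_idx) / length(idx)
  }

  clean <- matrix(0, H, W)
  clean[labels != 0L] <- spec$mu_muscle
  clean[truth] <- spec$mu_fat

  nc <- normalized_coords(H, W)
  surface <- evaluate_bias_surface(spec$bias_coefficients, nc$x, nc$y)
  img <- clean * surface
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)

  label_table <- do.call(rbind, lapply(spec$regions, function(r)
    data.frame(label = r$label, muscle = r$muscle, side = r$side,
               stringsAsFactors = FALSE)))

  structure(list(
    image = slice_image(img, spec$pixel_spacing_mm),
    masks = roi_mask(labels, label_table),
    truth_fat_mask = truth,
    truth_fat_fraction = truth_frac,
    applied_bias = list(coefficients = spec$bias_coefficients,
                        convention = "normalized [-1,1]^2 over image extent",
                        surface = surface),
    spec = spec
  ), class = "phantom_slice")
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat("phantom_slice:", nrow(x$image$intensities), "x",
      ncol(x$image$intensities), "px,",
      length(x$truth_fat_fraction), "regions\n")
  cat("  truth fat fractions:",
      paste(sprintf("%s=%.3f", names(x$truth_fat_fraction),
                    x$truth_fat_fraction), collapse = ", "), "\n")
  invisible(x)
}
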