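#' A 2D intensity slice with physical pixel spacing
#'
#' @param intensities numeric matrix of pixel intensities.
#' @param pixel_spacing_mm length-2 positive numeric (row, col) spacing in mm.
#' @return object of class `slice_image`.
#' @export
slice_image <- function(intensities, pixel_spacing_mm = c(1, 1)) {
  intensities <- as.matrix(intensities)
  if (!length(intensities)) stop("intensity grid must be non-empty")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be positive")
  structure(list(intensities = intensities,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "slice_image")
}

#' A labeled per-muscle, per-side region mask aligned to a slice
#'
#' @param labels integer matrix, 0 = background, same shape as the image it
#'   annotates.
#' @param label_table data.frame with columns `label`, `muscle` (`"psoas"` or
#'   `"PPM"`) and `side` (`"left"` or `"right"`); every nonzero label in
#'   `labels` must appear here.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(labels, label_table) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  used <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(used, label_table$label)
  if (length(missing))
    stop("labels present in grid but absent from label table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, label_table = label_table),
            class = "roi_mask")
}

#' @export
print.slice_image <- function(x, ...) {
  cat("slice_image:", nrow(x$intensities), "x", ncol(x$intensities),
      "px, spacing", paste(x$pixel_spacing_mm, collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask:", nrow(x$label_table), "regions;",
      sum(x$labels != 0L), "labeled pixels\n")
  invisible(x)
}
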