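#' Write / read a slice image
#'
#' NIfTI (`.nii` / `.nii.gz`, 2D with pixel spacing in the header) or a plain
#' CSV matrix for dependency-free round trips (spacing then supplied on read).
#'
#' @param image a [slice_image()].
#' @param path destination; format chosen by extension.
#' @return the path, invisibly.
#' @export
write_slice <- function(image, path) {
  stopifnot(inherits(image, "slice_image"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(image$intensities)
    RNifti::pixdim(img) <- image$pixel_spacing_mm
    RNifti::writeNifti(img, path)
  } else {
    utils::write.table(image$intensities, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_slice
#' @param pixel_spacing_mm spacing used for the CSV mode (ignored for NIfTI,
#'   where it comes from the header).
#' @export
read_slice <- function(path, pixel_spacing_mm = c(1, 1)) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- as.numeric(RNifti::pixdim(img)[1:2])
    m <- matrix(as.numeric(img), nrow = dim(img)[1])
    slice_image(m, sp)
  } else {
    slice_image(as.matrix(utils::read.table(path, sep = ",")), pixel_spacing_mm)
  }
}

#' Write / read a labeled ROI mask
#'
#' The label grid goes to NIfTI or CSV (as for [write_slice()]); the label
#' semantics (muscle, side per label) go to a JSON table next to it.
#'
#' @param mask a [roi_mask()].
#' @param path label-grid destination.
#' @param labels_path JSON label-table destination (default: `path` with a
#'   `.labels.json` suffix).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path,
                       labels_path = paste0(sub("\\.nii(\\.gz)?$|\\.csv$", "", path),
                                            ".labels.json")) {
  stopifnot(inherits(mask, "roi_mask"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(mask$labels), path)
  } else {
    utils::write.table(mask$labels, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(mask$label_table, labels_path, dataframe = "rows")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path,
                      labels_path = paste0(sub("\\.nii(\\.gz)?$|\\.csv$", "", path),
                                           ".labels.json")) {
  grid <- if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    matrix(as.integer(img), nrow = dim(img)[1])
  } else {
    as.matrix(utils::read.table(path, sep = ","))
  }
  tab <- jsonlite::fromJSON(labels_path)
  roi_mask(grid, tab)
}

#' Write a phantom to a directory
#'
#' Image and mask in the chosen format plus a JSON ground-truth sidecar
#' (per-region truth fractions, applied bias coefficients, seed).
#'
#' @param phantom a `phantom_slice`.
#' @param dir destination directory (created if needed).
#' @param format `"nifti"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("nifti", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".csv"
  write_slice(phantom$image, file.path(dir, paste0("image", ext)))
  write_mask(phantom$masks, file.path(dir, paste0("mask", ext)))
  jsonlite::write_json(list(
    truth_fat_fraction = as.list(phantom$truth_fat_fraction),
    bias_coefficients = phantom$applied_bias$coefficients,
    bias_convention = phantom$applied_bias$convention,
    seed = phantom$spec$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write / read a cohort table as CSV
#'
#' @param table a `cohort_table`.
#' @param path CSV destination.
#' @return the path (write) or the `cohort_table` (read).
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("FI_group3", "FI_group") %in% names(tab))) {
    tab$FI_group3 <- factor(tab$FI_group3, levels = c("low", "medium", "high"))
    tab$FI_group <- factor(tab$FI_group, levels = c("low_moderate", "high"))
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Pipeline run configuration
#'
#' Serializable configuration for [run_pipeline()]; `write_config()` /
#' `read_config()` round-trip it through JSON losslessly.
#'
#' @param seed top-level seed; each stage derives its own seed from it.
#' @param out output directory.
#' @param stages subset of `c("phantom", "measure", "cohort", "analyze")`.
#' @param n_patients cohort size.
#' @param phantom_fat_fraction per-region truth fraction for the phantom stage.
#' @param bias_correction,max_iterations,tol composition settings.
#' @param fi_boundaries FI group boundaries (percent).
#' @param alpha significance level used in reports.
#' @param format image format for the phantom stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out = "musclefi-run",
                       stages = c("phantom", "measure", "cohort", "analyze"),
                       n_patients = 190L, phantom_fat_fraction = 0.3,
                       bias_correction = TRUE, max_iterations = 25L,
                       tol = 1e-6, fi_boundaries = c(10, 50), alpha = 0.05,
                       format = "csv") {
  structure(list(seed = as.integer(seed), out = out, stages = stages,
                 n_patients = as.integer(n_patients),
                 phantom_fat_fraction = phantom_fat_fraction,
                 bias_correction = bias_correction,
                 max_iterations = as.integer(max_iterations), tol = tol,
                 fi_boundaries = fi_boundaries, alpha = alpha,
                 format = format),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON destination.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- run_config()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.integer(cfg[[nm]])) v <- as.integer(v)
    else if (is.double(cfg[[nm]])) v <- as.numeric(v)
    else if (is.character(cfg[[nm]])) v <- as.character(v)
    cfg[[nm]] <- v
  }
  cfg
}
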