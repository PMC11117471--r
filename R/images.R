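#' Calibrated CT image in Hounsfield units
#'
#' A light container for a single CT slice: a numeric matrix of HU values
#' (rows = y, columns = x; pixel `(x, y)` in 0-based coordinates is
#' `values[y + 1, x + 1]`) plus the in-plane pixel spacing in millimetres.
#'
#' @param values Numeric matrix of HU values; all finite.
#' @param spacing Pixel spacing in mm per pixel (> 0).
#' @return An object of class `hu_image`.
#' @export
hu_image <- function(values, spacing) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) rlang::abort("HU values must all be finite")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    rlang::abort("spacing must be a single positive number (mm/pixel)")
  }
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image> %d x %d px, %.3g mm/px, HU range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary lung mask
#'
#' @param values Logical matrix (TRUE = lung).
#' @param n_components Number of connected lung components recorded at
#'   extraction time.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(values, n_components = NA_integer_) {
  stopifnot(is.matrix(values), is.logical(values))
  structure(list(values = values, n_components = as.integer(n_components)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d x %d px, %d components, area %d px\n",
              nrow(x$values), ncol(x$values), x$n_components,
              sum(x$values)))
  invisible(x)
}

#' 8-bit grayscale image
#'
#' @param values Integer matrix with all values in `[0, 255]`.
#' @return An object of class `uint8_image`.
#' @export
uint8_image <- function(values) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  if (any(values < 0L | values > 255L)) {
    rlang::abort("uint8 image values must lie in [0, 255]")
  }
  structure(list(values = values), class = "uint8_image")
}

#' @export
print.uint8_image <- function(x, ...) {
  cat(sprintf("<uint8_image> %d x %d px, range [%d, %d]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

same_shape <- function(a, b) identical(dim(a), dim(b))
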