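#' Region-of-interest image
#'
#' Container for a 2D grayscale CT-like intensity grid together with a
#' pixel-validity mask marking the pixels that belong to the region of
#' interest (ROI). All objective image-quality estimators in the package
#' operate on this type.
#'
#' @param pixels numeric matrix of intensities (HU-like scale).
#' @param mask logical matrix of the same dimension; `TRUE` marks pixels
#'   inside the ROI. Defaults to all pixels valid.
#' @param pixel_spacing physical length per pixel (same unit in both
#'   directions); used only to express edge-sharpness widths. Default 1.
#'
#' @return An object of class `roi_image`: a list with elements `pixels`,
#'   `mask` and `pixel_spacing`.
#' @examples
#' img <- roi_image(matrix(68, 32, 32))
#' img
#' @export
roi_image <- function(pixels, mask = NULL, pixel_spacing = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(pixels)))
    stop("`mask` must be a logical matrix with the dimensions of `pixels`",
         call. = FALSE)
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stop("ROI mask has no valid pixel", call. = FALSE)
  if (any(!is.finite(pixels[mask])))
    stop("non-finite intensities inside the ROI mask", call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("`pixel_spacing` must be a positive scalar", call. = FALSE)
  structure(list(pixels = pixels, mask = mask,
                 pixel_spacing = pixel_spacing),
            class = "roi_image")
}

#' @noRd
as_roi_image <- function(x) {
  if (inherits(x, "roi_image")) return(x)
  if (is.matrix(x)) return(roi_image(x))
  stop("expected an `roi_image` or a numeric matrix", call. = FALSE)
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %d x %d pixels, %d in ROI (%.1f%%), spacing %g\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              100 * mean(x$mask), x$pixel_spacing))
  v <- x$pixels[x$mask]
  cat(sprintf("  intensity range [%.6g, %.6g], mean %.6g\n",
              min(v), max(v), mean(v)))
  invisible(x)
}

#' Noise map: local standard deviation of a highpass residual
#'
#' @param local_std numeric matrix; `NA` where the statistic is undefined
#'   (window not fully inside the ROI).
#' @param window_radius radius (pixels) of the circular window used.
#' @param source the `roi_image` the map was derived from.
#' @return An object of class `noise_map`.
#' @keywords internal
new_noise_map <- function(local_std, window_radius, source) {
  stopifnot(is.matrix(local_std))
  if (any(local_std[is.finite(local_std)] < 0))
    stop("negative local standard deviation", call. = FALSE)
  structure(list(local_std = local_std, window_radius = window_radius,
                 source = source),
            class = "noise_map")
}

#' @export
print.noise_map <- function(x, ...) {
  v <- x$local_std[is.finite(x$local_std)]
  cat(sprintf("<noise_map> %d x %d, window radius %g px, %d defined pixels\n",
              nrow(x$local_std), ncol(x$local_std), x$window_radius,
              length(v)))
  if (length(v))
    cat(sprintf("  local STD: mean %.4g, range [%.4g, %.4g]\n",
                mean(v), min(v), max(v)))
  invisible(x)
}
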