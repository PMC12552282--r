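#' Specification of a synthetic CT-like phantom
#'
#' Describes a two-dimensional digital phantom with one or two soft-tissue
#' plateaus, additive Gaussian noise of controlled magnitude and spatial
#' correlation, and a controlled boundary blur. Phantoms generated from a
#' spec carry exact ground truth, so every estimator in the package can be
#' validated by parameter recovery.
#'
#' @param shape integer vector `c(rows, cols)`, both positive. Default
#'   `c(256, 256)`.
#' @param si_low intensity of the (single or lower) tissue plateau
#'   (HU-like).
#' @param si_high optional intensity of the higher plateau; must exceed
#'   `si_low`. Absent for one-tissue phantoms.
#' @param noise_sigma standard deviation of the additive noise field
#'   (>= 0). The realized noise field is rescaled after correlation
#'   filtering so its sample standard deviation equals `noise_sigma`
#'   exactly.
#' @param noise_corr_sigma Gaussian correlation length of the noise field
#'   in pixels (0 = white noise).
#' @param edge_blur_sigma Gaussian blur of the tissue boundary in pixels
#'   (>= 0).
#' @param edge_geometry `"vertical-step"` (left half low, right half high)
#'   or `"disk"` (high-intensity disk of radius `min(shape)/4` at the
#'   center).
#' @param seed integer RNG seed; generation is deterministic given the
#'   spec.
#' @param quantize if `TRUE`, round intensities to integers (mimicking HU
#'   integer images). Default `FALSE` so estimator error is isolated from
#'   quantization error.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256, 256), si_low, si_high = NULL,
                         noise_sigma = 0, noise_corr_sigma = 0,
                         edge_blur_sigma = 0,
                         edge_geometry = c("vertical-step", "disk"),
                         seed = 1L, quantize = FALSE) {
  edge_geometry <- match.arg(edge_geometry)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape <= 0L))
    stop("`shape` must be two positive integers", call. = FALSE)
  if (missing(si_low) || is.null(si_low)) {
    if (!is.null(si_high))
      stop("`si_high` given without `si_low`", call. = FALSE)
    stop("`si_low` is required", call. = FALSE)
  }
  if (!is.null(si_high) && si_high <= si_low)
    stop("`si_high` must exceed `si_low`", call. = FALSE)
  for (s in c(noise_sigma, noise_corr_sigma, edge_blur_sigma))
    if (!is.finite(s) || s < 0)
      stop("sigma parameters must be >= 0", call. = FALSE)
  structure(list(shape = shape, si_low = si_low, si_high = si_high,
                 noise_sigma = noise_sigma,
                 noise_corr_sigma = noise_corr_sigma,
                 edge_blur_sigma = edge_blur_sigma,
                 edge_geometry = edge_geometry,
                 seed = as.integer(seed), quantize = isTRUE(quantize)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d %s, si %s%s, noise %g (corr %g px), blur %g px, seed %d\n",
              x$shape[1], x$shape[2], x$edge_geometry,
              format(x$si_low),
              if (is.null(x$si_high)) "" else paste0("/", format(x$si_high)),
              x$noise_sigma, x$noise_corr_sigma, x$edge_blur_sigma, x$seed))
  invisible(x)
}

#' Generate a phantom with known ground truth
#'
#' Renders the noiseless tissue template (plateaus convolved with a
#' Gaussian of `edge_blur_sigma`), adds white Gaussian noise optionally
#' convolved with a Gaussian of `noise_corr_sigma` and rescaled so its
#' realized standard deviation equals `noise_sigma` exactly, and records
#' per-tissue ground-truth masks. Pixels whose noiseless value differs
#' from both plateau levels by more than 1% of the plateau contrast form
#' the blurred boundary band and belong to neither tissue mask.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `spec`, `image`
#'   (an [roi_image]), `tissue_masks` (named list of logical matrices,
#'   disjoint), and `true_noise_sigma_effective` (realized noise standard
#'   deviation after rescaling).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  n <- spec$shape[1L]; m <- spec$shape[2L]
  template <- matrix(spec$si_low, n, m)
  two <- !is.null(spec$si_high)
  if (two) {
    if (spec$edge_geometry == "vertical-step") {
      template[, (floor(m / 2) + 1L):m] <- spec$si_high
    } else {
      r0 <- (n + 1) / 2; c0 <- (m + 1) / 2
      rad <- min(n, m) / 4
      inside <- (row(template) - r0)^2 + (col(template) - c0)^2 <= rad^2
      template[inside] <- spec$si_high
    }
  }
  if (spec$edge_blur_sigma > 0) {
    template <- conv_sep_masked(template, matrix(TRUE, n, m),
                                gaussian_kernel1d(spec$edge_blur_sigma))
  }
  if (two) {
    tol <- 0.01 * (spec$si_high - spec$si_low)
    masks <- list(low = abs(template - spec$si_low) <= tol,
                  high = abs(template - spec$si_high) <= tol)
  } else {
    masks <- list(tissue = matrix(TRUE, n, m))
  }
  noise <- matrix(0, n, m)
  sigma_eff <- 0
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    w <- matrix(stats::rnorm(n * m), n, m)
    if (spec$noise_corr_sigma > 0) {
      w <- conv_sep_masked(w, matrix(TRUE, n, m),
                           gaussian_kernel1d(spec$noise_corr_sigma))
    }
    noise <- w * (spec$noise_sigma / stats::sd(w))
    sigma_eff <- stats::sd(noise)
  }
  px <- template + noise
  if (spec$quantize) px <- round(px)
  structure(list(spec = spec,
                 image = roi_image(px),
                 tissue_masks = masks,
                 true_noise_sigma_effective = sigma_eff),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  realized noise STD %.6g; tissue masks: %s\n",
              x$true_noise_sigma_effective,
              paste(sprintf("%s (%d px)", names(x$tissue_masks),
                            vapply(x$tissue_masks, sum, 0L)),
                    collapse = ", ")))
  invisible(x)
}

#' Default validation grid of phantom specs
#'
#' The fixture grid used for estimator validation: every combination of
#' noise magnitude `sigma` in {0, 5, 10, 20, 40}, correlation length in
#' {0, 1.5} pixels and boundary blur in {0, 1, 2} pixels (30 phantoms),
#' on a 256 x 256 two-tissue vertical-step layout with plateaus at 50 and
#' 150 HU. Seeds are fixed, derived from `base_seed`.
#'
#' @param sigmas,corrs,blurs numeric grids of noise STD, correlation
#'   length and edge blur.
#' @param si_low,si_high plateau intensities.
#' @param shape phantom dimensions.
#' @param base_seed integer; phantom i receives seed `base_seed + i`.
#' @return List of [phantom_spec()] objects.
#' @export
default_phantom_grid <- function(sigmas = c(0, 5, 10, 20, 40),
                                 corrs = c(0, 1.5), blurs = c(0, 1, 2),
                                 si_low = 50, si_high = 150,
                                 shape = c(256, 256), base_seed = 101L) {
  grid <- expand.grid(sigma = sigmas, corr = corrs, blur = blurs,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    phantom_spec(shape = shape, si_low = si_low, si_high = si_high,
                 noise_sigma = grid$sigma[i],
                 noise_corr_sigma = grid$corr[i],
                 edge_blur_sigma = grid$blur[i],
                 edge_geometry = "vertical-step",
                 seed = as.integer(base_seed) + i)
  })
}

#' Generate a reproducible suite of phantoms
#'
#' @param grid non-empty list of [phantom_spec()] objects, e.g. from
#'   [default_phantom_grid()].
#' @return List of `phantom_truth` objects, one per spec, in grid order.
#' @export
phantom_suite <- function(grid = default_phantom_grid()) {
  if (!is.list(grid) || !length(grid))
    stop("`grid` must be a non-empty list of phantom_spec objects",
         call. = FALSE)
  lapply(grid, generate_phantom)
}

#' Write / read phantoms as portable text arrays
#'
#' `write_phantom()` stores the pixel grid as a plain CSV array (no
#' header) next to a JSON sidecar holding the full spec and the realized
#' noise magnitude. `read_array()` reads such an array (or any headerless
#' numeric CSV/TSV grid) back into an [roi_image].
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param name file stem; defaults to `"phantom"`.
#' @return `write_phantom()` returns the array path invisibly;
#'   `read_array()` returns an [roi_image].
#' @export
write_phantom <- function(truth, dir, name = "phantom") {
  stopifnot(inherits(truth, "phantom_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  array_path <- file.path(dir, paste0(name, ".csv"))
  utils::write.table(truth$image$pixels, array_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- c(unclass(truth$spec),
            list(true_noise_sigma_effective =
                   truth$true_noise_sigma_effective))
  side$si_high <- side$si_high %||% NA
  jsonlite::write_json(side, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(array_path)
}

#' @rdname write_phantom
#' @param path path of a headerless numeric CSV (or whitespace-separated)
#'   array file.
#' @param pixel_spacing physical length per pixel for the returned image.
#' @export
read_array <- function(path, pixel_spacing = 1) {
  if (!file.exists(path)) stop("array file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  M <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  roi_image(M, pixel_spacing = pixel_spacing)
}
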