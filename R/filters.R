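#' Mask-aware Gaussian lowpass filter
#'
#' Smooths an ROI image with an isotropic Gaussian kernel. The kernel
#' weights are renormalized over the valid pixels, so pixels outside the
#' mask contribute nothing and a constant image stays exactly constant up
#' to the ROI border (no edge darkening).
#'
#' @param image an [roi_image] (or plain numeric matrix).
#' @param lp_sigma Gaussian standard deviation in pixels; must be > 0.
#'   Default 2.
#' @return An [roi_image] with the smoothed intensities and the input mask.
#' @seealso [highpass_residual()], [std_filter()]
#' @export
lowpass <- function(image, lp_sigma = 2) {
  image <- as_roi_image(image)
  if (!is.numeric(lp_sigma) || length(lp_sigma) != 1L || lp_sigma <= 0)
    stop("`lp_sigma` must be a positive scalar", call. = FALSE)
  g <- gaussian_kernel1d(lp_sigma)
  sm <- conv_sep_masked(image$pixels, image$mask, g)
  out <- image$pixels
  out[image$mask] <- sm[image$mask]
  roi_image(out, image$mask, image$pixel_spacing)
}

#' Highpass residual (noise isolation)
#'
#' Subtracts a Gaussian lowpass copy from the original image, isolating the
#' high, predominantly noise-related spatial frequencies. For a smooth
#' underlying signal the residual has approximately zero mean over the ROI
#' interior, and for white noise of standard deviation `sigma` its standard
#' deviation is `sigma * highpass_attenuation(lp_sigma)`.
#'
#' @inheritParams lowpass
#' @return An [roi_image] holding the residual.
#' @export
highpass_residual <- function(image, lp_sigma = 2) {
  image <- as_roi_image(image)
  lp <- lowpass(image, lp_sigma)
  res <- image$pixels - lp$pixels
  res[!image$mask] <- 0
  roi_image(res, image$mask, image$pixel_spacing)
}

#' Noise attenuation factor of the highpass residual
#'
#' Standard-deviation attenuation applied to a stationary noise field by the
#' residual operator (identity minus Gaussian lowpass), computed from the
#' discrete kernel coefficients. For white noise the factor is
#' `sqrt(1 - 2 g0 + sum(g^2))` with `g` the 2D kernel and `g0` its center
#' weight. For noise pre-correlated with a Gaussian of width
#' `corr_sigma` the factor is the L2 norm of the composed kernel
#' relative to the norm of the correlation kernel (the noise field is
#' rescaled to its target magnitude after correlation).
#'
#' @param lp_sigma lowpass Gaussian width in pixels.
#' @param corr_sigma Gaussian correlation length of the noise field in
#'   pixels; 0 (default) means white noise.
#' @return Dimensionless attenuation factor in (0, 1).
#' @export
highpass_attenuation <- function(lp_sigma = 2, corr_sigma = 0) {
  g1 <- gaussian_kernel1d(lp_sigma)
  if (corr_sigma <= 0) {
    g0 <- g1[(length(g1) + 1L) / 2L]^2
    return(sqrt(1 - 2 * g0 + sum(g1^2)^2))
  }
  # composed 2D kernel K = delta*H - G*H with separable factors:
  # G*H = outer(conv(g1,h1), conv(g1,h1)); delta*H = H centered in K's support
  h1 <- gaussian_kernel1d(corr_sigma)
  GH <- conv1_full(g1, h1)
  padGH <- (length(GH) - length(h1)) / 2L
  H2big <- matrix(0, length(GH), length(GH))
  idx <- (padGH + 1L):(padGH + length(h1))
  H2big[idx, idx] <- outer(h1, h1)
  K <- H2big - outer(GH, GH)
  sqrt(sum(K^2) / sum(h1^2)^2)
}

#' @noRd
conv1_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- rep(0, n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Local standard-deviation filter (noise map)
#'
#' Applies a standard-deviation filter to a highpass residual: at every
#' pixel whose full circular window of radius `window_radius` lies inside
#' the valid mask, the sample standard deviation (denominator n - 1) of the
#' residual values in that window is recorded. Pixels whose window touches
#' the mask border or the grid border are undefined (`NA`).
#'
#' @param residual an [roi_image], normally the output of
#'   [highpass_residual()].
#' @param window_radius circular window radius in pixels (>= 1). Pixels with
#'   center distance `<= window_radius` belong to the window. Default 3.
#' @return A `noise_map` object.
#' @export
std_filter <- function(residual, window_radius = 3) {
  residual <- as_roi_image(residual)
  if (!is.numeric(window_radius) || length(window_radius) != 1L ||
      window_radius < 1)
    stop("`window_radius` must be >= 1", call. = FALSE)
  off <- disk_offsets(window_radius)
  nwin <- nrow(off)
  V <- matrix(as.numeric(residual$mask), nrow(residual$pixels))
  X <- residual$pixels * V
  X[!is.finite(X)] <- 0
  cnt <- window_sum(V, off)
  s1 <- window_sum(X, off)
  s2 <- window_sum(X^2, off)
  defined <- abs(cnt - nwin) < 0.5
  if (!any(defined))
    stop("ROI too small for noise estimation (no full window of radius ",
         window_radius, " fits inside the mask)", call. = FALSE)
  lstd <- matrix(NA_real_, nrow(X), ncol(X))
  vr <- (s2[defined] - s1[defined]^2 / nwin) / (nwin - 1)
  lstd[defined] <- sqrt(pmax(vr, 0))
  new_noise_map(lstd, window_radius, residual)
}

#' Minimum-noise estimate (STDmin)
#'
#' Mean of the `k_lowest` lowest circular-region averages of a noise map.
#' Candidate regions are circles of diameter `region_diameter_px` centered
#' at every pixel whose circle fits entirely inside `region_mask` and the
#' defined part of the noise map; each candidate's score is the mean local
#' standard deviation over its circle. The estimate is the mean of the
#' `k_lowest` smallest scores, with deterministic ties: candidates are
#' ordered by (score, row, column) and the first `k_lowest` are averaged.
#'
#' @param noise_map a `noise_map` from [std_filter()].
#' @param region_mask logical matrix selecting the tissue region; defaults
#'   to the source image mask.
#' @param region_diameter_px candidate circle diameter in pixels
#'   (default 12).
#' @param k_lowest number of lowest-scoring candidates averaged (default 5).
#' @return The STDmin estimate (scalar, intensity units).
#' @export
std_min <- function(noise_map, region_mask = NULL, region_diameter_px = 12,
                    k_lowest = 5) {
  if (!inherits(noise_map, "noise_map"))
    stop("`noise_map` must come from std_filter()", call. = FALSE)
  L <- noise_map$local_std
  if (is.null(region_mask)) region_mask <- noise_map$source$mask
  stopifnot(identical(dim(region_mask), dim(L)))
  if (region_diameter_px < 1) stop("`region_diameter_px` must be >= 1",
                                   call. = FALSE)
  off <- disk_offsets(region_diameter_px / 2)
  ncirc <- nrow(off)
  D <- matrix(as.numeric(is.finite(L) & region_mask), nrow(L))
  X <- L * D
  X[!is.finite(X)] <- 0
  cnt <- window_sum(D, off)
  valid <- abs(cnt - ncirc) < 0.5
  nc <- sum(valid)
  if (nc < k_lowest)
    stop(sprintf(paste0("fewer than %d candidate circles of diameter %g fit",
                        " inside the region (%d found); enlarge the region"),
                 k_lowest, region_diameter_px, nc), call. = FALSE)
  score <- window_sum(X, off)[valid] / ncirc
  rows <- row(L)[valid]
  cols <- col(L)[valid]
  ord <- order(score, rows, cols)
  mean(score[ord[seq_len(k_lowest)]])
}
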