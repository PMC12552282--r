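#' Objective image-quality assessment of an ROI
#'
#' Runs the full reference-free image-quality pipeline on a region of
#' interest: a Gaussian lowpass copy is subtracted from the image to
#' isolate the noise-dominated high frequencies, a circular
#' standard-deviation filter turns the residual into a noise map, and the
#' minimum-noise estimate STDmin is the mean of the five lowest
#' circular-region averages of that map. The grey-value histogram decides
#' whether the ROI holds one or two tissues; per tissue, the modal signal
#' intensity SI, SNR = SI / STDmin and the grey-value entropy are
#' computed, and for a two-tissue ROI additionally the contrast
#' CNR = (SI_high - SI_low) / mean(STDmin) and the 10-90% edge-transition
#' sharpness.
#'
#' A unimodal ROI always yields a single-tissue result; a two-tissue
#' result is only produced when the histogram is genuinely bimodal (two
#' modes at least two bins apart with a strict valley between them).
#' A noise estimate of exactly zero (e.g. a noiseless synthetic image)
#' raises an error rather than reporting an infinite SNR.
#'
#' @param image an [roi_image] or numeric matrix.
#' @param lp_sigma Gaussian lowpass width in pixels (default 2).
#' @param window_radius STD-filter circular window radius in pixels
#'   (default 3).
#' @param bin_width histogram bin width in intensity units (default 20).
#' @param region_diameter_px diameter of the sliding circles used for
#'   STDmin (default 12).
#' @param k_lowest number of lowest circle scores averaged into STDmin
#'   (default 5).
#' @param si_anchor histogram anchoring for the modal SI, see [modal_si()].
#' @return An object of class `roi_quality`; subclass `tissue_quality` for
#'   a one-tissue ROI or `two_tissue_quality` for a two-tissue ROI. Use
#'   `print()`, `summary()` and `as.data.frame()` to inspect it.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(128, 128), si_low = 50,
#'                                     si_high = 150, noise_sigma = 10,
#'                                     seed = 7))
#' q <- assess_roi(ph$image)
#' q
#' as.data.frame(q)
#' @export
assess_roi <- function(image, lp_sigma = 2, window_radius = 3,
                       bin_width = 20, region_diameter_px = 12,
                       k_lowest = 5,
                       si_anchor = c("sliding", "min", "origin")) {
  image <- as_roi_image(image)
  si_anchor <- match.arg(si_anchor)
  res <- highpass_residual(image, lp_sigma)
  nmap <- std_filter(res, window_radius)
  split <- tryCatch(split_two_tissues(image, bin_width),
                    ctiq_unimodal_error = function(e) NULL)
  pars <- list(lp_sigma = lp_sigma, window_radius = window_radius,
               bin_width = bin_width, region_diameter_px = region_diameter_px,
               k_lowest = k_lowest, si_anchor = si_anchor)

  one_tissue <- function(mask, label) {
    sm <- std_min(nmap, mask, region_diameter_px, k_lowest)
    si <- modal_si(image, mask, bin_width, si_anchor)
    list(tissue = label,
         si = si,
         std_min = sm,
         snr = snr(si, sm),
         entropy_bits = grey_entropy(image, mask, bin_width),
         n_pixels = sum(mask & image$mask))
  }

  if (is.null(split)) {
    out <- one_tissue(image$mask, "tissue")
    out$parameters <- pars
    class(out) <- c("tissue_quality", "roi_quality")
    return(out)
  }
  part <- coherent_partition(image, split$mask_low, split$mask_high)
  low <- one_tissue(part$low, "low")
  high <- one_tissue(part$high, "high")
  if (high$si < low$si) { tmp <- low; low <- high; high <- tmp
                          low$tissue <- "low"; high$tissue <- "high" }
  out <- list(
    low = low, high = high,
    delta_si = high$si - low$si,
    mean_std_min = (low$std_min + high$std_min) / 2,
    cnr = cnr(low$si, high$si, low$std_min, high$std_min),
    sharpness_width = edge_sharpness(image, split$mask_low,
                                     split$mask_high),
    threshold = split$threshold,
    parameters = pars)
  class(out) <- c("two_tissue_quality", "roi_quality")
  out
}

# Spatially coherent version of the two-tissue split: at high noise the
# pixelwise thresholded masks are salt-and-pepper (individual pixels of one
# tissue cross the threshold), so per-tissue regions are taken from the
# Gaussian-smoothed tissue indicator thresholded at 0.5.
#' @noRd
coherent_partition <- function(image, mask_low, mask_high, sigma = 2) {
  roi <- (mask_low | mask_high) & image$mask
  ind <- matrix(0, nrow(image$pixels), ncol(image$pixels))
  ind[mask_high] <- 1
  G <- conv_sep_masked(ind, roi, gaussian_kernel1d(sigma))
  high <- roi & is.finite(G) & G >= 0.5
  list(low = roi & !high, high = high)
}

#' @export
print.tissue_quality <- function(x, digits = 4, ...) {
  cat("Objective image quality - single tissue ROI\n")
  cat(sprintf("  SI (modal)  : %.*g\n", digits, x$si))
  cat(sprintf("  STDmin      : %.*g\n", digits, x$std_min))
  cat(sprintf("  SNR         : %.*g\n", digits, x$snr))
  cat(sprintf("  entropy     : %.*g bits\n", digits, x$entropy_bits))
  cat(sprintf("  pixels      : %d\n", x$n_pixels))
  invisible(x)
}

#' @export
print.two_tissue_quality <- function(x, digits = 4, ...) {
  cat("Objective image quality - two tissue ROI\n")
  cat(sprintf("  threshold   : %.*g\n", digits, x$threshold))
  for (t in list(x$low, x$high)) {
    cat(sprintf("  [%s] SI %.*g, STDmin %.*g, SNR %.*g, entropy %.*g bits\n",
                t$tissue, digits, t$si, digits, t$std_min, digits, t$snr,
                digits, t$entropy_bits))
  }
  cat(sprintf("  delta SI    : %.*g\n", digits, x$delta_si))
  cat(sprintf("  CNR         : %.*g\n", digits, x$cnr))
  cat(sprintf("  sharpness   : %.*g (10-90%% width)\n", digits,
              x$sharpness_width))
  invisible(x)
}

#' @export
summary.roi_quality <- function(object, ...) {
  print(object, ...)
  cat("parameters:",
      paste(names(object$parameters),
            unlist(object$parameters, use.names = FALSE),
            sep = "=", collapse = ", "), "\n")
  invisible(object)
}

#' Tabular form of an ROI quality result
#'
#' One row per tissue with columns `tissue`, `si`, `std_min`, `snr`,
#' `entropy_bits`, `n_pixels` and, for two-tissue ROIs, the shared
#' `delta_si`, `cnr` and `sharpness_width` repeated on both rows.
#'
#' @param x an object returned by [assess_roi()].
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.roi_quality <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  row_of <- function(t) data.frame(tissue = t$tissue, si = t$si,
                                   std_min = t$std_min, snr = t$snr,
                                   entropy_bits = t$entropy_bits,
                                   n_pixels = t$n_pixels)
  if (inherits(x, "two_tissue_quality")) {
    df <- rbind(row_of(x$low), row_of(x$high))
    df$delta_si <- x$delta_si
    df$cnr <- x$cnr
    df$sharpness_width <- x$sharpness_width
  } else {
    df <- row_of(x)
    df$delta_si <- NA_real_
    df$cnr <- NA_real_
    df$sharpness_width <- NA_real_
  }
  df
}
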