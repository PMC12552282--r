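#' Modal signal intensity from a fixed-width histogram
#'
#' Estimates a tissue's signal intensity (SI) as the modal value of its
#' grey-value histogram with a fixed bin width (default 20 HU). The default
#' `"sliding"` anchoring places the bin at the intensity offset that
#' maximizes its occupancy (a maximal-count sliding window of width
#' `bin_width`), which centers the modal bin on the densest part of the
#' histogram; SI is the mean of the pixel values falling inside that bin,
#' which avoids half-bin quantization bias. Fixed anchorings at the in-mask
#' minimum or at integer multiples of `bin_width` are available for
#' comparison. Ties between equally populated bins are broken toward the
#' bin whose lower edge is closest to the overall mean intensity.
#'
#' @param image an [roi_image] or numeric matrix.
#' @param tissue_mask logical matrix selecting the tissue pixels; defaults
#'   to the image mask.
#' @param bin_width histogram bin width in intensity units (default 20).
#' @param anchor `"sliding"` (default), `"min"` or `"origin"` bin anchoring.
#' @return Modal signal intensity (scalar).
#' @export
modal_si <- function(image, tissue_mask = NULL, bin_width = 20,
                     anchor = c("sliding", "min", "origin")) {
  image <- as_roi_image(image)
  anchor <- match.arg(anchor)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (is.null(tissue_mask)) tissue_mask <- image$mask
  tissue_mask <- tissue_mask & image$mask
  x <- image$pixels[tissue_mask]
  if (!length(x)) stop("empty tissue mask", call. = FALSE)
  if (anchor == "sliding") {
    xs <- sort(x)
    # count of values in the half-open window [xs[i], xs[i] + bin_width)
    n_le <- findInterval(xs + bin_width, xs)           # values <= left + bw
    n_eq <- n_le - findInterval(xs + bin_width, xs, left.open = TRUE)
    cnt <- n_le - n_eq - seq_along(xs) + 1L
    best <- max(cnt)
    cand <- which(cnt == best)
    if (length(cand) > 1L) {
      d <- abs(xs[cand] - mean(x))
      cand <- cand[order(d, xs[cand])]
    }
    i <- cand[1L]
    return(mean(xs[i:(i + best - 1L)]))
  }
  a <- if (anchor == "min") min(x) else bin_width * floor(min(x) / bin_width)
  idx <- floor((x - a) / bin_width)
  nb <- max(idx) + 1L
  idx[idx >= nb] <- nb - 1L
  cnt <- tabulate(idx + 1L, nbins = nb)
  best <- max(cnt)
  cand <- which(cnt == best) - 1L
  if (length(cand) > 1L) {
    d <- abs((a + bin_width * cand) - mean(x))
    cand <- cand[order(d, cand)]
  }
  mean(x[idx == cand[1L]])
}

#' Histogram-based two-tissue split
#'
#' Splits a bimodal ROI into a low-intensity and a high-intensity tissue
#' region. The grey-value histogram (bin width `bin_width`, anchored at the
#' in-ROI minimum) is scanned for its most populated bin and the most
#' populated bin at least two bins away (the low-range and high-range
#' modes). The threshold is the center of the least populated bin between
#' the two modes (the valley), or the midpoint of the two mode centers if
#' the valley is tied. The split is rejected as unimodal unless the valley
#' count is strictly below both mode counts.
#'
#' @inheritParams modal_si
#' @return A list with `mask_low`, `mask_high` (logical matrices
#'   partitioning the ROI) and `threshold` (intensity).
#' @export
split_two_tissues <- function(image, bin_width = 20) {
  image <- as_roi_image(image)
  x <- image$pixels[image$mask]
  a <- min(x)
  rng <- max(x) - a
  fail <- function() {
    stop(errorCondition("two-tissue split requires bimodal ROI",
                        class = c("ctiq_unimodal_error", "error")))
  }
  if (rng <= 0) fail()
  nb <- as.integer(ceiling(rng / bin_width))
  idx <- pmin(floor((x - a) / bin_width), nb - 1L)
  cnt <- tabulate(idx + 1L, nbins = nb)
  if (nb < 3L) fail()
  m1 <- which.max(cnt) - 1L
  far <- which(abs(seq_len(nb) - 1L - m1) >= 2L) - 1L
  if (!length(far) || max(cnt[far + 1L]) == 0L) fail()
  m2 <- far[which.max(cnt[far + 1L])]
  lo <- min(m1, m2); hi <- max(m1, m2)
  between <- (lo + 1L):(hi - 1L)
  vcnt <- cnt[between + 1L]
  if (min(vcnt) >= min(cnt[m1 + 1L], cnt[m2 + 1L])) fail()
  vmin <- between[vcnt == min(vcnt)]
  if (length(vmin) == 1L) {
    threshold <- a + bin_width * (vmin + 0.5)
  } else {
    threshold <- a + bin_width * ((lo + 0.5) + (hi + 0.5)) / 2
  }
  mask_low <- image$mask & image$pixels < threshold
  mask_high <- image$mask & image$pixels >= threshold
  list(mask_low = mask_low, mask_high = mask_high, threshold = threshold)
}

#' Signal-to-noise ratio
#'
#' SNR of a tissue: the quotient of its modal signal intensity and its
#' minimum-noise estimate, `SNR = SI / STDmin`.
#'
#' @param si modal signal intensity.
#' @param std_min minimum-noise estimate; must be strictly positive.
#' @return Dimensionless SNR.
#' @export
snr <- function(si, std_min) {
  if (!is.finite(std_min) || std_min <= 0)
    stop("zero noise estimate: SNR is undefined when STDmin is 0",
         call. = FALSE)
  si / std_min
}

#' Contrast-to-noise ratio
#'
#' CNR between two tissues: the difference of the two modal signal
#' intensities divided by the mean of both minimum-noise estimates,
#' `CNR = (SI_high - SI_low) / mean(STDmin_low, STDmin_high)`.
#'
#' @param si_low,si_high modal signal intensities of the low- and
#'   high-intensity tissue (callers order them so the result is >= 0).
#' @param std_min_low,std_min_high per-tissue minimum-noise estimates.
#' @return Dimensionless CNR.
#' @export
cnr <- function(si_low, si_high, std_min_low, std_min_high) {
  m <- (std_min_low + std_min_high) / 2
  if (!is.finite(m) || m <= 0)
    stop("zero noise estimate: CNR is undefined when both STDmin are 0",
         call. = FALSE)
  (si_high - si_low) / m
}

#' Grey-value entropy of a tissue region
#'
#' Shannon entropy (base 2) of the normalized grey-value histogram over the
#' tissue mask, with fixed-width bins anchored at the in-mask minimum.
#' Empty bins contribute zero.
#'
#' @inheritParams modal_si
#' @return Entropy in bits (>= 0).
#' @export
grey_entropy <- function(image, tissue_mask = NULL, bin_width = 20) {
  image <- as_roi_image(image)
  if (is.null(tissue_mask)) tissue_mask <- image$mask
  tissue_mask <- tissue_mask & image$mask
  x <- image$pixels[tissue_mask]
  if (!length(x)) stop("empty tissue mask", call. = FALSE)
  a <- min(x)
  nb <- max(1L, as.integer(ceiling((max(x) - a) / bin_width)))
  idx <- pmin(floor((x - a) / bin_width), nb - 1L)
  p <- tabulate(idx + 1L, nbins = nb) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Edge-transition sharpness (10-90% width)
#'
#' Measures the sharpness of the transition between two tissues as the
#' 10-90% transition distance of an error-function edge model. Intensity
#' profiles are extracted along the boundary normal (normals from the
#' Gaussian-smoothed gradient of the tissue indicator), aligned at their
#' 50% crossing, and the pooled profile is fitted with
#' `I(t) = A + (B - A) * pnorm((t - mu) / s)`; the returned width is
#' `2 * qnorm(0.9) * s` (about `2.563 * s`) in pixel-spacing units.
#'
#' @param image an [roi_image].
#' @param mask_low,mask_high logical matrices of the two tissue regions,
#'   e.g. from [split_two_tissues()].
#' @param profile_halfwidth half length of the sampled profiles in pixels
#'   (default 8).
#' @param step profile sampling step in pixels (default 0.5).
#' @param max_profiles upper bound on the number of boundary profiles used
#'   (deterministic thinning; default 200).
#' @return 10-90% transition width (length units).
#' @export
edge_sharpness <- function(image, mask_low, mask_high,
                           profile_halfwidth = 8, step = 0.5,
                           max_profiles = 200) {
  image <- as_roi_image(image)
  M <- image$pixels
  stopifnot(identical(dim(mask_low), dim(M)),
            identical(dim(mask_high), dim(M)))
  n <- nrow(M); m <- ncol(M)
  roi <- mask_low | mask_high
  ind <- matrix(0, n, m)
  ind[mask_high] <- 1
  # Smoothed tissue indicator, extrapolated across any unassigned band
  # between the two masks by the mask-aware normalization; thresholding it
  # at 0.5 partitions the grid so the interface is well defined even when
  # the masks exclude a blurred boundary band.
  G <- conv_sep_masked(ind, roi, gaussian_kernel1d(2))
  P <- is.finite(G) & G >= 0.5          # "high" side of the partition
  Pdef <- is.finite(G)
  shift_eq <- function(A, dr, dc) {
    B <- matrix(FALSE, n, m)
    rs <- max(1, 1 + dr):min(n, n + dr)
    cs <- max(1, 1 + dc):min(m, m + dc)
    B[rs, cs] <- A[rs - dr, cs - dc]
    B
  }
  lowP <- Pdef & !P
  nb_low <- shift_eq(lowP, 1, 0) | shift_eq(lowP, -1, 0) |
    shift_eq(lowP, 0, 1) | shift_eq(lowP, 0, -1)
  nb_high <- shift_eq(P, 1, 0) | shift_eq(P, -1, 0) |
    shift_eq(P, 0, 1) | shift_eq(P, 0, -1)
  boundary <- (lowP & nb_high) | (P & nb_low)
  if (sum(boundary) < 8)
    stop("insufficient boundary for sharpness (need >= 8 boundary pixels)",
         call. = FALSE)
  bidx <- which(boundary, arr.ind = TRUE)
  bidx <- bidx[order(bidx[, 1L], bidx[, 2L]), , drop = FALSE]
  if (nrow(bidx) > max_profiles) {
    keep <- unique(round(seq(1, nrow(bidx), length.out = max_profiles)))
    bidx <- bidx[keep, , drop = FALSE]
  }
  ts <- seq(-profile_halfwidth, profile_halfwidth, by = step)
  tt_all <- c(); val_all <- c()
  for (p in seq_len(nrow(bidx))) {
    r <- bidx[p, 1L]; cc <- bidx[p, 2L]
    gr <- if (r > 1 && r < n && is.finite(G[r - 1, cc]) &&
              is.finite(G[r + 1, cc])) (G[r + 1, cc] - G[r - 1, cc]) / 2
          else NA_real_
    gc <- if (cc > 1 && cc < m && is.finite(G[r, cc - 1]) &&
              is.finite(G[r, cc + 1])) (G[r, cc + 1] - G[r, cc - 1]) / 2
          else NA_real_
    if (!is.finite(gr) || !is.finite(gc)) next
    nrm <- sqrt(gr^2 + gc^2)
    if (nrm < 1e-8) next
    prof <- bilinear(M, r + ts * gr / nrm, cc + ts * gc / nrm)
    if (any(!is.finite(prof))) next
    # align at the 50% crossing nearest to the boundary pixel
    k <- max(3L, as.integer(length(ts) / 8))
    lo <- mean(prof[seq_len(k)]); hi <- mean(prof[seq(length(prof) - k + 1,
                                                      length(prof))])
    if (hi - lo < 1e-9 * (abs(hi) + abs(lo) + 1)) next
    mid <- (lo + hi) / 2
    s <- prof - mid
    cross <- which(s[-length(s)] * s[-1L] <= 0 & s[-length(s)] != s[-1L])
    if (!length(cross)) next
    t0s <- vapply(cross, function(i) {
      ts[i] + step * s[i] / (s[i] - s[i + 1L])
    }, numeric(1))
    t0 <- t0s[which.min(abs(t0s))]
    tt_all <- c(tt_all, ts - t0)
    val_all <- c(val_all, prof)
  }
  if (length(val_all) < 4 * length(ts))
    stop("insufficient boundary for sharpness (too few usable profiles)",
         call. = FALSE)
  fit <- fit_erf_edge(tt_all, val_all)
  2 * stats::qnorm(0.9) * fit$sigma * image$pixel_spacing
}

# Least-squares erf-edge fit with the amplitude profiled out linearly.
#' @noRd
fit_erf_edge <- function(t, y) {
  sse <- function(par) {
    mu <- par[1L]; sig <- exp(par[2L])
    z <- stats::pnorm((t - mu) / sig)
    X <- cbind(1, z)
    b <- tryCatch(stats::lsfit(X, y, intercept = FALSE)$coefficients,
                  error = function(e) NULL)
    if (is.null(b)) return(Inf)
    sum((y - X %*% b)^2)
  }
  # coarse init over plausible widths, then simplex refinement
  inits <- expand.grid(mu = c(-1, 0, 1), lsig = log(c(0.3, 1, 2, 4)))
  vals <- apply(inits, 1L, sse)
  p0 <- as.numeric(inits[which.min(vals), ])
  opt <- stats::optim(p0, sse, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(mu = opt$par[1L], sigma = exp(opt$par[2L]), sse = opt$value)
}
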