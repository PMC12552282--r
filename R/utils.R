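# Internal numerical helpers shared across the package.

#' @keywords internal
#' @noRd
gaussian_kernel1d <- function(sigma, truncate = 4) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  g / sum(g)
}

# Band matrix B such that (B %*% M) convolves the columns of M (i.e. along
# rows/dim 1) with the symmetric kernel g, zero boundary.
#' @noRd
conv_band_matrix <- function(n, g) {
  r <- (length(g) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    B[cbind(i[ok], j[ok])] <- g[d + r + 1L]
  }
  B
}

# Separable 2D convolution with zero padding outside the grid.
#' @noRd
conv_sep <- function(M, g) {
  Br <- conv_band_matrix(nrow(M), g)
  Bc <- conv_band_matrix(ncol(M), g)
  Br %*% M %*% t(Bc)
}

# Normalized (mask-aware) Gaussian smoothing: weights are renormalized over
# the valid pixels so pixels outside `mask` contribute nothing.
#' @noRd
conv_sep_masked <- function(M, mask, g) {
  W <- matrix(as.numeric(mask), nrow(M))
  M0 <- M * W
  M0[!is.finite(M0)] <- 0
  num <- conv_sep(M0, g)
  den <- conv_sep(W, g)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

# Offsets (dr, dc) of a discrete disk: center distance <= radius.
#' @noRd
disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  d <- expand.grid(dr = seq(-r, r), dc = seq(-r, r))
  d <- d[d$dr^2 + d$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(d)
}

# Sum of M over the window defined by `offsets` at every pixel, zero padding.
#' @noRd
window_sum <- function(M, offsets) {
  n <- nrow(M); m <- ncol(M)
  r <- max(abs(offsets))
  P <- matrix(0, n + 2L * r, m + 2L * r)
  P[(r + 1L):(r + n), (r + 1L):(r + m)] <- M
  out <- matrix(0, n, m)
  for (k in seq_len(nrow(offsets))) {
    out <- out + P[(r + 1L + offsets[k, 1L]):(r + n + offsets[k, 1L]),
                   (r + 1L + offsets[k, 2L]):(r + m + offsets[k, 2L])]
  }
  out
}

# Bilinear interpolation of matrix M at fractional (row, col) positions.
# Positions whose 4-pixel support leaves the grid yield NA.
#' @noRd
bilinear <- function(M, row, col) {
  n <- nrow(M); m <- ncol(M)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & r0 + 1 <= n & c0 >= 1 & c0 + 1 <= m
  out <- rep(NA_real_, length(row))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * M[i00] +
      (1 - fr[ok]) * fc[ok] * M[i01] +
      fr[ok] * (1 - fc[ok]) * M[i10] +
      fr[ok] * fc[ok] * M[i11]
  }
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
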