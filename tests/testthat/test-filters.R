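test_that("lowpass preserves constants, also against a masked-out half plane", {
  img <- roi_image(matrix(7, 40, 40))
  expect_equal(lowpass(img, 2)$pixels, matrix(7, 40, 40), tolerance = 1e-12)

  mask <- matrix(TRUE, 40, 40); mask[, 1:20] <- FALSE
  img2 <- roi_image(matrix(7, 40, 40), mask)
  lp <- lowpass(img2, 2)
  # renormalization contract: no edge darkening at the mask border
  expect_equal(lp$pixels[mask], rep(7, sum(mask)), tolerance = 1e-12)
  expect_identical(lp$mask, mask)

  expect_error(lowpass(img, 0), "positive")
  expect_error(roi_image(matrix(1, 4, 4), matrix(FALSE, 4, 4)), "no valid")
})

test_that("an impulse is smoothed to the kernel center weight", {
  M <- matrix(0, 41, 41); M[21, 21] <- 5
  g <- ctiq:::gaussian_kernel1d(2)
  g0 <- g[(length(g) + 1) / 2]
  lp <- lowpass(roi_image(M), 2)
  expect_equal(lp$pixels[21, 21], 5 * g0^2, tolerance = 1e-12)
  # explicit discrete-kernel convolution over the whole neighbourhood
  r <- (length(g) - 1) / 2
  expect_equal(lp$pixels[(21 - r):(21 + r), (21 - r):(21 + r)],
               5 * outer(g, g), tolerance = 1e-12)
})

test_that("highpass residual vanishes on smooth signals", {
  expect_equal(highpass_residual(roi_image(matrix(3, 30, 30)), 2)$pixels,
               matrix(0, 30, 30), tolerance = 1e-12)
  ramp <- outer(seq_len(64), rep(1, 64)) * 2
  res <- highpass_residual(roi_image(ramp), 2)
  interior <- res$pixels[12:52, 12:52]
  expect_lt(max(abs(interior)), 1e-6 * diff(range(ramp)))
})

test_that("white-noise residual STD matches the kernel attenuation factor", {
  a <- highpass_attenuation(2)
  g <- ctiq:::gaussian_kernel1d(2)
  g2 <- outer(g, g)
  ctr <- (length(g) + 1) / 2
  expect_equal(a, sqrt(1 - 2 * g2[ctr, ctr] + sum(g2^2)), tolerance = 1e-12)
  expect_true(a > 0 && a < 1)

  set.seed(101)
  N <- matrix(rnorm(256 * 256, sd = 10), 256, 256)
  res <- highpass_residual(roi_image(N), 2)
  interior <- res$pixels[10:247, 10:247]
  expect_equal(sd(interior), 10 * a, tolerance = 0.03)

  # correlated noise attenuates less than white noise at the same lp_sigma
  a_corr <- highpass_attenuation(2, corr_sigma = 1.5)
  expect_true(a_corr > 0 && a_corr < a)
})

test_that("std filter: zero residual, checkerboard closed form, window geometry", {
  z <- std_filter(roi_image(matrix(0, 20, 20)), 3)
  v <- z$local_std[is.finite(z$local_std)]
  expect_true(length(v) > 0 && all(v == 0))

  cb <- outer(1:32, 1:32, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  nm <- std_filter(roi_image(cb), 3)
  off <- ctiq:::disk_offsets(3)
  n <- nrow(off)
  n_same <- sum((off[, 1] + off[, 2]) %% 2 == 0)
  # closed-form sample STD of a +/-1 multiset with n_same/n-n_same split
  mb <- (n_same - (n - n_same)) / n
  expected <- sqrt((n - n * mb^2) / (n - 1))
  vals <- nm$local_std[is.finite(nm$local_std)]
  expect_equal(unname(unique(round(vals, 12))), round(expected, 12))

  expect_error(std_filter(roi_image(matrix(1, 3, 3)), 3), "too small")
  expect_error(std_filter(roi_image(matrix(1, 9, 9)), 0.5), ">= 1")
})

test_that("std filter and std_min match brute-force enumeration exactly", {
  set.seed(7)
  for (radius in c(1, 2)) {
    M <- matrix(rnorm(24 * 24), 24, 24)
    mask <- matrix(TRUE, 24, 24)
    mask[1:4, 1:10] <- FALSE            # irregular ROI
    mask[20:24, 15] <- FALSE
    img <- roi_image(M, mask)
    nm <- std_filter(img, radius)
    expect_equal(nm$local_std, brute_std_filter(M, mask, radius),
                 tolerance = 1e-12)
    got <- std_min(nm, mask, region_diameter_px = 2 * radius + 2,
                   k_lowest = 5)
    want <- brute_std_min(nm$local_std, mask, 2 * radius + 2, 5)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("std_min selects the cold region and reports candidate shortage", {
  L <- matrix(5, 40, 40)
  L[10:25, 10:25] <- 1                   # cold patch larger than a circle
  img <- roi_image(matrix(0, 40, 40))
  nm <- std_filter(highpass_residual(img, 2), 3)
  nm$local_std <- L                      # inject the synthetic noise map
  expect_equal(std_min(nm), 1)
  # constant map returns the constant
  nm$local_std <- matrix(3, 40, 40)
  expect_equal(std_min(nm), 3)
  expect_error(std_min(nm, region_diameter_px = 60), "fewer than 5")
})

test_that("std_min is a stable fraction of the true noise level across seeds", {
  a <- highpass_attenuation(2)
  ratios <- vapply(1:20, function(s) {
    ph <- generate_phantom(phantom_spec(shape = c(128, 128), si_low = 0,
                                        noise_sigma = 10, seed = 3000 + s))
    nm <- std_filter(highpass_residual(ph$image, 2), 3)
    sm <- std_min(nm)
    # order-statistic bound: mean of the five lowest <= spatial mean
    expect_lte(sm, mean(nm$local_std[is.finite(nm$local_std)]))
    sm / (10 * a)
  }, numeric(1))
  expect_lt(max(abs(ratios / mean(ratios) - 1)), 0.10)
})
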