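test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec(shape = c(0, 10), si_low = 50), "positive")
  expect_error(phantom_spec(shape = c(-4, 10), si_low = 50), "positive")
  expect_error(phantom_spec(si_low = 50, si_high = 50), "exceed")
  expect_error(phantom_spec(si_low = 50, si_high = 40), "exceed")
  expect_error(phantom_spec(si_high = 100), "si_low")
  expect_error(phantom_spec(si_low = 50, noise_sigma = -1), ">= 0")
  expect_error(phantom_spec(si_low = 50, edge_blur_sigma = -2), ">= 0")
  expect_s3_class(phantom_spec(si_low = 50), "phantom_spec")
})

test_that("noiseless phantoms reproduce their tissue levels exactly", {
  one <- generate_phantom(phantom_spec(shape = c(32, 32), si_low = 68))
  expect_true(all(one$image$pixels == 68))
  expect_identical(one$true_noise_sigma_effective, 0)

  step <- generate_phantom(phantom_spec(shape = c(32, 48), si_low = 50,
                                        si_high = 150))
  expect_setequal(unique(as.vector(step$image$pixels)), c(50, 150))
  expect_true(all(step$image$pixels[step$tissue_masks$low] == 50))
  expect_true(all(step$image$pixels[step$tissue_masks$high] == 150))
  # with zero blur the two masks tile the whole grid
  expect_true(all(step$tissue_masks$low | step$tissue_masks$high))
})

test_that("realized noise STD matches the requested magnitude", {
  for (corr in c(0, 1.5)) {
    ph <- generate_phantom(phantom_spec(shape = c(256, 256), si_low = 50,
                                        si_high = 150, noise_sigma = 10,
                                        noise_corr_sigma = corr, seed = 1))
    # recorded effective STD equals the target by the rescaling step
    expect_equal(ph$true_noise_sigma_effective, 10, tolerance = 1e-10)
    # sample STD inside each tissue mask within 5% of the target
    for (msk in ph$tissue_masks) {
      expect_equal(sd(ph$image$pixels[msk]), 10, tolerance = 0.05)
    }
  }
})

test_that("phantom generation is deterministic given the spec", {
  spec <- phantom_spec(shape = c(64, 64), si_low = 50, si_high = 150,
                       noise_sigma = 20, noise_corr_sigma = 1.5,
                       edge_blur_sigma = 1, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$tissue_masks, b$tissue_masks)
})

test_that("tissue masks are disjoint and exclude only the blurred band", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 64), si_low = 50,
                                      si_high = 150, edge_blur_sigma = 2))
  expect_false(any(ph$tissue_masks$low & ph$tissue_masks$high))
  band <- !(ph$tissue_masks$low | ph$tissue_masks$high)
  tpl <- ph$image$pixels
  expect_true(all(abs(tpl[band] - 50) > 1 & abs(tpl[band] - 150) > 1))
  # away from the band the template sits on its plateaus (1% of delta SI)
  expect_true(all(abs(tpl[ph$tissue_masks$low] - 50) <= 1))
  expect_true(all(abs(tpl[ph$tissue_masks$high] - 150) <= 1))
})

test_that("integer quantization is available but off by default", {
  sp <- phantom_spec(shape = c(32, 32), si_low = 50, si_high = 150,
                     noise_sigma = 10, seed = 3)
  ph <- generate_phantom(sp)
  expect_true(any(ph$image$pixels != round(ph$image$pixels)))
  spq <- phantom_spec(shape = c(32, 32), si_low = 50, si_high = 150,
                      noise_sigma = 10, seed = 3, quantize = TRUE)
  phq <- generate_phantom(spq)
  expect_true(all(phq$image$pixels == round(phq$image$pixels)))
  expect_equal(phq$image$pixels, round(ph$image$pixels))
})

test_that("the default validation grid enumerates 30 phantoms", {
  grid <- default_phantom_grid()
  expect_length(grid, 5 * 2 * 3)
  sig <- vapply(grid, function(s) s$noise_sigma, numeric(1))
  corr <- vapply(grid, function(s) s$noise_corr_sigma, numeric(1))
  blur <- vapply(grid, function(s) s$edge_blur_sigma, numeric(1))
  expect_setequal(unique(sig), c(0, 5, 10, 20, 40))
  expect_setequal(unique(corr), c(0, 1.5))
  expect_setequal(unique(blur), c(0, 1, 2))
  expect_equal(nrow(unique(data.frame(sig, corr, blur))), 30)

  expect_length(phantom_suite(grid[1]), 1)
  expect_error(phantom_suite(list()), "non-empty")
})

test_that("phantoms round-trip through portable array files", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24), si_low = 50,
                                      si_high = 150, noise_sigma = 5,
                                      seed = 9))
  dir <- withr::local_tempdir()
  path <- write_phantom(ph, dir, "p1")
  back <- read_array(path)
  expect_equal(back$pixels, ph$image$pixels, tolerance = 1e-12)
  side <- jsonlite::read_json(file.path(dir, "p1.json"),
                              simplifyVector = TRUE)
  expect_equal(side$noise_sigma, 5)
  expect_equal(side$true_noise_sigma_effective,
               ph$true_noise_sigma_effective)
})
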