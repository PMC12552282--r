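test_that("perfect agreement gives AC2 = 1, maximal discord goes negative", {
  perfect <- matrix(rep(c(1, 2, 3, 4, 5), 3), 5, 3)
  res <- gwet_ac2(perfect, categories = 1:5)
  expect_equal(res$coefficient, 1)
  expect_equal(res$benchmark, "excellent")

  disc <- rbind(c(1, 5), c(1, 5))
  g <- gwet_ac2(disc, categories = 1:5)
  expect_lt(g$coefficient, 0)
  w <- agreement_weights(5, "linear")
  oracle <- gwet_oracle(disc, 1:5, w)
  expect_equal(g$coefficient, oracle$ac2, tolerance = 1e-12)
})

test_that("a single category used throughout is perfect agreement by convention", {
  one <- matrix(3, 4, 3)
  res <- gwet_ac2(one, categories = 1:5)
  expect_equal(res$coefficient, 1)
  expect_true(res$degenerate)
  expect_equal(res$se, 0)
  res2 <- gwet_ac2(one)
  expect_equal(res2$coefficient, 1)
})

test_that("estimator matches an independent transcription to 12 decimals", {
  w <- agreement_weights(5, "linear")
  for (seed in 1:6) {
    sc <- make_ratings(10, 3, copy_prob = 0.8, seed = seed)
    got <- gwet_ac2(sc, categories = 1:5)
    want <- gwet_oracle(sc, 1:5, w)
    expect_equal(got$coefficient, want$ac2, tolerance = 1e-12)
    expect_equal(got$pa, want$pa, tolerance = 1e-12)
    expect_equal(got$pe, want$pe, tolerance = 1e-12)
    expect_equal(got$se, sqrt(want$variance), tolerance = 1e-12)
    expect_equal(got$ci_low, max(-1, want$ac2 - qnorm(0.975) *
                                   sqrt(want$variance)), tolerance = 1e-12)
  }
  # with missing cells (pairwise deletion within item)
  for (seed in 7:9) {
    sc <- make_ratings(12, 4, copy_prob = 0.7, seed = seed,
                       missing_frac = 0.15)
    if (!any(rowSums(!is.na(sc)) >= 2)) next
    got <- gwet_ac2(sc, categories = 1:5)
    want <- gwet_oracle(sc, 1:5, w)
    expect_equal(got$coefficient, want$ac2, tolerance = 1e-12)
    expect_equal(got$se, sqrt(want$variance), tolerance = 1e-12)
  }
})

test_that("identity weights with two categories reduce AC2 to AC1", {
  w <- agreement_weights(2, "identity")
  for (seed in 1:4) {
    sc <- make_ratings(15, 3, copy_prob = 0.7, seed = seed,
                       categories = 1:2)
    got <- gwet_ac2(sc, weights = "identity", categories = 1:2)
    want <- gwet_oracle(sc, 1:2, w)
    expect_equal(got$coefficient, want$ac2, tolerance = 1e-12)
  }
})

test_that("AC2 is invariant under order- and spacing-preserving relabeling", {
  sc <- make_ratings(12, 3, copy_prob = 0.75, seed = 5)
  a <- gwet_ac2(sc, categories = 1:5)
  b <- gwet_ac2(sc * 2 + 10, categories = 1:5 * 2 + 10)
  expect_equal(a$coefficient, b$coefficient, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("duplicating a perfectly agreed item does not lower AC2", {
  for (seed in 1:5) {
    sc <- make_ratings(10, 3, copy_prob = 0.6, seed = seed)
    sc[1, ] <- 3                          # unanimous item
    base <- gwet_ac2(sc, categories = 1:5)$coefficient
    dup <- gwet_ac2(rbind(sc, sc[1, ]), categories = 1:5)$coefficient
    expect_gte(dup + 1e-12, base)
  }
})

test_that("benchmarks follow the poor/good/excellent thresholds", {
  expect_equal(benchmark_agreement(0.39), "poor")
  expect_equal(benchmark_agreement(0.40), "good")
  expect_equal(benchmark_agreement(0.75), "good")
  expect_equal(benchmark_agreement(0.76), "excellent")
  expect_equal(benchmark_agreement(0.97), "excellent")
  expect_error(benchmark_agreement(1.5), "\\[-1, 1\\]")
  expect_error(benchmark_agreement(-1.2), "\\[-1, 1\\]")
})

test_that("ratings input validation and CSV readers work", {
  expect_error(gwet_ac2(matrix(1:4, 4, 1)), "2 raters")
  expect_error(gwet_ac2(matrix(1, 1, 3)), "2 items")
  expect_error(gwet_ac2(matrix(c(1, NA, NA, 2, NA, NA), 2, 3),
                        categories = 1:5), "at least 2 raters")
  expect_error(gwet_ac2(matrix(c(1, 7, 1, 7), 2), categories = 1:5),
               "outside")

  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id,rater_id,score",
               "i1,r1,1", "i1,r2,1", "i2,r1,4", "i2,r2,5",
               "i3,r1,3", "i3,r2,3"), long)
  m <- read_ratings(long)
  expect_equal(dim(m), c(3L, 2L))
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item,r1,r2", "i1,1,1", "i2,4,5", "i3,3,3"), wide)
  m2 <- read_ratings(wide)
  expect_equal(unname(m), unname(m2))
  expect_equal(gwet_ac2(m, categories = 1:5)$coefficient,
               gwet_ac2(m2, categories = 1:5)$coefficient)
})
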