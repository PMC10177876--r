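test_that("source normalization divides out the source and is invertible", {
  grid <- seq(500, 509)
  src <- toy_mean_spectrum(rep(4, 10), wavelengths = grid)
  s <- spectrum_series(grid, matrix(2, nrow = 3, ncol = 10), toy_site())
  norm <- normalize_to_source(s, src)
  expect_true(all(norm$intensities == 0.5))
  # series identical to the source mean gives all ones
  s1 <- spectrum_series(grid, matrix(4, nrow = 2, ncol = 10), toy_site())
  expect_true(all(normalize_to_source(s1, src)$intensities == 1))
  # inverse operation recovers the input to 1e-12
  set.seed(4)
  raw <- matrix(runif(30, 0.5, 2), nrow = 3)
  s2 <- spectrum_series(grid, raw, toy_site())
  back <- sweep(normalize_to_source(s2, src)$intensities, 2, src$mean, "*")
  expect_lt(max(abs(back - raw)), 1e-12)
})

test_that("below-floor source wavelengths are masked or rejected", {
  grid <- seq(500, 504)
  src <- toy_mean_spectrum(c(1, 1, 0, 1, 1), wavelengths = grid)
  s <- spectrum_series(grid, matrix(1, nrow = 2, ncol = 5), toy_site())
  masked <- normalize_to_source(s, src)
  expect_equal(masked$wavelengths, c(500, 501, 503, 504))
  expect_error(normalize_to_source(s, src, mask = FALSE), "floor")
})

test_that("confidence band follows the two-sided Student t formula", {
  # zero-variance series: band collapses onto the mean
  grid <- c(500, 501)
  s0 <- spectrum_series(grid, matrix(5, nrow = 4, ncol = 2), toy_site())
  m0 <- average_and_ci(s0)
  expect_equal(m0$ci_low, m0$mean)
  expect_equal(m0$ci_high, m0$mean)
  # n = 16, sd = 0.4: half-width = t(0.975, 15) * 0.4 / 4 = 2.1315 * 0.1
  # (t quantile from a standard table)
  set.seed(1)
  x <- rnorm(16)
  x <- 1 + 0.4 * (x - mean(x)) / sd(x)  # exact sample sd 0.4
  s <- spectrum_series(grid, cbind(x, x), toy_site())
  m <- average_and_ci(s, alpha = 0.05)
  expect_equal(m$ci_high[1] - m$mean[1], 0.21315, tolerance = 1e-4)
  expect_error(average_and_ci(s, alpha = 1.2), "alpha")
  expect_warning(average_and_ci(toy_series(n = 1)), "single measurement")
})

test_that("confidence half-widths shrink as 1/sqrt(n)", {
  grid <- c(500, 501)
  set.seed(9)
  ratios <- replicate(50, {
    small <- matrix(rnorm(16 * 2), ncol = 2)
    big <- matrix(rnorm(64 * 2), ncol = 2)
    h1 <- with(average_and_ci(spectrum_series(grid, 5 + small, toy_site())),
               mean(ci_high - mean))
    h2 <- with(average_and_ci(spectrum_series(grid, 5 + big, toy_site())),
               mean(ci_high - mean))
    h1 / h2
  })
  expect_gt(mean(ratios), 1.8)
  expect_lt(mean(ratios), 2.2)
})

test_that("normalized RMS is the coefficient of variation", {
  grid <- c(500, 501)
  s0 <- spectrum_series(grid, matrix(7, nrow = 5, ncol = 2), toy_site())
  expect_equal(normalized_rms(s0), c(0, 0))
  # two measurements 1 and 3: sd = sqrt(2), mean = 2
  s <- spectrum_series(grid, rbind(c(1, 1), c(3, 3)), toy_site())
  expect_equal(normalized_rms(s), rep(sqrt(2) / 2, 2), tolerance = 1e-12)
  # scale invariance
  s10 <- spectrum_series(grid, 10 * rbind(c(1, 1), c(3, 3)), toy_site())
  expect_equal(normalized_rms(s10), normalized_rms(s))
  # zero mean is masked with a warning
  sz <- spectrum_series(grid, rbind(c(0, 1), c(0, 3)), toy_site())
  expect_warning(out <- normalized_rms(sz), "zero mean")
  expect_true(is.na(out[1]))
})

test_that("joint maximum normalization uses the global max of the triple", {
  grid <- seq(500, 504)
  intact <- toy_mean_spectrum(c(2, 1, 1, 1, 1), wavelengths = grid)
  lesion <- toy_mean_spectrum(c(1, 5, 1, 1, 1), wavelengths = grid,
                              label = "lesion")
  ref <- toy_mean_spectrum(c(1, 1, 3, 1, 1), wavelengths = grid,
                           label = "reference")
  tri <- triple_max_normalize(intact, lesion, ref)
  expect_equal(max(tri$lesion$mean), 1)
  expect_equal(max(tri$intact$mean), 0.4)
  expect_equal(max(tri$reference$mean), 0.6)
  # pairwise ratios preserved exactly
  expect_equal(tri$intact$mean / tri$lesion$mean, intact$mean / lesion$mean)
  # joint rescaling of all three inputs changes nothing
  scale3 <- function(sp, c) toy_mean_spectrum(sp$mean * c, wavelengths = grid,
                                              label = sp$site$label)
  tri2 <- triple_max_normalize(scale3(intact, 7), scale3(lesion, 7),
                               scale3(ref, 7))
  expect_equal(tri2$intact$mean, tri$intact$mean)
  # all-zero triple is rejected
  z <- toy_mean_spectrum(rep(0, 5), wavelengths = grid)
  expect_error(triple_max_normalize(z, z, z), "not positive")
})
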