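test_that("Q profile matches direct arithmetic and its invariances", {
  grid <- c(500, 501)
  # means 1.0 vs 0.5, variances 0.04 and 0.05: Q = 0.5 / sqrt(0.09)
  a <- toy_mean_spectrum(c(1, 1), sd = sqrt(c(0.04, 0.04)),
                         wavelengths = grid)
  b <- toy_mean_spectrum(c(0.5, 0.5), sd = sqrt(c(0.05, 0.05)),
                         wavelengths = grid, label = "lesion")
  pr <- q_profile(a, b)
  expect_equal(pr$q, rep(0.5 / sqrt(0.09), 2), tolerance = 1e-12)
  # swapping the classes leaves |Q| unchanged
  expect_equal(q_profile(b, a)$q, pr$q)
  # identical class means give Q = 0 even with zero variance
  expect_equal(q_profile(a, a)$q, c(0, 0))
})

test_that("Q is invariant under common positive rescaling of both classes", {
  set.seed(2)
  grid <- seq(500, 519)
  mk <- function(label, shift) lapply(1:6, function(i)
    toy_mean_spectrum(runif(20, 1, 2) + shift, wavelengths = grid,
                      label = label, patient = sprintf("P%d", i)))
  norm <- mk("intact", 0)
  les <- mk("lesion", 0.3)
  pr1 <- q_profile(norm, les)
  scale_all <- function(sps, c) lapply(sps, function(sp)
    toy_mean_spectrum(sp$mean * c, wavelengths = grid,
                      label = sp$site$label))
  pr2 <- q_profile(scale_all(norm, 13.7), scale_all(les, 13.7))
  expect_equal(pr2$q, pr1$q, tolerance = 1e-12)
})

test_that("zero-variance wavelengths with differing means are masked", {
  grid <- c(500, 501)
  a <- toy_mean_spectrum(c(1, 1), wavelengths = grid)
  b <- toy_mean_spectrum(c(0.5, 1), sd = c(0, 0.1), wavelengths = grid,
                         label = "lesion")
  expect_warning(pr <- q_profile(a, b), "zero variance")
  expect_true(is.na(pr$q[1]))
  expect_false(is.na(pr$q[2]))
})

test_that("thresholding extracts exactly the above-threshold runs", {
  grid <- seq(360, 1000)
  q <- numeric(length(grid))
  q[grid >= 520 & grid <= 580] <- 2
  q[grid >= 850 & grid <= 950] <- 2
  pr <- structure(list(wavelengths = grid, q = q, n_norm = 5, n_les = 5),
                  class = "q_profile")
  bs <- bands_from_threshold(pr, 1)
  expect_equal(unname(bs$bands), rbind(c(520, 580), c(850, 950)))
  # below-threshold everywhere: empty set
  expect_equal(nrow(bands_from_threshold(pr, 3)$bands), 0)
  # threshold just below a run's level returns the full run
  expect_equal(unname(bands_from_threshold(pr, 1.999)$bands[1, ]),
               c(520, 580))
  # narrow runs are dropped by min_width
  q2 <- numeric(length(grid)); q2[grid == 700] <- 5
  pr2 <- structure(list(wavelengths = grid, q = q2, n_norm = 5, n_les = 5),
                   class = "q_profile")
  expect_equal(nrow(bands_from_threshold(pr2, 1, min_width = 5)$bands), 0)
  expect_error(bands_from_threshold(pr, -1), "positive")
})

test_that("bands are nested and band count non-increasing as qth rises", {
  co <- generate_cohort(cohort_spec(n_patients = 12, paired = TRUE,
                                    effect_size = 2, seed = 5))
  sp <- cohort_mean_spectra(co)
  labs <- vapply(sp, function(s) s$site$label, "")
  pr <- q_profile(sp[labs == "intact"], sp[labs == "lesion"])
  qths <- c(0.4, 0.7, 0.8, 1.0, 1.2)
  sets <- lapply(qths, function(q) bands_from_threshold(pr, q)$bands)
  for (i in seq_along(qths)[-1]) {
    hi <- sets[[i]]; lo <- sets[[i - 1]]
    expect_lte(nrow(hi), nrow(lo))
    if (nrow(hi) > 0) {
      contained <- vapply(seq_len(nrow(hi)), function(k)
        any(lo[, 1] <= hi[k, 1] & lo[, 2] >= hi[k, 2]), TRUE)
      expect_true(all(contained))
    }
  }
})

test_that("PCA pruning drops the band that carries no signal", {
  set.seed(8)
  base <- rnorm(40)
  x <- cbind(b1 = base + rnorm(40, sd = 0.01),
             b2 = 2 * base + rnorm(40, sd = 0.01),
             b3 = rnorm(40, sd = 0.1))  # pure noise, no shared signal
  feats <- gaussian_features(20, p = 3)
  feats$x <- x
  pruned <- pca_prune_bands(feats, k_drop = 1)
  expect_true(pruned$report$dropped[3])
  expect_equal(nrow(pruned$band_set$bands), 2)
  # k_drop = 0 keeps the band set unchanged
  same <- pca_prune_bands(feats, k_drop = 0)
  expect_equal(same$band_set$bands, feats$band_set$bands)
  # variance_target = 1 retains all components
  all_comp <- pca_prune_bands(feats, variance_target = 1, k_drop = 0)
  expect_equal(all_comp$n_components, 3L)
  expect_error(pca_prune_bands(feats, k_drop = 3), "k_drop")
})
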