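test_that("bootstrap reference is deterministic and respects degenerate input", {
  grid <- seq(500, 509)
  # identical measurements: the reference equals them exactly
  s0 <- spectrum_series(grid, matrix(2, nrow = 15, ncol = 10), toy_site())
  ref <- simulate_reference(s0, seed = 1)
  expect_equal(ref$mean, rep(2, 10))
  expect_equal(ref$site$label, "reference")
  # same seed identical, different seed generally different
  set.seed(20)
  s <- spectrum_series(grid, matrix(runif(150, 1, 2), nrow = 15), toy_site())
  expect_equal(simulate_reference(s, seed = 5)$mean,
               simulate_reference(s, seed = 5)$mean)
  expect_false(isTRUE(all.equal(simulate_reference(s, seed = 5)$mean,
                                simulate_reference(s, seed = 6)$mean)))
  expect_error(simulate_reference(toy_series(n = 1)), "at least 2")
})

test_that("bootstrap reference stays in the convex hull of the measurements", {
  grid <- seq(500, 509)
  set.seed(21)
  s <- spectrum_series(grid, matrix(runif(150, 1, 3), nrow = 15), toy_site())
  lo <- apply(s$intensities, 2, min)
  hi <- apply(s$intensities, 2, max)
  for (seed in 1:25) {
    ref <- simulate_reference(s, seed = seed)
    expect_true(all(ref$mean >= lo - 1e-12 & ref$mean <= hi + 1e-12))
  }
})

test_that("delta spectra are differences on the normalized triple", {
  grid <- seq(500, 509)
  intact <- toy_mean_spectrum(seq(1, 2, length.out = 10), wavelengths = grid)
  lesion <- toy_mean_spectrum(seq(1, 2, length.out = 10) + 0.1,
                              wavelengths = grid, label = "lesion")
  ref <- intact
  ref$site <- site_record("P001", "tongue", "reference")
  tri <- patient_triple(intact, lesion, ref)
  d <- build_deltas(tri)
  # reference identical to intact: zero intact delta
  expect_equal(d$delta_intact, rep(0, 10))
  # constant offset survives as a constant delta difference
  expect_equal(d$delta_lesion - d$delta_intact, rep(0.1 / 2.1, 10))
  # joint pre-scaling of the triple is absorbed by the normalization
  scl <- function(sp, c) { sp$mean <- sp$mean * c; sp$sd <- sp$sd * c
    sp$ci_low <- sp$ci_low * c; sp$ci_high <- sp$ci_high * c; sp }
  tri2 <- patient_triple(scl(intact, 9), scl(lesion, 9), scl(ref, 9))
  expect_equal(build_deltas(tri2)$delta_lesion, d$delta_lesion)
})

test_that("patient-wise classification separates constructed deltas", {
  grid <- seq(500, 900, by = 10)
  nw <- length(grid)
  mk_deltas <- function(offset, seed) {
    set.seed(seed)
    lapply(1:12, function(p) structure(
      list(wavelengths = grid,
           delta_intact = rnorm(nw, 0, 0.01),
           delta_lesion = rnorm(nw, offset, 0.01),
           patient_id = sprintf("P%02d", p)),
      class = "delta_record"))
  }
  # constant large in-range offset: perfectly separable
  expect_equal(patientwise_classify(mk_deltas(0.5, 1), c(500, 900), seed = 1),
               100)
  # indistinguishable classes: near chance
  accs <- sapply(1:8, function(s)
    patientwise_classify(mk_deltas(0, s), c(500, 900), seed = s))
  expect_lt(abs(mean(accs) - 50), 15)
  # determinism
  d <- mk_deltas(0.1, 3)
  expect_equal(patientwise_classify(d, c(500, 900), seed = 7),
               patientwise_classify(d, c(500, 900), seed = 7))
  expect_error(patientwise_classify(d, c(300, 900)), "outside the grid")
})

test_that("label permutation of deltas calibrates to chance", {
  grid <- seq(500, 900, by = 10)
  set.seed(30)
  deltas <- lapply(1:16, function(p) structure(
    list(wavelengths = grid,
         delta_intact = rnorm(length(grid), 0, 0.01),
         delta_lesion = rnorm(length(grid), 0.3, 0.01),
         patient_id = sprintf("P%02d", p)),
    class = "delta_record"))
  flip <- sample(16, 8)
  for (p in flip) {
    tmp <- deltas[[p]]$delta_intact
    deltas[[p]]$delta_intact <- deltas[[p]]$delta_lesion
    deltas[[p]]$delta_lesion <- tmp
  }
  accs <- sapply(1:6, function(s)
    patientwise_classify(deltas, c(500, 900), seed = s))
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("the default range grid reproduces the 25 configured intervals", {
  g <- default_range_grid()
  expect_equal(nrow(g), 25)
  expect_equal(unname(g[1, ]), c(500, 900))
  expect_true(any(g[, 1] == 700 & g[, 2] == 701))
  expect_equal(sort(unique(g[, 1])), c(500, 550, 600, 650, 700))
  expect_equal(sort(unique(g[, 2])), c(701, 750, 800, 850, 900))
  # range table has one row per range
  grid <- seq(500, 901)
  set.seed(31)
  deltas <- lapply(1:6, function(p) structure(
    list(wavelengths = grid,
         delta_intact = rnorm(length(grid), 0, 0.01),
         delta_lesion = rnorm(length(grid), 0.5, 0.01),
         patient_id = sprintf("P%02d", p)),
    class = "delta_record"))
  tab <- range_grid_accuracy(deltas, rbind(c(500, 900)), seed = 2)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$accuracy, 100)
})

test_that("cohort deltas pair each eligible patient's sites", {
  co <- generate_cohort(cohort_spec(n_patients = 6, paired = TRUE, seed = 40))
  d <- cohort_deltas(co, seed = 40)
  expect_length(d, 6)
  expect_setequal(names(d), sprintf("P%03d", 1:6))
  # unpaired cohorts have no eligible patients
  co2 <- generate_cohort(cohort_spec(paired = FALSE, n_intact_sites = 2,
                                     n_lesion_sites = 2, seed = 41))
  expect_error(cohort_deltas(co2), "both an intact and a lesion")
})
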