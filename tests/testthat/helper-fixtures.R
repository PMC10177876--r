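# Small in-code fixtures shared across test files.

toy_site <- function(label = "intact", patient = "P001", type = "tongue")
  site_record(patient, type, label)

# A tiny deterministic series: n measurements on a short grid.
toy_series <- function(n = 3, wavelengths = c(500, 501, 502, 503, 504),
                       base = 10, label = "intact", patient = "P001") {
  m <- outer(seq_len(n), seq_along(wavelengths),
             function(i, j) base + i + 0.1 * j)
  spectrum_series(wavelengths, m, toy_site(label, patient))
}

# Mean spectrum with prescribed mean and sd vectors.
toy_mean_spectrum <- function(mean, sd = rep(0, length(mean)),
                              wavelengths = seq(500, length.out = length(mean)),
                              n = 5, label = "intact", patient = "P001") {
  half <- 2 * sd / sqrt(n)
  mean_spectrum(wavelengths, mean, sd, mean - half, mean + half, n,
                toy_site(label, patient))
}

# Gaussian-feature matrix with two classes separated by `delta` (in sd units).
gaussian_features <- function(n_per_class = 20, p = 2, delta = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = delta), ncol = p))
  labels <- factor(rep(c("intact", "lesion"), each = n_per_class),
                   levels = c("intact", "lesion"))
  structure(list(x = x, labels = labels,
                 patient_ids = sprintf("P%03d", seq_len(2 * n_per_class)),
                 band_set = band_set(cbind(seq(400, by = 20,
                                               length.out = p),
                                           seq(410, by = 20,
                                               length.out = p)))),
            class = "feature_matrix")
}

# Total length of the intersection and union of two interval sets, and their
# Jaccard overlap. Interval sets are two-column matrices.
interval_jaccard <- function(a, b) {
  grid <- seq(360, 1000, by = 0.5)
  in_set <- function(s) {
    hit <- rep(FALSE, length(grid))
    if (length(s) == 0) return(hit)
    s <- matrix(s, ncol = 2)
    for (i in seq_len(nrow(s)))
      hit <- hit | (grid >= s[i, 1] & grid <= s[i, 2])
    hit
  }
  ia <- in_set(a); ib <- in_set(b)
  u <- sum(ia | ib)
  if (u == 0) return(1)
  sum(ia & ib) / u
}
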