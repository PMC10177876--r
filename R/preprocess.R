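#' Averaged spectrum with confidence band
#'
#' Container for a per-site averaged (usually source-normalized) spectrum in
#' relative units, with the two-sided Student-t confidence band and the number
#' of repeated measurements it was averaged from.
#'
#' @param wavelengths Wavelength grid, nm.
#' @param mean,sd Per-wavelength mean and sample standard deviation (r.u.).
#' @param ci_low,ci_high Confidence band, r.u.
#' @param n Number of measurements averaged.
#' @param site A [site_record()].
#' @return An object of class \code{mean_spectrum}.
#' @export
mean_spectrum <- function(wavelengths, mean, sd, ci_low, ci_high, n, site) {
  wavelengths <- wavelength_grid(wavelengths)
  stopifnot(length(mean) == length(wavelengths),
            length(sd) == length(wavelengths),
            length(ci_low) == length(wavelengths),
            length(ci_high) == length(wavelengths))
  if (any(sd < 0, na.rm = TRUE)) stop("sd must be non-negative")
  if (any(ci_low > mean + 1e-12 | ci_high < mean - 1e-12, na.rm = TRUE))
    stop("confidence band must bracket the mean")
  structure(list(wavelengths = wavelengths, mean = as.numeric(mean),
                 sd = as.numeric(sd), ci_low = as.numeric(ci_low),
                 ci_high = as.numeric(ci_high), n = as.integer(n),
                 site = site),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("<mean_spectrum> %d wavelengths (%g-%g nm), n = %d, %s/%s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$n, x$site$patient_id, x$site$label))
  invisible(x)
}

#' Normalize a series to the light-source spectrum
#'
#' Divides every measurement elementwise by the mean raw source spectrum,
#' yielding dimensionless relative units that are independent of the source
#' intensity profile. Wavelengths where the source mean falls below
#' \code{floor_rel * max(source mean)} (source roll-off at the range edges)
#' are masked out of the grid when \code{mask = TRUE}; with \code{mask =
#' FALSE} such wavelengths raise an error instead.
#'
#' @param series A [spectrum_series()].
#' @param source A [mean_spectrum()] of the light source on the same grid.
#' @param floor_rel Relative source floor; default \code{1e-6}.
#' @param mask Drop below-floor wavelengths (default) or error on them.
#' @return A [spectrum_series()] in relative units (grid possibly reduced).
#' @export
normalize_to_source <- function(series, source, floor_rel = 1e-6, mask = TRUE) {
  if (!isTRUE(all.equal(series$wavelengths, source$wavelengths)))
    stop("series and source must share one wavelength grid", call. = FALSE)
  floor <- floor_rel * max(source$mean)
  low <- source$mean <= floor
  if (any(low)) {
    if (!mask)
      stop(sprintf("source spectrum at or below floor at %d wavelength(s): %s nm",
                   sum(low),
                   paste(utils::head(series$wavelengths[low], 5), collapse = ", ")),
           call. = FALSE)
    keep <- !low
    series <- spectrum_series(series$wavelengths[keep],
                              series$intensities[, keep, drop = FALSE],
                              series$site)
    src_mean <- source$mean[keep]
  } else src_mean <- source$mean
  out <- sweep(series$intensities, 2L, src_mean, "/")
  spectrum_series(series$wavelengths, out, series$site)
}

#' Average a series and attach a Student-t confidence band
#'
#' Per wavelength, the arithmetic mean of the n repeated measurements and the
#' two-sided confidence interval
#' \eqn{\bar I \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}} with \eqn{s} the sample
#' standard deviation (n-1 denominator).
#'
#' @param series A [spectrum_series()].
#' @param alpha Significance level in (0,1); default 0.05 (95\% band).
#' @return A [mean_spectrum()].
#' @export
average_and_ci <- function(series, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  x <- series$intensities
  n <- nrow(x)
  m <- colMeans(x)
  if (n == 1L) {
    warning("single measurement: confidence interval degenerates to the mean")
    return(mean_spectrum(series$wavelengths, m, rep(0, length(m)), m, m, 1L,
                         series$site))
  }
  s <- apply(x, 2L, stats::sd)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
  mean_spectrum(series$wavelengths, m, s, m - half, m + half, n, series$site)
}

#' Normalized RMS (coefficient of variation) of a series
#'
#' Per-wavelength sample standard deviation divided by the per-wavelength
#' mean; the scale-free repeatability measure used to compare instruments.
#' Wavelengths with zero mean are returned as \code{NA} with a warning.
#'
#' @param series A [spectrum_series()] with at least two measurements.
#' @return Numeric vector, one value per wavelength.
#' @export
normalized_rms <- function(series) {
  x <- series$intensities
  if (nrow(x) < 2L) stop("need at least 2 measurements", call. = FALSE)
  m <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  out <- s / m
  if (any(m == 0)) {
    warning(sprintf("%d wavelength(s) with zero mean masked", sum(m == 0)))
    out[m == 0] <- NA_real_
  }
  out
}

#' Joint maximum normalization of an intact/lesion/reference triple
#'
#' The stage-2 convention: all three mean spectra are divided by the single
#' global maximum across the three, so the largest of the three signals peaks
#' at exactly 1 and all pairwise intensity ratios are preserved.
#'
#' @param intact,lesion,reference [mean_spectrum()] objects on one grid.
#' @return A named list \code{(intact, lesion, reference)} of rescaled
#'   [mean_spectrum()] objects.
#' @export
triple_max_normalize <- function(intact, lesion, reference) {
  triple <- list(intact = intact, lesion = lesion, reference = reference)
  grid <- intact$wavelengths
  for (sp in triple) {
    if (!isTRUE(all.equal(sp$wavelengths, grid)))
      stop("all three spectra must share one wavelength grid", call. = FALSE)
    if (any(sp$mean < 0)) stop("means must be non-negative", call. = FALSE)
  }
  divisor <- max(vapply(triple, function(sp) max(sp$mean), 0))
  if (divisor <= 0) stop("all-zero inputs: joint maximum is not positive",
                         call. = FALSE)
  lapply(triple, function(sp)
    mean_spectrum(sp$wavelengths, sp$mean / divisor, sp$sd / divisor,
                  sp$ci_low / divisor, sp$ci_high / divisor, sp$n, sp$site))
}

#' Source-normalized averaged spectra for a whole cohort
#'
#' Convenience pipeline: averages the source series, normalizes every site
#' series to it, and averages each with a confidence band. The common
#' source-floor mask is applied to all series identically.
#'
#' @param cohort A [drs_cohort()].
#' @param alpha CI significance level.
#' @return List of [mean_spectrum()], one per series.
#' @export
cohort_mean_spectra <- function(cohort, alpha = 0.05) {
  src <- average_and_ci(cohort$source, alpha)
  lapply(cohort$series, function(s)
    average_and_ci(normalize_to_source(s, src), alpha))
}
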