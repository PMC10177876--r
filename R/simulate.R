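# Synthetic chromophore absorption templates. These are Gaussian-band
# stand-ins with documented constants chosen to place absorption where the
# real chromophores absorb (oxyhemoglobin 542/577 nm, deoxyhemoglobin 556 nm
# with a weak 760 nm band, water 970 nm); they are not tabulated literature
# extinction spectra. All widths are Gaussian sigmas in nm; amplitudes are
# effective extinction scales such that plausible blood/water fractions give
# optical depths of order 1 in the visible.

#' Synthetic chromophore and fluorescence template constants
#'
#' One place holding every spectral constant of the generator: Gaussian band
#' centers, widths (sigma, nm) and amplitudes for the oxy-/deoxyhemoglobin
#' and water absorption stand-ins, the fluorescence emission band, and the
#' NIR scattering-change window.
#'
#' @return Named list of template constants.
#' @export
drs_templates <- function() {
  list(
    hbo2 = list(centers = c(542, 577), sigmas = c(15, 12), amps = c(25, 22.5)),
    hb = list(centers = c(556, 760), sigmas = c(18, 18), amps = c(25, 1.25)),
    water = list(centers = 970, sigmas = 40, amps = 0.5),
    fluor = list(center = 500, sigma = 60),
    nir_window = list(center = 840, width = 20)
  )
}

gauss_bands <- function(w, centers, sigmas, amps) {
  out <- numeric(length(w))
  for (i in seq_along(centers))
    out <- out + amps[i] * exp(-(w - centers[i])^2 / (2 * sigmas[i]^2))
  out
}

#' Synthetic light-source spectrum
#'
#' A Planck blackbody curve at 2800 K (a halogen-lamp stand-in), peak
#' normalized to 1 on the grid. Smooth, strictly positive, and monotone
#' increasing over 360--1000 nm (the Planck peak at 2800 K lies beyond
#' 1000 nm).
#'
#' @param wavelengths Grid, nm, within 360--1000.
#' @return A [mean_spectrum()] labeled \code{"reference"} (n = 1).
#' @export
source_spectrum <- function(wavelengths = canonical_grid()) {
  wavelengths <- wavelength_grid(wavelengths)
  if (min(wavelengths) < 360 || max(wavelengths) > 1000)
    stop("source model defined on 360-1000 nm", call. = FALSE)
  temp_k <- 2800
  x <- 1.43877e7 / (wavelengths * temp_k)  # hc/(lambda k T), lambda in nm
  b <- wavelengths^-5 / (exp(x) - 1)
  b <- b / max(b)
  site <- site_record("source", "tongue", "reference")
  mean_spectrum(wavelengths, b, rep(0, length(b)), b, b, 1L, site)
}

#' Tissue optics parameter set
#'
#' @param blood_fraction Blood volume fraction, in [0, 0.2].
#' @param oxygen_saturation Hemoglobin oxygen saturation, in [0, 1].
#' @param water_fraction Water volume fraction, in [0, 1].
#' @param scatter_amplitude Scattering baseline at 500 nm, r.u. (> 0).
#' @param scatter_power Mie-like wavelength exponent of the scattering
#'   baseline.
#' @param fluor_amplitude Fluorescence background amplitude, r.u. (>= 0).
#' @param nir_scatter Relative NIR scattering change (0 = none); applied
#'   inside a logistic window above ~840 nm.
#' @return An object of class \code{tissue_optics_params}.
#' @export
tissue_optics_params <- function(blood_fraction = 0.03,
                                 oxygen_saturation = 0.7,
                                 water_fraction = 0.65,
                                 scatter_amplitude = 0.5,
                                 scatter_power = 1.0,
                                 fluor_amplitude = 0.05,
                                 nir_scatter = 0) {
  p <- list(blood_fraction = blood_fraction,
            oxygen_saturation = oxygen_saturation,
            water_fraction = water_fraction,
            scatter_amplitude = scatter_amplitude,
            scatter_power = scatter_power,
            fluor_amplitude = fluor_amplitude,
            nir_scatter = nir_scatter)
  if (blood_fraction < 0 || blood_fraction > 0.2)
    stop("blood_fraction must be in [0, 0.2]", call. = FALSE)
  if (oxygen_saturation < 0 || oxygen_saturation > 1)
    stop("oxygen_saturation must be in [0, 1]", call. = FALSE)
  if (water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must be in [0, 1]", call. = FALSE)
  if (scatter_amplitude <= 0) stop("scatter_amplitude must be positive",
                                   call. = FALSE)
  if (fluor_amplitude < 0) stop("fluor_amplitude must be non-negative",
                                call. = FALSE)
  if (nir_scatter < 0) stop("nir_scatter must be non-negative", call. = FALSE)
  structure(p, class = "tissue_optics_params")
}

#' Synthetic tissue diffuse reflectance
#'
#' A modified Beer-Lambert forward model with unit path factor:
#' \deqn{R(\lambda) = S(\lambda)\, e^{-\mu_a(\lambda)} + F(\lambda),}
#' where the scattering baseline is
#' \eqn{S = A (\lambda/500)^{-b} (1 + \delta_{nir} w(\lambda))} with a
#' logistic NIR window \eqn{w}, the absorption coefficient mixes the
#' hemoglobin and water templates,
#' \eqn{\mu_a = c_{blood}[s\,\varepsilon_{HbO_2} + (1-s)\varepsilon_{Hb}] +
#' c_{water}\varepsilon_{H_2O}}, and \eqn{F} is a Gaussian fluorescence
#' background at 500 nm. The result is validated to lie in (0, 1].
#'
#' @param params A [tissue_optics_params()].
#' @param wavelengths Grid, nm.
#' @return Numeric reflectance vector in (0, 1].
#' @export
tissue_reflectance <- function(params, wavelengths = canonical_grid()) {
  if (!inherits(params, "tissue_optics_params"))
    params <- do.call(tissue_optics_params, as.list(params))
  w <- wavelength_grid(wavelengths)
  tpl <- drs_templates()
  mu_a <- params$blood_fraction *
    (params$oxygen_saturation *
       gauss_bands(w, tpl$hbo2$centers, tpl$hbo2$sigmas, tpl$hbo2$amps) +
     (1 - params$oxygen_saturation) *
       gauss_bands(w, tpl$hb$centers, tpl$hb$sigmas, tpl$hb$amps)) +
    params$water_fraction *
      gauss_bands(w, tpl$water$centers, tpl$water$sigmas, tpl$water$amps)
  nir <- stats::plogis((w - tpl$nir_window$center) / tpl$nir_window$width)
  s <- params$scatter_amplitude * (w / 500)^(-params$scatter_power) *
    (1 + params$nir_scatter * nir)
  f <- params$fluor_amplitude *
    exp(-(w - tpl$fluor$center)^2 / (2 * tpl$fluor$sigma^2))
  r <- s * exp(-mu_a) + f
  if (any(r <= 0) || any(r > 1))
    stop("reflectance outside (0, 1]; parameter combination is unphysical",
         call. = FALSE)
  r
}

#' Cohort generation settings
#'
#' The settings default to the study conditions: series of 15 repeated
#' measurements per area, relative measurement noise of 2 percent, a
#' log-normal per-patient multiplicative gain with sd 0.1 (probe-contact and
#' coupling variability), and class effects concentrated in the 400--600 nm
#' chromophore/fluorescence region and the 800--1000 nm scattering region.
#'
#' @param n_patients Number of patients (used when \code{paired = TRUE}).
#' @param paired If \code{TRUE} every patient contributes one intact and one
#'   lesion site (the stage-2 design); if \code{FALSE} each site belongs to
#'   its own patient (the stage-1 design of independent areas).
#' @param n_intact_sites,n_lesion_sites Site counts for the unpaired design;
#'   defaults 8 and 14 (the tongue stage-1 sample).
#' @param site_type \code{"tongue"} or \code{"cheek"}.
#' @param n_measurements Repeated measurements per site, in [15, 30].
#' @param effect_size Multiplier on every lesion-vs-intact parameter shift;
#'   0 gives the null cohort.
#' @param patient_gain_sd Log-sd of the per-patient multiplicative gain.
#' @param noise_sd Relative Gaussian measurement noise.
#' @param effect_mode \code{"biophysical"}: lesion shifts of blood fraction
#'   (+0.02), water fraction (+0.05), fluorescence (-0.015) and NIR
#'   scattering (+0.25), each times \code{effect_size}. \code{"bands"}:
#'   a flat multiplicative suppression of depth \code{band_depth *
#'   effect_size} confined exactly to \code{effect_bands} (used to test band
#'   recovery against known injected intervals).
#' @param effect_bands Two-column matrix of injected intervals for
#'   \code{effect_mode = "bands"}; default 520--580 and 850--950 nm.
#' @param band_depth Relative suppression depth per unit effect size.
#' @param seed Master seed; all randomness is derived from it.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 20L, paired = FALSE,
                        n_intact_sites = 8L, n_lesion_sites = 14L,
                        site_type = "tongue", n_measurements = 15L,
                        effect_size = 1, patient_gain_sd = 0.1,
                        noise_sd = 0.02,
                        effect_mode = c("biophysical", "bands"),
                        effect_bands = rbind(c(520, 580), c(850, 950)),
                        band_depth = 0.3, seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  if (n_measurements < 1L) stop("n_measurements must be >= 1", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd < 0 || patient_gain_sd < 0)
    stop("noise_sd and patient_gain_sd must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), paired = paired,
                 n_intact_sites = as.integer(n_intact_sites),
                 n_lesion_sites = as.integer(n_lesion_sites),
                 site_type = match.arg(site_type, site_types),
                 n_measurements = as.integer(n_measurements),
                 effect_size = effect_size,
                 patient_gain_sd = patient_gain_sd, noise_sd = noise_sd,
                 effect_mode = effect_mode,
                 effect_bands = matrix(as.numeric(effect_bands), ncol = 2L),
                 band_depth = band_depth, seed = as.integer(seed)),
            class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-patient baseline optics draw (runs inside the patient's RNG stream).
draw_baseline_params <- function() {
  tissue_optics_params(
    blood_fraction = clamp(stats::rnorm(1, 0.03, 0.005), 0.005, 0.2),
    oxygen_saturation = clamp(stats::rnorm(1, 0.7, 0.05), 0, 1),
    water_fraction = clamp(stats::rnorm(1, 0.65, 0.05), 0, 1),
    scatter_amplitude = clamp(stats::rnorm(1, 0.5, 0.03), 0.05, 0.65),
    scatter_power = clamp(stats::rnorm(1, 1.0, 0.05), 0.5, 1.5),
    fluor_amplitude = clamp(stats::rnorm(1, 0.05, 0.01), 0, 0.2))
}

apply_lesion_shift <- function(params, effect_size) {
  tissue_optics_params(
    blood_fraction = clamp(params$blood_fraction + 0.02 * effect_size,
                           0, 0.2),
    oxygen_saturation = params$oxygen_saturation,
    water_fraction = clamp(params$water_fraction + 0.05 * effect_size, 0, 1),
    scatter_amplitude = params$scatter_amplitude,
    scatter_power = params$scatter_power,
    fluor_amplitude = clamp(params$fluor_amplitude - 0.015 * effect_size,
                            0, 0.2),
    nir_scatter = 0.25 * effect_size)
}

#' Generate a synthetic DRS cohort
#'
#' Per patient, baseline optics parameters are drawn from the priors and a
#' multiplicative gain from LogNormal(0, \code{patient_gain_sd}); lesion
#' sites apply the effect shifts scaled by \code{effect_size}; each repeated
#' measurement is the tissue reflectance times the source spectrum times the
#' patient gain, with relative Gaussian noise. Randomness is fully
#' deterministic given \code{spec$seed}: every patient has a derived
#' sub-stream, so cohorts are bit-identical across runs.
#'
#' @param spec A [cohort_spec()].
#' @param grid Analysis grid; default [canonical_grid()].
#' @return A [drs_cohort()] including the source series (the source series
#'   carries small instrument noise around the model source spectrum).
#' @export
generate_cohort <- function(spec, grid = canonical_grid()) {
  stopifnot(inherits(spec, "cohort_spec"))
  src_model <- source_spectrum(grid)
  layout <- if (spec$paired) {
    data.frame(patient = rep(seq_len(spec$n_patients), each = 2L),
               label = rep(c("intact", "lesion"), spec$n_patients))
  } else {
    n_sites <- spec$n_intact_sites + spec$n_lesion_sites
    data.frame(patient = seq_len(n_sites),
               label = c(rep("intact", spec$n_intact_sites),
                         rep("lesion", spec$n_lesion_sites)))
  }
  in_bands <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(spec$effect_bands)))
    in_bands <- in_bands | (grid >= spec$effect_bands[i, 1] &
                            grid <= spec$effect_bands[i, 2])
  depth <- clamp(spec$band_depth * spec$effect_size, 0, 0.95)

  series <- vector("list", nrow(layout))
  current <- 0L
  for (p in unique(layout$patient)) {
    rows <- which(layout$patient == p)
    pseed <- derive_seed(spec$seed, 11L, p)
    series[rows] <- with_seed(pseed, {
      base <- draw_baseline_params()
      gain <- exp(stats::rnorm(1, 0, spec$patient_gain_sd))
      lapply(rows, function(i) {
        lab <- layout$label[i]
        r <- if (spec$effect_mode == "biophysical") {
          prm <- if (lab == "lesion")
            apply_lesion_shift(base, spec$effect_size) else base
          tissue_reflectance(prm, grid)
        } else {
          r0 <- tissue_reflectance(base, grid)
          if (lab == "lesion") r0 * (1 - depth * in_bands) else r0
        }
        clean <- gain * r * src_model$mean
        noise <- matrix(stats::rnorm(spec$n_measurements * length(grid),
                                     0, spec$noise_sd),
                        nrow = spec$n_measurements)
        m <- sweep(1 + noise, 2L, clean, "*")
        m[m < 0] <- 0
        site <- site_record(sprintf("P%03d", p), spec$site_type, lab,
                            if (lab == "lesion") "hyperkeratosis" else NULL)
        spectrum_series(grid, m, site)
      })
    })
    current <- current + length(rows)
  }
  src_noise <- with_seed(derive_seed(spec$seed, 22L, 1L),
                         matrix(stats::rnorm(15L * length(grid), 0, 0.002),
                                nrow = 15L))
  src_m <- sweep(1 + src_noise, 2L, src_model$mean, "*")
  src_series <- spectrum_series(grid, src_m,
                                site_record("source", spec$site_type,
                                            "reference"))
  drs_cohort(series, src_series)
}

#' Null cohort (no class effect)
#'
#' Identical to [generate_cohort()] with \code{effect_size} forced to 0:
#' intact and lesion sites are drawn from one distribution.
#'
#' @param spec A [cohort_spec()].
#' @param grid Analysis grid.
#' @return A [drs_cohort()].
#' @export
null_cohort <- function(spec, grid = canonical_grid()) {
  spec$effect_size <- 0
  generate_cohort(spec, grid)
}
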