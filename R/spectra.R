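#' Validate a wavelength grid
#'
#' A wavelength grid is a strictly increasing numeric vector of wavelengths in
#' nanometres within the spectrometer's sensitive range (325--1100 nm).
#'
#' @param wavelengths Numeric vector of wavelengths, nm.
#' @return The validated numeric vector, invisibly usable as a grid.
#' @export
wavelength_grid <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L)
    stop("wavelength grid must contain at least 2 points", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelength grid contains non-finite values", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(wavelengths < 325) || any(wavelengths > 1100))
    stop("wavelengths must lie within the instrument range [325, 1100] nm",
         call. = FALSE)
  wavelengths
}

#' Canonical analysis grid
#'
#' The default analysis grid: 360 to 1000 nm at 1 nm pitch. All cohort spectra
#' are co-registered onto this grid before any statistics are computed.
#'
#' @param from,to,by Grid limits and step, nm.
#' @return Numeric wavelength grid.
#' @export
canonical_grid <- function(from = 360, to = 1000, by = 1) {
  wavelength_grid(seq(from, to, by = by))
}

site_types <- c("tongue", "cheek")
site_labels <- c("intact", "lesion", "reference")
lesion_types <- c("hyperkeratosis", "lichen_planus", "leukoplakia",
                  "traumatic_erosion", "glossitis", "fibroma", "unmarked")

#' Site metadata record
#'
#' Describes one measured area of the oral mucosa: which patient, which
#' anatomical site, and whether the area is clinically intact or a lesion.
#' The label \code{"reference"} is reserved for the simulated stage-2
#' reference signal (see [simulate_reference()]) and for the light source.
#'
#' @param patient_id Character scalar.
#' @param site_type One of \code{"tongue"}, \code{"cheek"}.
#' @param label One of \code{"intact"}, \code{"lesion"}, \code{"reference"}.
#' @param lesion_type Optional lesion subtype (metadata only).
#' @return An object of class \code{site_record}.
#' @export
site_record <- function(patient_id, site_type = "tongue", label = "intact",
                        lesion_type = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  site_type <- match.arg(site_type, site_types)
  label <- match.arg(label, site_labels)
  if (!is.null(lesion_type))
    lesion_type <- match.arg(lesion_type, lesion_types)
  structure(list(patient_id = patient_id, site_type = site_type,
                 label = label, lesion_type = lesion_type),
            class = "site_record")
}

#' Series of repeated backscattering spectra for one site
#'
#' Holds the 15--30 repeated intensity measurements registered at one area,
#' as an \code{n_measurements x n_wavelengths} matrix on a common grid.
#'
#' @param wavelengths Wavelength grid, nm (see [wavelength_grid()]).
#' @param intensities Numeric matrix, one row per repeated measurement;
#'   arbitrary non-negative intensity units.
#' @param site A [site_record()].
#' @return An object of class \code{spectrum_series}.
#' @export
spectrum_series <- function(wavelengths, intensities, site) {
  wavelengths <- wavelength_grid(wavelengths)
  intensities <- as.matrix(intensities)
  if (!inherits(site, "site_record")) stop("site must be a site_record")
  if (ncol(intensities) != length(wavelengths))
    stop(sprintf("intensity rows have %d columns but grid has %d points",
                 ncol(intensities), length(wavelengths)), call. = FALSE)
  if (nrow(intensities) < 1L) stop("need at least one measurement")
  bad <- which(!is.finite(intensities) | intensities < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite or negative intensity at measurement %d, wavelength %g nm",
                 bad[1, 1], wavelengths[bad[1, 2]]), call. = FALSE)
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 site = site),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %d measurements x %d wavelengths (%g-%g nm)\n",
              nrow(x$intensities), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  patient %s, %s, %s\n", x$site$patient_id, x$site$site_type,
              x$site$label))
  invisible(x)
}

#' Cohort of spectrum series plus the light-source spectrum
#'
#' @param series List of [spectrum_series()] objects sharing one grid.
#' @param source A [spectrum_series()] of the light source (label
#'   \code{"reference"}).
#' @return An object of class \code{drs_cohort}.
#' @export
drs_cohort <- function(series, source) {
  stopifnot(is.list(series), length(series) >= 1L)
  lapply(series, function(s) {
    if (!inherits(s, "spectrum_series")) stop("series must be spectrum_series")
  })
  if (!inherits(source, "spectrum_series"))
    stop("source must be a spectrum_series")
  grid <- series[[1]]$wavelengths
  for (s in c(series, list(source)))
    if (!isTRUE(all.equal(s$wavelengths, grid)))
      stop("all series (and the source) must share one wavelength grid; ",
           "resample with resample_to_grid() first", call. = FALSE)
  structure(list(series = series, source = source), class = "drs_cohort")
}

#' @export
print.drs_cohort <- function(x, ...) {
  labs <- vapply(x$series, function(s) s$site$label, "")
  cat(sprintf("<drs_cohort> %d series (%d intact, %d lesion) on %d-point grid\n",
              length(x$series), sum(labs == "intact"), sum(labs == "lesion"),
              length(x$series[[1]]$wavelengths)))
  invisible(x)
}

#' Linear resampling of a series onto a target grid
#'
#' Each measurement row is linearly interpolated onto \code{target}. The target
#' must be contained in the measured range: extrapolation is refused rather
#' than fabricating data outside it.
#'
#' @param series A [spectrum_series()].
#' @param target Target wavelength grid, nm.
#' @return A [spectrum_series()] on \code{target}.
#' @export
resample_to_grid <- function(series, target) {
  target <- wavelength_grid(target)
  w <- series$wavelengths
  if (min(target) < min(w) || max(target) > max(w))
    stop(sprintf("target grid [%g, %g] nm extends beyond measured range [%g, %g] nm",
                 min(target), max(target), min(w), max(w)), call. = FALSE)
  out <- t(apply(series$intensities, 1L, function(row)
    stats::approx(w, row, xout = target, method = "linear")$y))
  if (length(target) == 1L) out <- matrix(out, ncol = 1L)
  spectrum_series(target, out, series$site)
}
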