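#' Band-area features of one spectrum
#'
#' For each informative subrange the area under the spectrum is accumulated
#' as a left Riemann sum on the uniform analysis grid:
#' \eqn{S(\Delta\lambda_i) = \sum_{\lambda_{lo} \le \lambda < \lambda_{hi}}
#' I(\lambda)\,\Delta\lambda}, with \eqn{\Delta\lambda} the grid step. The
#' grid point at the upper band edge is the right endpoint of the last step
#' and is therefore excluded; the convention is exact and tested.
#'
#' @param spectrum A [mean_spectrum()].
#' @param bands A [band_set()] lying within the spectrum grid.
#' @return Numeric vector, one area (r.u. nm) per band.
#' @export
band_areas <- function(spectrum, bands) {
  w <- spectrum$wavelengths
  step <- diff(w)
  if (max(step) - min(step) > 1e-9)
    stop("band areas require a uniform wavelength grid", call. = FALSE)
  step <- step[1L]
  b <- bands$bands
  if (nrow(b) == 0L) return(numeric(0))
  if (any(b[, 1] < min(w)) || any(b[, 2] > max(w)))
    stop("band outside the spectrum grid range", call. = FALSE)
  vapply(seq_len(nrow(b)), function(i) {
    idx <- w >= b[i, 1] & w < b[i, 2]
    sum(spectrum$mean[idx]) * step
  }, 0)
}

#' Stack band-area feature rows for a cohort
#'
#' One row per averaged site spectrum, one column per band; class labels come
#' from the attached site records. Reference-labeled spectra (the light
#' source, simulated stage-2 references) are excluded.
#'
#' @param spectra List of [mean_spectrum()] on one shared grid.
#' @param bands A non-empty [band_set()].
#' @return An object of class \code{feature_matrix}: \code{x} (matrix),
#'   \code{labels} (factor intact/lesion), \code{patient_ids}, \code{band_set}.
#' @export
build_feature_matrix <- function(spectra, bands) {
  if (length(spectra) == 0L) stop("empty spectra list", call. = FALSE)
  if (nrow(bands$bands) == 0L) stop("empty band set", call. = FALSE)
  spectra <- Filter(function(sp) sp$site$label != "reference", spectra)
  if (length(spectra) == 0L)
    stop("no intact/lesion spectra after excluding references", call. = FALSE)
  grid <- spectra[[1]]$wavelengths
  for (sp in spectra)
    if (!isTRUE(all.equal(sp$wavelengths, grid)))
      stop("all spectra must share one wavelength grid", call. = FALSE)
  x <- do.call(rbind, lapply(spectra, band_areas, bands = bands))
  colnames(x) <- sprintf("band_%g_%g", bands$bands[, 1], bands$bands[, 2])
  labels <- factor(vapply(spectra, function(sp) sp$site$label, ""),
                   levels = c("intact", "lesion"))
  if (anyNA(x)) stop("missing values in feature matrix", call. = FALSE)
  structure(list(x = x, labels = labels,
                 patient_ids = vapply(spectra, function(sp) sp$site$patient_id, ""),
                 band_set = bands),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d spectra x %d band(s) (%d intact, %d lesion)\n",
              nrow(x$x), ncol(x$x), sum(x$labels == "intact"),
              sum(x$labels == "lesion")))
  invisible(x)
}
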