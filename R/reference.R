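#' Simulate a patient's reference intact signal
#'
#' Bootstraps the intact series: n measurements are drawn from the n
#' available with replacement and averaged. The resample (rather than the
#' plain mean) makes the reference an independent-looking realization of the
#' same site, so the intact-minus-reference delta carries genuine
#' measurement variability instead of being identically zero.
#'
#' @param intact_series A [spectrum_series()] with n >= 2 measurements.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [mean_spectrum()] labeled \code{"reference"}.
#' @export
simulate_reference <- function(intact_series, seed = 1L) {
  n <- nrow(intact_series$intensities)
  if (n < 2L)
    stop("need at least 2 intact measurements to model a reference",
         call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  resampled <- spectrum_series(intact_series$wavelengths,
                               intact_series$intensities[idx, , drop = FALSE],
                               intact_series$site)
  out <- suppressWarnings(average_and_ci(resampled))
  out$site <- site_record(intact_series$site$patient_id,
                          intact_series$site$site_type, "reference")
  out
}

#' Intact/lesion/reference triple for one patient
#'
#' Applies the stage-2 joint maximum normalization (see
#' [triple_max_normalize()]) so the triple is ready for delta construction.
#'
#' @param intact,lesion [mean_spectrum()] objects for the patient's sites.
#' @param reference The simulated reference [mean_spectrum()].
#' @param seed Seed the reference was simulated with (provenance).
#' @return An object of class \code{patient_triple}.
#' @export
patient_triple <- function(intact, lesion, reference, seed = NA_integer_) {
  if (intact$site$patient_id != lesion$site$patient_id ||
      intact$site$patient_id != reference$site$patient_id)
    stop("triple must belong to one patient", call. = FALSE)
  tri <- triple_max_normalize(intact, lesion, reference)
  structure(c(tri, list(patient_id = intact$site$patient_id,
                        seed = as.integer(seed))),
            class = "patient_triple")
}

#' Delta spectra of one patient
#'
#' Elementwise differences against the patient's own reference:
#' \code{delta_intact = intact - reference}, \code{delta_lesion = lesion -
#' reference}, on the (already jointly normalized) shared grid.
#'
#' @param triple A [patient_triple()].
#' @return An object of class \code{delta_record}: \code{wavelengths},
#'   \code{delta_intact}, \code{delta_lesion}, \code{patient_id}.
#' @export
build_deltas <- function(triple) {
  if (!inherits(triple, "patient_triple"))
    stop("triple must be a patient_triple", call. = FALSE)
  if (!isTRUE(all.equal(triple$intact$wavelengths,
                        triple$lesion$wavelengths)) ||
      !isTRUE(all.equal(triple$intact$wavelengths,
                        triple$reference$wavelengths)))
    stop("grid mismatch inside triple", call. = FALSE)
  structure(list(wavelengths = triple$intact$wavelengths,
                 delta_intact = triple$intact$mean - triple$reference$mean,
                 delta_lesion = triple$lesion$mean - triple$reference$mean,
                 patient_id = triple$patient_id),
            class = "delta_record")
}

#' Patient-grouped classification of delta spectra
#'
#' Each patient contributes two rows: the intact delta (class 0/intact) and
#' the lesion delta (class 1/lesion), restricted to a wavelength range. Folds
#' are formed over patients, never over rows, so both rows of a patient land
#' in the same fold and no patient straddles train and test. Returns the mean
#' held-out accuracy in percent, rows equally weighted.
#'
#' @param deltas List of [build_deltas()] records, one per patient.
#' @param range Length-2 numeric \code{c(lambda_lo, lambda_hi)}, nm.
#' @param method Classifier; default \code{"RF"} (random forest).
#' @param folds,repeats Cross-validation over patients; defaults 5 and 1.
#' @param seed Integer seed (fold assignment and classifier randomness).
#' @return Accuracy in percent (scalar).
#' @export
patientwise_classify <- function(deltas, range, method = "RF", folds = 5L,
                                 repeats = 1L, seed = 1L) {
  method <- match.arg(toupper(method), cv_methods)
  if (length(deltas) < 2L) stop("need at least 2 patients", call. = FALSE)
  w <- deltas[[1]]$wavelengths
  for (d in deltas)
    if (!isTRUE(all.equal(d$wavelengths, w)))
      stop("delta records must share one wavelength grid", call. = FALSE)
  if (range[1] < min(w) || range[2] > max(w))
    stop(sprintf("range [%g, %g] nm outside the grid [%g, %g] nm",
                 range[1], range[2], min(w), max(w)), call. = FALSE)
  sel <- w >= range[1] & w <= range[2]
  if (!any(sel)) stop("empty wavelength selection", call. = FALSE)
  n_pat <- length(deltas)
  x <- do.call(rbind, lapply(deltas, function(d)
    rbind(d$delta_intact[sel], d$delta_lesion[sel])))
  y <- factor(rep(c("intact", "lesion"), n_pat),
              levels = c("intact", "lesion"))
  pat <- rep(seq_len(n_pat), each = 2L)
  folds <- min(folds, n_pat)
  acc <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_of_patient <- with_seed(derive_seed(seed, 303L, r),
                                 sample(rep_len(seq_len(folds), n_pat)))
    for (f in seq_len(folds)) {
      te <- fold_of_patient[pat] == f
      if (!any(te) || all(te)) next
      pred <- with_seed(derive_seed(seed, 404L, r, f),
                        fit_predict(method, x[!te, , drop = FALSE], y[!te],
                                    x[te, , drop = FALSE]))
      acc <- c(acc, pred == y[te])
    }
  }
  100 * mean(acc)
}

#' Default stage-2 wavelength-range grid
#'
#' The 25 ranges over which patient-wise delta classification is evaluated:
#' lower limits 500--700 nm in 50 nm steps crossed with upper limits 900,
#' 850, 800, 750 and 701 nm (the 1 nm-wide 700--701 range kept verbatim).
#'
#' @return Two-column matrix \code{(lambda_lo, lambda_hi)}, 25 rows.
#' @export
default_range_grid <- function() {
  his <- c(900, 850, 800, 750, 701)
  rows <- do.call(rbind, lapply(c(500, 550, 600, 650), function(lo)
    cbind(lo, his)))
  rows <- rbind(rows, cbind(700, c(900, 800, 750, 701, 850)))
  colnames(rows) <- c("lambda_lo", "lambda_hi")
  rows
}

#' Accuracy of patient-wise delta classification over a range grid
#'
#' @param deltas List of [build_deltas()] records.
#' @param range_grid Two-column matrix of ranges; default
#'   [default_range_grid()].
#' @param method,folds,repeats,seed Passed to [patientwise_classify()]; the
#'   same seed is used for every range so fold assignments are shared across
#'   rows.
#' @return Data frame: \code{lambda_lo}, \code{lambda_hi}, \code{accuracy}
#'   (percent), \code{n_patients}, \code{seed}.
#' @export
range_grid_accuracy <- function(deltas, range_grid = default_range_grid(),
                                method = "RF", folds = 5L, repeats = 1L,
                                seed = 1L) {
  range_grid <- matrix(as.numeric(range_grid), ncol = 2L)
  acc <- vapply(seq_len(nrow(range_grid)), function(i)
    patientwise_classify(deltas, range_grid[i, ], method = method,
                         folds = folds, repeats = repeats, seed = seed), 0)
  data.frame(lambda_lo = range_grid[, 1], lambda_hi = range_grid[, 2],
             accuracy = acc, n_patients = length(deltas), seed = seed)
}

#' Build patient triples and deltas for a whole cohort
#'
#' For every patient with at least one intact and one lesion series, the
#' intact series is bootstrapped into a reference signal (per-patient seed
#' derived from \code{seed}), the three averaged spectra are jointly
#' normalized, and the delta record is formed. Spectra are source-normalized
#' first.
#'
#' @param cohort A [drs_cohort()].
#' @param seed Master seed for the per-patient reference bootstraps.
#' @return List of [build_deltas()] records, one per eligible patient.
#' @export
cohort_deltas <- function(cohort, seed = 1L) {
  src <- average_and_ci(cohort$source)
  by_patient <- split(cohort$series,
                      vapply(cohort$series, function(s) s$site$patient_id, ""))
  deltas <- list()
  for (pid in names(by_patient)) {
    group <- by_patient[[pid]]
    labs <- vapply(group, function(s) s$site$label, "")
    if (!any(labs == "intact") || !any(labs == "lesion")) next
    intact_raw <- normalize_to_source(group[[which(labs == "intact")[1]]], src)
    lesion_raw <- normalize_to_source(group[[which(labs == "lesion")[1]]], src)
    pseed <- derive_seed(seed, 505L, length(deltas) + 1L)
    ref <- simulate_reference(intact_raw, seed = pseed)
    tri <- patient_triple(average_and_ci(intact_raw),
                          average_and_ci(lesion_raw), ref, seed = pseed)
    deltas[[pid]] <- build_deltas(tri)
  }
  if (length(deltas) == 0L)
    stop("no patient has both an intact and a lesion series", call. = FALSE)
  deltas
}
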