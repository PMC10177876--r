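#' Per-wavelength class-separability profile (Q coefficient)
#'
#' For each wavelength, the absolute difference of the class means divided by
#' the square root of the summed class variances:
#' \deqn{Q(\lambda) = \frac{|\,\bar I_{norm}(\lambda) - \bar I_{les}(\lambda)\,|}
#'   {\sqrt{\sigma^2_{norm}(\lambda) + \sigma^2_{les}(\lambda)}}.}
#' With several averaged spectra per class the means and unbiased variances
#' are taken across the spectra (the pooled "total" profile); with a single
#' spectrum per class the per-series standard deviations stored in the
#' [mean_spectrum()] are used instead (the patient-level profile).
#'
#' Wavelengths where both variances are zero while the means differ are
#' masked (\code{NA}) with a warning; where the means are equal Q is 0.
#'
#' @param norm_spectra,les_spectra Lists of [mean_spectrum()] (or single
#'   objects) for the intact and lesion classes, on one shared grid.
#' @return An object of class \code{q_profile}: wavelengths, \code{q},
#'   \code{n_norm}, \code{n_les}.
#' @export
q_profile <- function(norm_spectra, les_spectra) {
  as_list <- function(x) if (inherits(x, "mean_spectrum")) list(x) else x
  norm_spectra <- as_list(norm_spectra)
  les_spectra <- as_list(les_spectra)
  if (length(norm_spectra) == 0L || length(les_spectra) == 0L)
    stop("both class lists must be non-empty", call. = FALSE)
  grid <- norm_spectra[[1]]$wavelengths
  for (sp in c(norm_spectra, les_spectra))
    if (!isTRUE(all.equal(sp$wavelengths, grid)))
      stop("all spectra must share one wavelength grid", call. = FALSE)

  class_stats <- function(spectra) {
    m <- do.call(rbind, lapply(spectra, `[[`, "mean"))
    if (nrow(m) >= 2L)
      list(mean = colMeans(m), var = apply(m, 2L, stats::var))
    else
      list(mean = m[1L, ], var = spectra[[1L]]$sd^2)
  }
  a <- class_stats(norm_spectra)
  b <- class_stats(les_spectra)
  num <- abs(a$mean - b$mean)
  den2 <- a$var + b$var
  q <- numeric(length(grid))
  zero_den <- den2 <= 0
  q[!zero_den] <- num[!zero_den] / sqrt(den2[!zero_den])
  q[zero_den & num == 0] <- 0
  degenerate <- zero_den & num > 0
  if (any(degenerate)) {
    warning(sprintf("%d wavelength(s) with zero variance but differing means masked",
                    sum(degenerate)))
    q[degenerate] <- NA_real_
  }
  if (all(is.na(q)))
    stop("degenerate input: Q undefined at every wavelength", call. = FALSE)
  structure(list(wavelengths = grid, q = q,
                 n_norm = length(norm_spectra), n_les = length(les_spectra)),
            class = "q_profile")
}

#' @export
print.q_profile <- function(x, ...) {
  cat(sprintf("<q_profile> %d wavelengths, %d intact vs %d lesion spectra, max Q = %.3g\n",
              length(x$wavelengths), x$n_norm, x$n_les, max(x$q, na.rm = TRUE)))
  invisible(x)
}

#' Informative wavelength subranges
#'
#' @param bands Two-column matrix (or list of length-2 vectors) of
#'   \code{[lambda_lo, lambda_hi]} intervals in nm.
#' @param qth Threshold the bands were derived with (\code{NA} if fixed by
#'   hand).
#' @param min_width Minimum band width used, nm.
#' @return An object of class \code{band_set}.
#' @export
band_set <- function(bands, qth = NA_real_, min_width = 0) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  if (is.null(bands) || length(bands) == 0L)
    bands <- matrix(numeric(0), ncol = 2L)
  bands <- matrix(as.numeric(bands), ncol = 2L,
                  dimnames = list(NULL, c("lambda_lo", "lambda_hi")))
  if (nrow(bands) > 0) {
    if (any(bands[, 2] < bands[, 1])) stop("band upper limit below lower limit")
    o <- order(bands[, 1])
    bands <- bands[o, , drop = FALSE]
    if (nrow(bands) > 1 && any(bands[-1, 1] <= bands[-nrow(bands), 2]))
      stop("bands must be disjoint")
  }
  structure(list(bands = bands, qth = qth, min_width = min_width),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d band(s), qth = %s\n", nrow(x$bands),
              format(x$qth)))
  if (nrow(x$bands) > 0)
    cat(paste(sprintf("  [%g, %g] nm", x$bands[, 1], x$bands[, 2]),
              collapse = "\n"), "\n")
  invisible(x)
}

#' @export
length.band_set <- function(x) nrow(x$bands)

#' Threshold a Q profile into informative subranges
#'
#' Maximal runs of consecutive grid points with \code{Q > qth} become closed
#' nm intervals; wavelength subranges below the threshold are excluded. Runs
#' narrower than \code{min_width} nm are dropped as single-point noise
#' crossings. \code{NA} (masked) profile points count as below threshold.
#'
#' @param profile A [q_profile()].
#' @param qth Positive threshold on Q.
#' @param min_width Minimum band width, nm; default 5.
#' @return A [band_set()] (possibly empty).
#' @export
bands_from_threshold <- function(profile, qth, min_width = 5) {
  if (!is.numeric(qth) || length(qth) != 1L || qth <= 0)
    stop("qth must be a single positive number", call. = FALSE)
  above <- !is.na(profile$q) & profile$q > qth
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  w <- profile$wavelengths
  iv <- lapply(keep, function(i) c(w[starts[i]], w[ends[i]]))
  iv <- Filter(function(b) (b[2] - b[1]) >= min_width, iv)
  band_set(iv, qth = qth, min_width = min_width)
}

#' Prune bands by principal-component loadings
#'
#' Fits a centered (unscaled) PCA on the band-area features, retains the
#' minimal number of components whose cumulative explained variance reaches
#' \code{variance_target}, scores each band by its loading contribution to
#' the leading components (at most the first two, fewer when one component
#' already reaches the target --- the loading-plot convention), and drops the
#' \code{k_drop} bands with the smallest contribution.
#'
#' @param features A [build_feature_matrix()] result.
#' @param variance_target Fraction of variance to cover, in (0, 1]; default
#'   0.95.
#' @param k_drop How many minimal-contribution bands to drop.
#' @param contribution \code{"max_abs"} (default): max |loading| over the
#'   leading PCs; \code{"sumsq"}: sum of squared loadings over them.
#' @return List: \code{band_set} (pruned), \code{report} (per-band loadings
#'   and the drop decision), \code{n_components}, \code{explained}.
#' @export
pca_prune_bands <- function(features, variance_target = 0.95, k_drop = 1L,
                            contribution = c("max_abs", "sumsq")) {
  contribution <- match.arg(contribution)
  x <- features$x
  if (ncol(x) < 2L) stop("need at least 2 feature columns", call. = FALSE)
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]", call. = FALSE)
  if (k_drop >= ncol(x))
    stop("k_drop must be smaller than the number of bands", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- cumsum(p$sdev^2) / sum(p$sdev^2)
  n_comp <- which(expl >= variance_target - 1e-12)[1L]
  n_load <- max(1L, min(2L, n_comp, ncol(p$rotation)))
  load <- p$rotation[, seq_len(n_load), drop = FALSE]
  contrib <- if (contribution == "max_abs") apply(abs(load), 1L, max)
             else rowSums(load^2)
  drop_idx <- if (k_drop > 0) order(contrib)[seq_len(k_drop)] else integer(0)
  bs <- features$band_set
  keep <- setdiff(seq_len(nrow(bs$bands)), drop_idx)
  report <- data.frame(lambda_lo = bs$bands[, 1], lambda_hi = bs$bands[, 2],
                       pc1 = load[, 1],
                       pc2 = if (ncol(load) > 1) load[, 2] else NA_real_,
                       contribution = contrib,
                       dropped = seq_len(nrow(bs$bands)) %in% drop_idx)
  list(band_set = band_set(bs$bands[keep, , drop = FALSE], qth = bs$qth,
                           min_width = bs$min_width),
       report = report, n_components = n_comp, explained = expl)
}
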