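# CSV dialect: a commented metadata block (# key: value) followed by a header
# row "wavelength,m1,m2,..." and one row per wavelength. Self-describing files
# avoid sidecar/metadata mismatch.

#' Write a spectrum series to CSV
#'
#' Layout: \code{# key: value} metadata lines (patient_id, site_type, label,
#' optional lesion_type), then a column table with a \code{wavelength} column
#' and one column per repeated measurement.
#'
#' @param series A [spectrum_series()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- series$site
  writeLines(c(sprintf("# patient_id: %s", s$patient_id),
               sprintf("# site_type: %s", s$site_type),
               sprintf("# label: %s", s$label)), con)
  if (!is.null(s$lesion_type))
    writeLines(sprintf("# lesion_type: %s", s$lesion_type), con)
  m <- t(series$intensities)
  df <- data.frame(wavelength = series$wavelengths, m)
  names(df) <- c("wavelength", sprintf("m%d", seq_len(ncol(m))))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

parse_header_block <- function(lines) {
  meta <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      key <- trimws(substr(kv, 1, pos - 1))
      val <- trimws(substr(kv, pos + 1, nchar(kv)))
      meta[[key]] <- val
    }
  }
  meta
}

#' Read one spectrum series from CSV
#'
#' Inverse of [write_series()]. Wavelength monotonicity and intensity
#' non-negativity are validated on read.
#'
#' @param path CSV file path.
#' @return A [spectrum_series()].
#' @export
read_one_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  meta <- parse_header_block(lines[startsWith(lines, "#")])
  for (k in c("patient_id", "site_type", "label"))
    if (is.null(meta[[k]]))
      stop(sprintf("%s: metadata block lacks '%s'", path, k), call. = FALSE)
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  if (!"wavelength" %in% names(df))
    stop(sprintf("%s: no 'wavelength' column", path), call. = FALSE)
  mcols <- setdiff(names(df), "wavelength")
  if (length(mcols) == 0L)
    stop(sprintf("%s: no measurement columns", path), call. = FALSE)
  w <- as.numeric(df$wavelength)
  if (any(diff(w) <= 0))
    stop(sprintf("%s: wavelengths are not strictly increasing", path),
         call. = FALSE)
  m <- t(as.matrix(df[mcols]))
  dimnames(m) <- NULL
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("%s: negative intensity in measurement column %s, row %d",
                 path, mcols[neg[1, 1]], neg[1, 2]), call. = FALSE)
  site <- site_record(meta$patient_id, meta$site_type, meta$label,
                      meta$lesion_type)
  spectrum_series(w, m, site)
}

#' Read a cohort from a manifest
#'
#' The manifest (YAML or JSON) lists a \code{source} file and a vector of
#' \code{series} files, all in the CSV dialect of [write_series()]. Every
#' series is resampled onto \code{grid} on load so the cohort shares one
#' analysis grid.
#'
#' @param path Manifest path (.yaml/.yml or .json).
#' @param grid Analysis grid; default [canonical_grid()].
#' @return A [drs_cohort()].
#' @export
read_cohort <- function(path, grid = canonical_grid()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  man <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(man$source) || is.null(man$series))
    stop("manifest must list 'source' and 'series' paths", call. = FALSE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  src <- resample_to_grid(read_one_series(resolve(man$source)), grid)
  series <- lapply(unlist(man$series), function(p)
    resample_to_grid(read_one_series(resolve(p)), grid))
  drs_cohort(series, src)
}

#' Write a cohort to a directory with a manifest
#'
#' @param cohort A [drs_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$series))
  for (i in seq_along(cohort$series)) {
    s <- cohort$series[[i]]
    files[i] <- sprintf("series_%03d_%s_%s.csv", i, s$site$patient_id,
                        s$site$label)
    write_series(s, file.path(dir, files[i]))
  }
  write_series(cohort$source, file.path(dir, "source.csv"))
  man <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(source = "source.csv", series = as.list(files)), man)
  invisible(man)
}
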