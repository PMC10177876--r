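cv_methods <- c("DT", "DA", "LR", "NKB", "SVM", "KNN", "RF")

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed < 2^31 from a master seed and stream indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

#' Class-conditional confusion frequencies
#'
#' Relative frequencies of the four classification outcomes, conditioned on
#' the true class: within the lesion class \code{n_tp + n_fn = 1}, within the
#' intact class \code{n_tn + n_fp = 1}.
#'
#' @param truth,pred Factors (or vectors) with levels intact/lesion.
#' @return An object of class \code{confusion_frequencies}.
#' @export
confusion_frequencies <- function(truth, pred) {
  truth <- factor(truth, levels = c("intact", "lesion"))
  pred <- factor(pred, levels = c("intact", "lesion"))
  stopifnot(length(truth) == length(pred))
  n_les <- sum(truth == "lesion")
  n_int <- sum(truth == "intact")
  structure(list(
    n_tp = if (n_les > 0) sum(truth == "lesion" & pred == "lesion") / n_les else NA_real_,
    n_fn = if (n_les > 0) sum(truth == "lesion" & pred == "intact") / n_les else NA_real_,
    n_tn = if (n_int > 0) sum(truth == "intact" & pred == "intact") / n_int else NA_real_,
    n_fp = if (n_int > 0) sum(truth == "intact" & pred == "lesion") / n_int else NA_real_),
    class = "confusion_frequencies")
}

#' Sensitivity and specificity from confusion frequencies
#'
#' \eqn{Se = N_{TP} / (N_{TP} + N_{FN})},
#' \eqn{Sp = N_{TN} / (N_{TN} + N_{FP})}.
#'
#' @param freq A [confusion_frequencies()] object or a named list with
#'   \code{n_tp}, \code{n_fn}, \code{n_tn}, \code{n_fp}.
#' @return Named numeric vector \code{c(se, sp)}.
#' @export
se_sp <- function(freq) {
  den_se <- freq$n_tp + freq$n_fn
  den_sp <- freq$n_tn + freq$n_fp
  if (is.na(den_se) || den_se <= 0)
    stop("sensitivity undefined: no lesion-class observations", call. = FALSE)
  if (is.na(den_sp) || den_sp <= 0)
    stop("specificity undefined: no intact-class observations", call. = FALSE)
  c(se = freq$n_tp / den_se, sp = freq$n_tn / den_sp)
}

# Fit the named classifier on (xtr, ytr) and predict labels for xte.
# Distance/margin methods (KNN, SVM, LR) see features z-scored with training
# statistics; tree methods and DA/NKB consume raw features. Constant training
# columns are dropped for every method.
fit_predict <- function(method, xtr, ytr, xte,
                        knn_k = 5L, svm_cost = 1, rf_ntree = 100L) {
  keep <- apply(xtr, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    maj <- names(which.max(table(ytr)))
    return(factor(rep(maj, nrow(xte)), levels = levels(ytr)))
  }
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  if (method %in% c("KNN", "SVM", "LR")) {
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2L, stats::sd)
    xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
    xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
  }
  dtr <- data.frame(xtr, check.names = FALSE)
  dte <- data.frame(xte, check.names = FALSE)
  names(dte) <- names(dtr) <- sprintf("f%d", seq_len(ncol(xtr)))
  dtr$y <- ytr
  pred <- switch(method,
    DT = {
      fit <- rpart::rpart(y ~ ., data = dtr, method = "class")
      stats::predict(fit, dte, type = "class")
    },
    DA = {
      fit <- MASS::lda(y ~ ., data = dtr)
      stats::predict(fit, dte)$class
    },
    LR = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dtr, family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, dte, type = "response"))
      factor(levels(ytr)[1L + (p > 0.5)], levels = levels(ytr))
    },
    NKB = {
      fit <- e1071::naiveBayes(y ~ ., data = dtr)
      stats::predict(fit, dte)
    },
    SVM = {
      fit <- e1071::svm(y ~ ., data = dtr, kernel = "radial",
                        cost = svm_cost, scale = FALSE)
      stats::predict(fit, dte)
    },
    KNN = {
      k <- min(knn_k, nrow(xtr))
      class::knn(xtr, xte, cl = ytr, k = k)
    },
    RF = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = rf_ntree)
      stats::predict(fit, xte)
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
  factor(as.character(pred), levels = levels(ytr))
}

# Stratified fold assignment: within each class, a random permutation is
# dealt into `folds` groups of near-equal size.
stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 1L) next
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))[
      seq_along(idx)]
  }
  assignment
}

# Fit a PCA on training features and return the transform applied to both
# sets, retaining the minimal component count reaching variance_target.
pca_transform <- function(xtr, xte, variance_target = 0.95) {
  keep <- apply(xtr, 2L, function(col) stats::sd(col) > 0)
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  if (ncol(xtr) == 0L) return(list(train = xtr, test = xte, n_components = 0L))
  p <- stats::prcomp(xtr, center = TRUE, scale. = TRUE)
  expl <- cumsum(p$sdev^2) / sum(p$sdev^2)
  n_comp <- which(expl >= variance_target - 1e-12)[1L]
  list(train = stats::predict(p, xtr)[, seq_len(n_comp), drop = FALSE],
       test = stats::predict(p, xte)[, seq_len(n_comp), drop = FALSE],
       n_components = n_comp)
}

#' Repeated stratified cross-validation of one classifier
#'
#' Stratified k-fold cross-validation (default 5 folds, 5 repeats) of one of
#' the benchmarked methods on a band-area [build_feature_matrix()]. Per fold
#' the model is fitted on the training rows only (with an optional PCA
#' transform, itself fitted on the training rows only, retaining components
#' up to the 95\% explained-variance target), held-out rows are predicted,
#' and class-conditional confusion frequencies, sensitivity, specificity and
#' accuracy are recorded; means and standard deviations over folds x repeats
#' are reported.
#'
#' @param features A [build_feature_matrix()] result.
#' @param method One of \code{"DT"} (decision tree), \code{"DA"} (linear
#'   discriminant analysis), \code{"LR"} (logistic regression), \code{"NKB"}
#'   (naive Bayes), \code{"SVM"} (RBF support vector machine), \code{"KNN"}
#'   (k nearest neighbours, k = 5), \code{"RF"} (random forest, 100 trees).
#' @param folds Number of folds, >= 2; default 5.
#' @param repeats Number of repeated fold cycles; default 5 (\code{repeats =
#'   1} reproduces a single 5-fold cycle).
#' @param seed Integer seed; the report is bit-identical across runs for a
#'   fixed seed.
#' @param pca Apply the per-fold PCA transform first.
#' @param variance_target PCA explained-variance target; default 0.95.
#' @return An object of class \code{cv_report} (also
#'   \code{as.data.frame}-able): per-metric mean and sd.
#' @export
run_cv <- function(features, method, folds = 5L, repeats = 5L, seed = 1L,
                   pca = FALSE, variance_target = 0.95) {
  method <- match.arg(toupper(method), cv_methods)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  x <- features$x
  y <- features$labels
  if (any(table(y) < 2L))
    stop("need at least 2 observations per class for stratified folds",
         call. = FALSE)
  metrics <- c("n_tp", "n_fn", "n_tn", "n_fp", "se", "sp", "accuracy")
  rec <- matrix(NA_real_, nrow = folds * repeats, ncol = length(metrics),
                dimnames = list(NULL, metrics))
  row <- 0L
  for (r in seq_len(repeats)) {
    assignment <- with_seed(derive_seed(seed, 101L, r),
                            stratified_folds(y, folds))
    for (f in seq_len(folds)) {
      row <- row + 1L
      te <- assignment == f
      if (all(te) || length(unique(y[!te])) < 2L)
        stop("stratification failure: a training fold lacks a class",
             call. = FALSE)
      xtr <- x[!te, , drop = FALSE]; ytr <- y[!te]
      xte <- x[te, , drop = FALSE]
      if (!any(te)) next
      if (pca) {
        tr <- pca_transform(xtr, xte, variance_target)
        xtr <- tr$train; xte <- tr$test
      }
      pred <- with_seed(derive_seed(seed, 202L, r, f),
                        fit_predict(method, xtr, ytr, xte))
      fr <- confusion_frequencies(y[te], pred)
      rec[row, c("n_tp", "n_fn", "n_tn", "n_fp")] <-
        c(fr$n_tp, fr$n_fn, fr$n_tn, fr$n_fp)
      if (!is.na(fr$n_tp) && !is.na(fr$n_tn)) {
        ss <- se_sp(fr)
        rec[row, c("se", "sp")] <- ss
      }
      rec[row, "accuracy"] <- mean(pred == y[te])
    }
  }
  structure(list(method = method, folds = folds, repeats = repeats,
                 seed = seed, pca = pca,
                 mean = colMeans(rec, na.rm = TRUE),
                 sd = apply(rec, 2L, stats::sd, na.rm = TRUE),
                 per_fold = rec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%d-fold x %d, pca = %s): accuracy %.3f +/- %.3f, Se %.3f, Sp %.3f\n",
              x$method, x$folds, x$repeats, x$pca,
              x$mean["accuracy"], x$sd["accuracy"], x$mean["se"], x$mean["sp"]))
  invisible(x)
}

#' @export
as.data.frame.cv_report <- function(x, ...) {
  data.frame(method = x$method, pca = x$pca, folds = x$folds,
             repeats = x$repeats, seed = x$seed,
             n_tp = x$mean["n_tp"], n_tp_sd = x$sd["n_tp"],
             n_fn = x$mean["n_fn"], n_fn_sd = x$sd["n_fn"],
             n_fp = x$mean["n_fp"], n_fp_sd = x$sd["n_fp"],
             n_tn = x$mean["n_tn"], n_tn_sd = x$sd["n_tn"],
             se = x$mean["se"], se_sd = x$sd["se"],
             sp = x$mean["sp"], sp_sd = x$sd["sp"],
             accuracy = x$mean["accuracy"], accuracy_sd = x$sd["accuracy"],
             row.names = NULL)
}

#' Full stage-1 benchmark over a threshold and method grid
#'
#' Runs the complete stage-1 pipeline on a cohort: source-normalized averaged
#' spectra, pooled Q profile, informative bands per threshold, band-area
#' features, and cross-validation of every requested method with and/or
#' without the PCA transform. Thresholds whose band set comes out empty are
#' reported as skipped rather than aborting the grid.
#'
#' @param cohort A [drs_cohort()].
#' @param qth_list Numeric vector of Q thresholds (e.g. \code{c(1.2, 1.0,
#'   0.7, 0.4)} for tongue tissue, \code{c(1.0, 0.8, 0.4)} for cheek).
#' @param methods Subset of the method panel; default all seven.
#' @param pca Logical vector: run without PCA (\code{FALSE}), with
#'   (\code{TRUE}), or both (\code{c(FALSE, TRUE)}).
#' @param site_type Restrict to one anatomical site (\code{NULL} keeps all).
#' @param min_width Minimum band width, nm.
#' @param folds,repeats,seed Cross-validation parameters, see [run_cv()].
#' @return List: \code{report} (one data.frame row per method x qth x pca,
#'   with a \code{skipped} flag), \code{profile} (the pooled [q_profile()]),
#'   \code{bands} (named list of [band_set()] per threshold).
#' @export
benchmark_grid <- function(cohort, qth_list, methods = cv_methods,
                           pca = c(FALSE, TRUE), site_type = NULL,
                           min_width = 5, folds = 5L, repeats = 5L,
                           seed = 1L) {
  methods <- match.arg(toupper(methods), cv_methods, several.ok = TRUE)
  series <- cohort$series
  if (!is.null(site_type))
    series <- Filter(function(s) s$site$site_type == site_type, series)
  if (length(series) == 0L) stop("no series for the requested site type",
                                 call. = FALSE)
  sub <- drs_cohort(series, cohort$source)
  spectra <- cohort_mean_spectra(sub)
  labs <- vapply(spectra, function(sp) sp$site$label, "")
  if (!any(labs == "intact") || !any(labs == "lesion"))
    stop("cohort must contain both intact and lesion series", call. = FALSE)
  profile <- q_profile(spectra[labs == "intact"], spectra[labs == "lesion"])
  rows <- list()
  bands_out <- list()
  for (qth in qth_list) {
    bands <- bands_from_threshold(profile, qth, min_width)
    bands_out[[format(qth)]] <- bands
    for (use_pca in pca) for (m in methods) {
      if (nrow(bands$bands) == 0L ||
          (use_pca && nrow(bands$bands) < 2L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          qth = qth, method = m, pca = use_pca, skipped = TRUE,
          n_bands = nrow(bands$bands))
        next
      }
      feats <- build_feature_matrix(spectra, bands)
      rep <- run_cv(feats, m, folds = folds, repeats = repeats,
                    seed = seed, pca = use_pca)
      df <- as.data.frame(rep)
      df$qth <- qth
      df$skipped <- FALSE
      df$n_bands <- nrow(bands$bands)
      rows[[length(rows) + 1L]] <- df
    }
  }
  report <- do.call(rbind, lapply(rows, function(d) {
    need <- c("qth", "method", "pca", "skipped", "n_bands",
              "n_tp", "n_tp_sd", "n_fn", "n_fn_sd", "n_fp", "n_fp_sd",
              "n_tn", "n_tn_sd", "se", "se_sd", "sp", "sp_sd",
              "accuracy", "accuracy_sd")
    for (col in setdiff(need, names(d))) d[[col]] <- NA_real_
    d[need]
  }))
  list(report = report, profile = profile, bands = bands_out)
}
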