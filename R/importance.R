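#' Per-wavelength permutation importance
#'
#' Global interpretability for spectral classifiers: for each wavelength
#' the intensity column is shuffled across spectra (`n_repeats` fresh
#' permutations), accuracy is recomputed, and the importance is the drop
#' from the unpermuted baseline accuracy (percentage points; slightly
#' negative values are permutation noise). Works with a single
#' [da_train()] model or a [da_ensemble()] (majority-vote accuracy).
#'
#' @param predictor A `da_model` or `da_ensemble`.
#' @param ds A [spectra] object with at least 2 spectra.
#' @param truths True classes; defaults to `ds$meta$allergen_class`.
#' @param n_repeats Permutations per wavelength (default 10).
#' @param seed Integer seed for the permutations.
#' @return An object of class `importance_profile`: data frame with
#'   columns `wavelength`, `importance` (percentage points), plus
#'   attributes `baseline_accuracy` and `n_repeats`.
#' @export
permutation_importance <- function(predictor, ds, truths = NULL,
                                   n_repeats = 10, seed = 1) {
  stopifnot(inherits(ds, "spectra"), n_repeats >= 1)
  if (n_spectra(ds) < 2)
    stop("permutation importance needs at least 2 spectra")
  if (is.null(truths)) truths <- ds$meta$allergen_class
  pred_fun <- if (inherits(predictor, "da_ensemble")) {
    function(X) predict(predictor, X)$predicted_class
  } else if (inherits(predictor, "da_model")) {
    function(X) predict(predictor, X, type = "class")
  } else stop("predictor must be a da_model or da_ensemble")
  X <- ds$intensity
  n <- nrow(X)
  baseline <- 100 * mean(pred_fun(X) == truths)
  local_seed(seed)
  imp <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    acc <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      Xp <- X
      Xp[, j] <- X[sample.int(n), j]
      acc[r] <- 100 * mean(pred_fun(Xp) == truths)
    }
    imp[j] <- baseline - mean(acc)
  }
  structure(data.frame(wavelength = ds$wavelengths, importance = imp),
            baseline_accuracy = baseline, n_repeats = n_repeats,
            seed = seed,
            class = c("importance_profile", "data.frame"))
}

#' Extract ranked contiguous important wavelength ranges
#'
#' Grid points whose importance exceeds `mean + threshold_sd * sd` (over
#' all points) are merged into maximal contiguous runs; runs narrower than
#' `min_width` nm are dropped and the rest are ranked by descending mean
#' importance. Runs never span gaps in the grid (such as the 1950 to
#' 2000 nm gap between the two sensors) because contiguity requires 1 nm
#' steps.
#'
#' @param profile An [permutation_importance()] profile.
#' @param threshold_sd Threshold in standard deviations above the mean
#'   importance (default 2).
#' @param min_width Minimum range width in nm (default 5).
#' @return Data frame with columns `start_nm`, `end_nm`, `width_nm`,
#'   `mean_importance`, ordered most important first; zero rows when no
#'   point clears the threshold.
#' @export
extract_important_ranges <- function(profile, threshold_sd = 2,
                                     min_width = 5) {
  stopifnot(inherits(profile, "importance_profile"))
  imp <- profile$importance
  wl <- profile$wavelength
  thr <- mean(imp) + threshold_sd * stats::sd(imp)
  hot <- which(imp > thr)
  empty <- data.frame(start_nm = numeric(0), end_nm = numeric(0),
                      width_nm = numeric(0), mean_importance = numeric(0))
  if (length(hot) == 0) return(empty)
  # split hot points into runs contiguous in both index and wavelength
  breaks <- c(0, which(diff(hot) != 1 | diff(wl[hot]) != 1), length(hot))
  rows <- list()
  for (k in seq_len(length(breaks) - 1)) {
    run <- hot[(breaks[k] + 1):breaks[k + 1]]
    width <- wl[run[length(run)]] - wl[run[1]] + 1
    if (width < min_width) next
    rows[[length(rows) + 1]] <- data.frame(
      start_nm = wl[run[1]], end_nm = wl[run[length(run)]],
      width_nm = width, mean_importance = mean(imp[run]))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_importance), ]
  rownames(out) <- NULL
  out
}

#' Plot a permutation-importance profile
#'
#' @param x An `importance_profile`.
#' @param ranges Optional output of [extract_important_ranges()] to shade.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.importance_profile <- function(x, ranges = NULL, ...) {
  graphics::plot(x$wavelength, x$importance, type = "h",
                 xlab = "wavelength (nm)",
                 ylab = "accuracy drop (percentage points)",
                 main = "Permutation wavelength importance", ...)
  if (!is.null(ranges) && nrow(ranges)) {
    for (k in seq_len(nrow(ranges)))
      graphics::rect(ranges$start_nm[k], graphics::par("usr")[3],
                     ranges$end_nm[k], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  invisible(x)
}
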