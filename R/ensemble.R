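#' Train a deep ensemble of domain-adaptation models
#'
#' Trains `n_models` models that differ only in their seeds
#' (`seed, seed + 1, ...`), exploiting random weight initialization to
#' produce diverse members; data and every other control parameter are
#' shared. Majority voting over members both raises accuracy and yields a
#' vote-share confidence score per prediction.
#'
#' @param split A `domain_split`.
#' @param method Training procedure passed to [da_train()].
#' @param control A [da_control()]; member `i` uses `control$seed + i - 1`.
#' @param n_models Ensemble size (default 5; at least 2).
#' @return An object of class `da_ensemble` (list of `da_model`s).
#' @export
da_ensemble <- function(split, method = c("tl", "dann", "sgan", "combined"),
                        control = da_control(), n_models = 5) {
  method <- match.arg(method)
  if (n_models < 2) stop("an ensemble needs at least 2 models")
  models <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    ctl_i <- control
    ctl_i$seed <- control$seed + i - 1L
    models[[i]] <- da_train(split, method, ctl_i)
  }
  structure(list(models = models, method = models[[1]]$method,
                 n_models = as.integer(n_models),
                 class_levels = models[[1]]$class_levels,
                 base_seed = control$seed),
            class = "da_ensemble")
}

#' @export
print.da_ensemble <- function(x, ...) {
  cat("Deep ensemble: ", x$n_models, " x ", x$method,
      " models (base seed ", x$base_seed, ")\n", sep = "")
  cat("  classes: ", paste(x$class_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ensemble predictions with vote-share confidence
#'
#' Each member votes a class per spectrum; the prediction is the majority
#' class (ties broken alphabetically) and the confidence is the majority
#' vote share, e.g. 3 of 5 members agreeing scores 0.6 and unanimity 1.0.
#'
#' @param object A [da_ensemble()].
#' @param newdata A [spectra] object or matrix on the members' grid.
#' @param ... Unused.
#' @return A data frame of class `ensemble_prediction` with columns
#'   `predicted_class`, `confidence`, and one `vote_<i>` column per member.
#' @export
predict.da_ensemble <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) newdata$intensity
       else as.matrix(newdata)
  votes <- vapply(object$models, function(m) predict(m, X, type = "class"),
                  character(nrow(X)))
  votes <- matrix(votes, ncol = object$n_models)
  lv <- object$class_levels
  counts <- vapply(lv, function(cl) rowSums(votes == cl),
                   numeric(nrow(votes)))
  counts <- matrix(counts, ncol = length(lv), dimnames = list(NULL, lv))
  # max.col "first" on alphabetically ordered levels = alphabetical tie-break
  win <- max.col(counts, ties.method = "first")
  out <- data.frame(predicted_class = lv[win],
                    confidence = counts[cbind(seq_len(nrow(counts)), win)] /
                      object$n_models)
  colnames(votes) <- paste0("vote_", seq_len(object$n_models))
  out <- cbind(out, as.data.frame(votes))
  class(out) <- c("ensemble_prediction", "data.frame")
  out
}

#' Accuracy-by-confidence report for ensemble predictions
#'
#' Cross-tabulates correct and incorrect predictions by occupied confidence
#' bin, with within-bin percentages and the overall accuracy — the layout
#' used to judge whether low-confidence predictions concentrate the errors.
#' Optionally flags the share of predictions at or above an alert
#' threshold.
#'
#' @param preds An `ensemble_prediction` (or data frame with
#'   `predicted_class` and `confidence`).
#' @param truths Character vector of true classes, same length.
#' @param threshold Confidence threshold for the alert summary
#'   (default 0.8).
#' @return A list of class `confidence_report`: `counts` (3 x bins+1 matrix
#'   with rows correct/incorrect/total), `percentages` (within-bin %),
#'   `overall_accuracy` (%), and `above_threshold` share.
#' @export
confidence_report <- function(preds, truths, threshold = 0.8) {
  if (nrow(preds) != length(truths))
    stop("predictions and truths have different lengths")
  bins <- sort(unique(preds$confidence))
  correct <- preds$predicted_class == truths
  counts <- sapply(bins, function(b) {
    in_bin <- preds$confidence == b
    c(correct = sum(correct & in_bin), incorrect = sum(!correct & in_bin))
  })
  counts <- matrix(counts, nrow = 2,
                   dimnames = list(c("correct", "incorrect"),
                                   format(bins)))
  counts <- rbind(counts, total = colSums(counts))
  pct <- sweep(counts[1:2, , drop = FALSE], 2, counts["total", ], "/") * 100
  pct[, counts["total", ] == 0] <- NA
  counts <- cbind(counts, total = rowSums(counts))
  overall <- 100 * counts["correct", "total"] / counts["total", "total"]
  structure(list(counts = counts, percentages = round(pct, 1),
                 overall_accuracy = round(overall, 2),
                 threshold = threshold,
                 above_threshold = mean(preds$confidence >= threshold)),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat("Ensemble confidence report (overall accuracy ",
      x$overall_accuracy, "%)\n", sep = "")
  cat("Counts by confidence bin:\n")
  print(x$counts)
  cat("Within-bin percentages:\n")
  print(x$percentages)
  cat(round(100 * x$above_threshold, 1), "% of predictions at confidence >= ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Breakdown of misclassified spectra by material and predicted class
#'
#' One row per (material, predicted class) pair among the errors, with the
#' true class, error frequency and the individual confidence scores sorted
#' in descending order.
#'
#' @param preds An `ensemble_prediction`.
#' @param truths True allergen classes.
#' @param material_ids Material identifier per spectrum.
#' @return Data frame with columns `material_id`, `true_class`,
#'   `predicted_class`, `frequency`, `confidences` (comma-separated,
#'   descending); empty when there are no errors.
#' @export
misclassification_breakdown <- function(preds, truths, material_ids) {
  if (nrow(preds) != length(truths) || length(truths) != length(material_ids))
    stop("predictions, truths and material_ids must have equal lengths")
  err <- preds$predicted_class != truths
  if (!any(err)) {
    return(data.frame(material_id = character(0), true_class = character(0),
                      predicted_class = character(0), frequency = integer(0),
                      confidences = character(0)))
  }
  d <- data.frame(material_id = material_ids[err],
                  true_class = truths[err],
                  predicted_class = preds$predicted_class[err],
                  confidence = preds$confidence[err])
  key <- paste(d$material_id, d$predicted_class, sep = " -> ")
  rows <- lapply(sort(unique(key)), function(k) {
    dk <- d[key == k, ]
    data.frame(material_id = dk$material_id[1],
               true_class = dk$true_class[1],
               predicted_class = dk$predicted_class[1],
               frequency = nrow(dk),
               confidences = paste(format(sort(dk$confidence,
                                               decreasing = TRUE)),
                                   collapse = ", "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
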