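#' Classification accuracy in percent
#'
#' @param preds Predicted class labels.
#' @param truths True class labels, same length, non-empty.
#' @return `100 * correct / total`, rounded to 2 decimals.
#' @export
#' @examples
#' accuracy(c("a", "b", "b"), c("a", "b", "a"))  # 66.67
accuracy <- function(preds, truths) {
  if (length(preds) == 0) stop("empty prediction vector")
  if (length(preds) != length(truths))
    stop("predictions and truths have different lengths")
  round(100 * mean(preds == truths), 2)
}

#' Run the method x speed x sensor x labelled experiment grid
#'
#' For every requested combination, builds the domain split from the
#' matching dataset pair, trains the method, and scores accuracy on the
#' held-out moving-condition test set. Cell seeds are derived
#' deterministically from `base_seed` so any cell can be reproduced in
#' isolation. A missing dataset or a failed fit marks the cell failed
#' (with the reason) and the run continues.
#'
#' @param datasets Nested named list: `datasets[[sensor]][[speed]]` is a
#'   list with `spectra` elements `static` and `moving` (as returned by
#'   [simulate_domain_pair()]).
#' @param methods Subset of `c("combined", "sgan", "dann", "tl")`.
#' @param speeds Subset of `c("slow", "medium", "fast")`.
#' @param sensors Subset of `c("both", "S2.0", "S2.5")`.
#' @param labelled Subset of `c("none", "single")`: labelled target
#'   instances per material-brand unit (0 or 1).
#' @param control A [da_control()]; its seed is the grid's base seed.
#' @return Object of class `experiment_grid`: a data frame with one row
#'   per cell (`method`, `sensor`, `speed`, `labelled`, `accuracy`,
#'   `seed`, `status`, `reason`).
#' @export
run_experiment_grid <- function(datasets,
                                methods = c("combined", "sgan", "dann", "tl"),
                                speeds = c("slow", "medium", "fast"),
                                sensors = "both",
                                labelled = c("none", "single"),
                                control = da_control()) {
  methods <- match.arg(methods, several.ok = TRUE)
  speeds <- match.arg(speeds, c("slow", "medium", "fast"),
                      several.ok = TRUE)
  labelled <- match.arg(labelled, c("none", "single"), several.ok = TRUE)
  cells <- expand.grid(method = methods, sensor = sensors, speed = speeds,
                       labelled = labelled, stringsAsFactors = FALSE)
  cells$accuracy <- NA_real_
  cells$seed <- NA_integer_
  cells$status <- "ok"
  cells$reason <- ""
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    cell_seed <- control$seed + 101L * (i - 1L)
    cells$seed[i] <- cell_seed
    res <- tryCatch({
      pair <- datasets[[cell$sensor]][[cell$speed]]
      if (is.null(pair)) stop("no dataset for sensor ", cell$sensor,
                              ", speed ", cell$speed)
      split <- make_domain_split(pair$static, pair$moving,
                                 n_labelled_per_unit =
                                   if (cell$labelled == "single") 1 else 0,
                                 seed = cell_seed)
      ctl <- control
      ctl$seed <- cell_seed
      fit <- da_train(split, cell$method, ctl)
      accuracy(predict(fit, split$target_test),
               split$target_test$meta$allergen_class)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cells$status[i] <- "failed"
      cells$reason[i] <- conditionMessage(res)
    } else {
      cells$accuracy[i] <- res
    }
  }
  class(cells) <- c("experiment_grid", "data.frame")
  cells
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("Experiment grid (", nrow(x), " cells, ",
      sum(x$status == "ok"), " ok)\n", sep = "")
  print(format_grid(x))
  invisible(x)
}

# Accuracy matrix: rows = sensor x speed, columns = method x labelled.
format_grid <- function(x) {
  row_key <- paste(x$sensor, x$speed, sep = " / ")
  col_key <- paste(toupper(substr(x$method, 1, 8)), x$labelled, sep = ".")
  col_key <- sub("COMBINED", "SGAN+DANN", col_key)
  out <- matrix(NA_real_, length(unique(row_key)), length(unique(col_key)),
                dimnames = list(unique(row_key), unique(col_key)))
  for (i in seq_len(nrow(x)))
    out[row_key[i], col_key[i]] <- x$accuracy[i]
  out
}

#' Write an experiment grid as CSV plus a JSON summary
#'
#' @param grid An [run_experiment_grid()] result.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of the paths written.
#' @export
write_grid_results <- function(grid, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(grid), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(grid), json_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
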