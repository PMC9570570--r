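# Metadata columns every spectral table carries, in interchange order.
META_COLS <- c("material_id", "brand_id", "allergen_class", "domain_tag",
               "sensor_tag", "sample_id", "replicate_id")

ALLERGEN_CLASSES <- c("egg", "gluten", "gluten-free", "peanut", "tree nut")
DOMAIN_TAGS <- c("static", "slow", "medium", "fast")
SENSOR_TAGS <- c("S2.0", "S2.5", "both")

#' Material vocabulary: 19 agri-food powders over five allergen classes
#'
#' The study design covers 19 powder materials; wheat flour, gluten-free white
#' flour and almond flour are each sourced from three brands, giving 25
#' material-brand units in total.
#'
#' @return A data frame with columns `material_id`, `allergen_class` and
#'   `n_brands` (19 rows).
#' @export
#' @examples
#' m <- material_table()
#' sum(m$n_brands)  # 25 material-brand units
material_table <- function() {
  data.frame(
    material_id = c("spelt", "rye", "buckwheat", "oat", "barley", "brown",
                    "wheat", "wheat gluten",
                    "gluten-free white", "coconut", "tapioca", "corn", "rice",
                    "peanut", "peanut butter",
                    "almond",
                    "whole egg", "egg yolk", "egg white"),
    allergen_class = c(rep("gluten", 8),
                       rep("gluten-free", 5),
                       rep("peanut", 2),
                       "tree nut",
                       rep("egg", 3)),
    n_brands = c(rep(1L, 6), 3L, 1L,
                 3L, rep(1L, 4),
                 1L, 1L,
                 3L,
                 rep(1L, 3)),
    stringsAsFactors = FALSE
  )
}

#' Wavelength grid of an NIR sensor
#'
#' `"S2.0"` covers 1550--1950 nm and `"S2.5"` 2000--2450 nm, both at 1 nm
#' resolution; `"both"` is their 852-point concatenation (the 50 nm gap
#' between the sensors is a physical gap, not interpolated).
#'
#' @param sensor One of `"S2.0"`, `"S2.5"`, `"both"`.
#' @return Numeric vector of wavelengths in nm (length 401, 451 or 852).
#' @export
sensor_grid <- function(sensor = c("S2.0", "S2.5", "both")) {
  sensor <- match.arg(sensor)
  switch(sensor,
         "S2.0" = 1550:1950,
         "S2.5" = 2000:2450,
         "both" = c(1550:1950, 2000:2450))
}

#' Construct a spectral dataset
#'
#' A `spectra` object stores one intensity matrix (rows = spectra, columns =
#' wavelengths) together with per-spectrum metadata and the shared wavelength
#' grid. All member spectra share one grid and one sensor tag.
#'
#' @param intensity Numeric matrix, one row per spectrum.
#' @param meta Data frame with columns `material_id`, `brand_id`,
#'   `allergen_class`, `domain_tag`, `sample_id`, `replicate_id` (and
#'   optionally `sensor_tag`, which must be constant).
#' @param wavelengths Strictly increasing numeric grid in nm, one value per
#'   intensity column.
#' @param sensor Sensor tag; inferred from the grid when `NULL`.
#' @param validate Check metadata against the material vocabulary
#'   ([material_table()]). Default `TRUE`.
#' @return An object of class `spectra`.
#' @export
spectra <- function(intensity, meta, wavelengths, sensor = NULL,
                    validate = TRUE) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(meta) != nrow(intensity))
    stop("meta has ", nrow(meta), " rows but intensity has ", nrow(intensity))
  if (length(wavelengths) != ncol(intensity))
    stop("grid length ", length(wavelengths),
         " does not match ", ncol(intensity), " intensity columns")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (is.null(sensor)) sensor <- infer_sensor(wavelengths)
  if ("sensor_tag" %in% names(meta)) {
    tags <- unique(meta$sensor_tag)
    if (length(tags) > 1)
      stop("mixed sensor_tag values in one dataset: ",
           paste(tags, collapse = ", "))
  }
  meta$sensor_tag <- sensor
  miss <- setdiff(setdiff(META_COLS, "sensor_tag"), names(meta))
  if (length(miss))
    stop("missing metadata columns: ", paste(miss, collapse = ", "))
  meta <- meta[, META_COLS, drop = FALSE]
  meta$brand_id <- as.integer(meta$brand_id)
  meta$sample_id <- as.integer(meta$sample_id)
  meta$replicate_id <- as.integer(meta$replicate_id)
  rownames(meta) <- NULL
  dimnames(intensity) <- list(NULL, as.character(wavelengths))
  obj <- structure(list(intensity = intensity, meta = meta,
                        wavelengths = as.numeric(wavelengths),
                        sensor = sensor),
                   class = "spectra")
  if (validate) validate_spectra(obj)
  obj
}

infer_sensor <- function(wavelengths) {
  for (s in SENSOR_TAGS)
    if (length(wavelengths) == length(sensor_grid(s)) &&
        all(wavelengths == sensor_grid(s))) return(s)
  "custom"
}

validate_spectra <- function(x) {
  m <- x$meta
  bad <- !m$allergen_class %in% ALLERGEN_CLASSES
  if (any(bad))
    stop("unknown allergen class: ", paste(unique(m$allergen_class[bad]),
                                           collapse = ", "))
  bad <- !m$domain_tag %in% DOMAIN_TAGS
  if (any(bad))
    stop("unknown domain tag: ", paste(unique(m$domain_tag[bad]),
                                       collapse = ", "))
  vocab <- material_table()
  known <- m$material_id %in% vocab$material_id
  if (any(known)) {
    expected <- vocab$allergen_class[match(m$material_id[known],
                                           vocab$material_id)]
    wrong <- m$allergen_class[known] != expected
    if (any(wrong)) {
      i <- which(known)[which(wrong)[1]]
      stop("material '", m$material_id[i], "' is labelled '",
           m$allergen_class[i], "' but belongs to allergen class '",
           expected[which(wrong)[1]], "'")
    }
    nb <- vocab$n_brands[match(m$material_id[known], vocab$material_id)]
    over <- m$brand_id[known] > nb | m$brand_id[known] < 1
    if (any(over)) {
      i <- which(known)[which(over)[1]]
      stop("material '", m$material_id[i], "' has no brand ",
           m$brand_id[i])
    }
  }
  invisible(x)
}

#' @export
print.spectra <- function(x, ...) {
  cat("NIR spectral dataset: ", nrow(x$intensity), " spectra x ",
      length(x$wavelengths), " wavelengths (sensor ", x$sensor, ", ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm)\n", sep = "")
  cat("  classes: ", paste(sort(unique(x$meta$allergen_class)),
                           collapse = ", "), "\n", sep = "")
  cat("  domains: ", paste(unique(x$meta$domain_tag), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
`[.spectra` <- function(x, i, ...) {
  structure(list(intensity = x$intensity[i, , drop = FALSE],
                 meta = x$meta[i, , drop = FALSE],
                 wavelengths = x$wavelengths,
                 sensor = x$sensor),
            class = "spectra")
}

#' @export
dim.spectra <- function(x) dim(x$intensity)

#' Number of spectra in a dataset
#' @param x A `spectra` object.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(x) nrow(x$intensity)

#' Bind two spectral datasets row-wise
#' @param x,y `spectra` objects sharing a grid.
#' @return A `spectra` object.
#' @keywords internal
rbind_spectra <- function(x, y) {
  if (n_spectra(y) == 0) return(x)
  if (n_spectra(x) == 0) return(y)
  if (!identical(x$wavelengths, y$wavelengths))
    stop("cannot bind datasets with different grids")
  structure(list(intensity = rbind(x$intensity, y$intensity),
                 meta = rbind(x$meta, y$meta),
                 wavelengths = x$wavelengths, sensor = x$sensor),
            class = "spectra")
}

record_keys <- function(x) {
  with(x$meta, paste(material_id, brand_id, sample_id, replicate_id,
                     sep = "/"))
}

unit_keys <- function(x) {
  with(x$meta, paste(material_id, brand_id, sep = "/"))
}

#' Read a wide-format spectral table
#'
#' The interchange format is a wide CSV: the metadata columns
#' `material_id, brand_id, allergen_class, domain_tag, sensor_tag,
#' sample_id, replicate_id` followed by one numeric column per wavelength,
#' with integer-nm headers.
#'
#' @param path Path to a CSV file.
#' @param validate Validate metadata against the material vocabulary.
#' @return A [spectra] object.
#' @export
read_spectra_table <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(META_COLS, names(df))
  if (length(miss))
    stop("not a spectral table, missing columns: ",
         paste(miss, collapse = ", "))
  wl_cols <- setdiff(names(df), META_COLS)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) stop("non-numeric wavelength column header: ",
                      paste(wl_cols[is.na(wl)][1]))
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelength columns are not strictly increasing")
  intensity <- as.matrix(df[, wl_cols, drop = FALSE])
  if (!is.numeric(intensity)) stop("non-numeric intensity values")
  sensor <- unique(df$sensor_tag)
  if (length(sensor) != 1)
    stop("mixed sensor_tag values in one table")
  spectra(intensity, df[, META_COLS], wl, sensor = sensor,
          validate = validate)
}

#' Write a spectral dataset as a wide CSV table
#'
#' @param ds A [spectra] object (non-empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(ds, path) {
  stopifnot(inherits(ds, "spectra"))
  if (n_spectra(ds) == 0) stop("refusing to write an empty dataset")
  out <- cbind(ds$meta,
               as.data.frame(ds$intensity, check.names = FALSE))
  names(out) <- c(META_COLS, as.character(as.integer(ds$wavelengths)))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Concatenate measurements from the two NIR sensors
#'
#' Per (material, brand, sample, replicate, domain) key, the S2.0 and S2.5
#' intensity vectors are concatenated in grid order to give 852-feature
#' spectra with sensor tag `"both"`. Both inputs must cover exactly the
#' same keys.
#'
#' @param ds_s20 `spectra` on the S2.0 grid (1550--1950 nm).
#' @param ds_s25 `spectra` on the S2.5 grid (2000--2450 nm).
#' @return A `spectra` object on the combined 852-point grid.
#' @export
combine_sensors <- function(ds_s20, ds_s25) {
  stopifnot(inherits(ds_s20, "spectra"), inherits(ds_s25, "spectra"))
  if (ds_s20$sensor != "S2.0") stop("first argument must be an S2.0 dataset")
  if (ds_s25$sensor != "S2.5") stop("second argument must be an S2.5 dataset")
  key <- function(x) with(x$meta, paste(material_id, brand_id, sample_id,
                                        replicate_id, domain_tag, sep = "/"))
  k20 <- key(ds_s20); k25 <- key(ds_s25)
  if (anyDuplicated(k20)) stop("duplicate key in S2.0 dataset: ",
                               k20[duplicated(k20)][1])
  if (anyDuplicated(k25)) stop("duplicate key in S2.5 dataset: ",
                               k25[duplicated(k25)][1])
  only20 <- setdiff(k20, k25); only25 <- setdiff(k25, k20)
  if (length(only20)) stop("key missing from S2.5 dataset: ", only20[1])
  if (length(only25)) stop("key missing from S2.0 dataset: ", only25[1])
  idx <- match(k20, k25)
  spectra(cbind(ds_s20$intensity, ds_s25$intensity[idx, , drop = FALSE]),
          ds_s20$meta[, setdiff(META_COLS, "sensor_tag")],
          c(ds_s20$wavelengths, ds_s25$wavelengths), sensor = "both")
}

#' Build the source/target domain split
#'
#' All stationary spectra form the labelled source set. Per material-brand
#' unit the moving spectra are split half-and-half into an unlabelled
#' training pool and a held-out test set, stratified by sample so both
#' halves see every physical sample. With `n_labelled_per_unit = 1`, one
#' moving spectrum per unit is moved from the unlabelled pool into a small
#' labelled target set (chosen uniformly at random under `seed`).
#'
#' At the full study scale (1250 stationary + 1250 moving spectra per
#' sensor) this yields 1250 source, 625 unlabelled and 625 test spectra.
#'
#' @param static_ds `spectra` measured under stationary conditions.
#' @param moving_ds `spectra` measured under one moving condition, same grid.
#' @param n_labelled_per_unit 0 (default) or 1 labelled moving spectrum per
#'   material-brand unit.
#' @param seed Integer seed controlling the random halves.
#' @return An object of class `domain_split` with elements
#'   `source_labelled`, `target_labelled`, `target_unlabelled`,
#'   `target_test`, and the `seed`.
#' @export
make_domain_split <- function(static_ds, moving_ds, n_labelled_per_unit = 0,
                              seed = 1) {
  stopifnot(inherits(static_ds, "spectra"), inherits(moving_ds, "spectra"))
  if (!identical(static_ds$wavelengths, moving_ds$wavelengths))
    stop("static and moving datasets are on different grids")
  if (!n_labelled_per_unit %in% c(0, 1))
    stop("n_labelled_per_unit must be 0 or 1")
  units <- unit_keys(moving_ds)
  tab <- table(units)
  if (any(tab < 2)) stop("unit with fewer than 2 moving spectra: ",
                         names(tab)[tab < 2][1])
  if (any(tab %% 2 != 0))
    stop("moving replicate count must be even per unit; unit ",
         names(tab)[tab %% 2 != 0][1], " has ", tab[tab %% 2 != 0][1])
  local_seed(seed)
  unlab_idx <- integer(0); test_idx <- integer(0)
  for (u in sort(unique(units))) {
    iu <- which(units == u)
    # stratify by sample: alternate shuffled replicates within each sample,
    # balancing any odd remainders across the unit
    carry <- 0L
    for (s in sort(unique(moving_ds$meta$sample_id[iu]))) {
      is_ <- iu[moving_ds$meta$sample_id[iu] == s]
      is_ <- is_[sample.int(length(is_))]
      n_un <- length(is_) %/% 2L
      if (length(is_) %% 2L == 1L) {
        n_un <- n_un + carry
        carry <- 1L - carry
      }
      unlab_idx <- c(unlab_idx, is_[seq_len(n_un)])
      test_idx <- c(test_idx, is_[setdiff(seq_along(is_), seq_len(n_un))])
    }
  }
  lab_idx <- integer(0)
  if (n_labelled_per_unit == 1) {
    un_units <- unit_keys(moving_ds)[unlab_idx]
    for (u in sort(unique(un_units))) {
      pool <- unlab_idx[un_units == u]
      lab_idx <- c(lab_idx, pool[sample.int(length(pool), 1)])
    }
    unlab_idx <- setdiff(unlab_idx, lab_idx)
  }
  structure(list(source_labelled = static_ds,
                 target_labelled = moving_ds[lab_idx],
                 target_unlabelled = moving_ds[sort(unlab_idx)],
                 target_test = moving_ds[sort(test_idx)],
                 seed = seed),
            class = "domain_split")
}

#' @export
print.domain_split <- function(x, ...) {
  cat("Domain split (seed ", x$seed, ")\n", sep = "")
  cat("  source labelled:   ", n_spectra(x$source_labelled), " spectra\n",
      sep = "")
  cat("  target labelled:   ", n_spectra(x$target_labelled), " spectra\n",
      sep = "")
  cat("  target unlabelled: ", n_spectra(x$target_unlabelled), " spectra\n",
      sep = "")
  cat("  target test:       ", n_spectra(x$target_test), " spectra\n",
      sep = "")
  invisible(x)
}

#' Write a JSON manifest of a domain split
#'
#' Lists the record keys (material/brand/sample/replicate) of each subset
#' plus the seed, so a split can be audited or rebuilt.
#'
#' @param split A `domain_split`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "domain_split"))
  manifest <- list(seed = split$seed,
                   source_labelled = record_keys(split$source_labelled),
                   target_labelled = record_keys(split$target_labelled),
                   target_unlabelled = record_keys(split$target_unlabelled),
                   target_test = record_keys(split$target_test))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Set the RNG seed locally: the caller's RNG state is restored when the
# calling function exits.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  do.call(on.exit, list(bquote(restore_rng(.(old))), add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  invisible(NULL)
}
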