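test_that("sensor grids match the instrument ranges", {
  expect_equal(length(sensor_grid("S2.0")), 401)
  expect_equal(range(sensor_grid("S2.0")), c(1550, 1950))
  expect_equal(length(sensor_grid("S2.5")), 451)
  expect_equal(range(sensor_grid("S2.5")), c(2000, 2450))
  expect_equal(sensor_grid("both"),
               c(sensor_grid("S2.0"), sensor_grid("S2.5")))
})

test_that("material vocabulary has 19 materials in 5 classes, 25 units", {
  m <- material_table()
  expect_equal(nrow(m), 19)
  expect_setequal(unique(m$allergen_class),
                  c("gluten", "gluten-free", "peanut", "tree nut", "egg"))
  expect_equal(sum(m$n_brands), 25)
  expect_equal(m$n_brands[m$material_id %in%
                            c("wheat", "gluten-free white", "almond")],
               rep(3L, 3))
})

test_that("a written spectral table reads back identically", {
  pair <- small_pair(seed = 3, n_units = 4)
  ds <- pair$static
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(ds, path)
  ds2 <- read_spectra_table(path)
  expect_equal(ds2$wavelengths, ds$wavelengths)
  expect_equal(ds2$meta, ds$meta)
  expect_equal(ds2$intensity, ds$intensity, tolerance = 1e-12)
  expect_equal(n_spectra(ds2), n_spectra(ds))
})

test_that("reading validates grid monotonicity and class consistency", {
  # mislabelled material: oat is a gluten material, not egg
  ds <- small_pair(seed = 1, n_units = 4)$static
  ds$meta$material_id[1] <- "oat"
  ds$meta$allergen_class[1] <- "egg"
  path <- withr::local_tempfile(fileext = ".csv")
  out <- cbind(ds$meta, as.data.frame(ds$intensity, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  expect_error(read_spectra_table(path), "oat")

  # non-monotone wavelength headers
  out2 <- out
  names(out2)[c(8, 9)] <- names(out2)[c(9, 8)]
  utils::write.csv(out2, path, row.names = FALSE)
  expect_error(read_spectra_table(path), "increasing")
})

test_that("writing an empty dataset errors", {
  ds <- small_pair(seed = 1, n_units = 2)$static
  expect_error(write_spectra_table(ds[integer(0)], tempfile()), "empty")
})

test_that("combine_sensors concatenates matched keys and is invertible", {
  p20 <- small_pair(seed = 2, sensor = "S2.0", n_units = 3)
  p25 <- small_pair(seed = 2, sensor = "S2.5", n_units = 3)
  both <- combine_sensors(p20$static, p25$static)
  expect_equal(ncol(both$intensity), 852)
  expect_equal(both$sensor, "both")
  expect_equal(n_spectra(both), n_spectra(p20$static))
  # slicing the first 401 columns recovers the S2.0 intensities
  expect_equal(both$intensity[, 1:401, drop = FALSE],
               p20$static$intensity, ignore_attr = TRUE)
  # missing replicate is reported by key
  expect_error(combine_sensors(p20$static, p25$static[-1]), "missing")
  # duplicate key
  dup <- p25$static[c(1, seq_len(n_spectra(p25$static)))]
  expect_error(combine_sensors(p20$static, dup), "duplicate")
})

test_that("domain split conserves records, stratifies and is seeded", {
  pair <- small_pair(seed = 4, n_units = 6, n_samples = 2,
                     n_replicates = 4)
  sp <- make_domain_split(pair$static, pair$moving, 0, seed = 11)
  n_mv <- n_spectra(pair$moving)
  expect_equal(n_spectra(sp$target_unlabelled) + n_spectra(sp$target_test),
               n_mv)
  expect_equal(n_spectra(sp$target_labelled), 0)
  # disjointness by record key
  key <- function(x) paste(x$meta$material_id, x$meta$brand_id,
                           x$meta$sample_id, x$meta$replicate_id)
  expect_length(intersect(key(sp$target_unlabelled), key(sp$target_test)), 0)
  # both halves see every (unit, sample) stratum
  strat <- function(x) unique(paste(x$meta$material_id, x$meta$brand_id,
                                    x$meta$sample_id))
  expect_setequal(strat(sp$target_unlabelled), strat(pair$moving))
  expect_setequal(strat(sp$target_test), strat(pair$moving))
  # determinism
  sp2 <- make_domain_split(pair$static, pair$moving, 0, seed = 11)
  expect_identical(key(sp$target_test), key(sp2$target_test))
  sp3 <- make_domain_split(pair$static, pair$moving, 0, seed = 12)
  expect_false(identical(key(sp$target_test), key(sp3$target_test)))
})

test_that("single-labelled split takes one spectrum per unit from the pool", {
  pair <- small_pair(seed = 5, n_units = 6, n_samples = 2, n_replicates = 4)
  sp <- make_domain_split(pair$static, pair$moving, 1, seed = 3)
  expect_equal(n_spectra(sp$target_labelled), 6)
  units <- paste(sp$target_labelled$meta$material_id,
                 sp$target_labelled$meta$brand_id)
  expect_equal(anyDuplicated(units), 0L)
  expect_equal(n_spectra(sp$target_unlabelled) +
                 n_spectra(sp$target_labelled), n_spectra(sp$target_test))
  expect_error(make_domain_split(pair$static, pair$moving, 2, seed = 1),
               "0 or 1")
})

test_that("paper-scale split sizes are 1250/625/625", {
  lib <- material_library(0)
  expect_length(lib, 25)
  # sample-count bookkeeping only: splits need metadata, not real signal,
  # so simulate a cheap narrow grid by reusing unit metadata
  pair <- simulate_domain_pair(lib, "slow", n_samples = 5,
                               n_replicates = 10,
                               shift = motion_shift(sigma0 = 0),
                               sensor = "S2.0", seed = 0)
  expect_equal(n_spectra(pair$static), 1250)
  sp <- make_domain_split(pair$static, pair$moving, 0, seed = 1)
  expect_equal(n_spectra(sp$source_labelled), 1250)
  expect_equal(n_spectra(sp$target_unlabelled), 625)
  expect_equal(n_spectra(sp$target_test), 625)
  sp1 <- make_domain_split(pair$static, pair$moving, 1, seed = 1)
  expect_equal(n_spectra(sp1$target_labelled), 25)
  expect_equal(n_spectra(sp1$target_unlabelled), 600)
})

test_that("split manifest records subset keys and the seed", {
  sp <- small_split(seed = 6, n_units = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(sp, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$seed, 6)
  expect_length(m$target_test, n_spectra(sp$target_test))
  expect_length(m$source_labelled, n_spectra(sp$source_labelled))
})
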