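test_that("default library has 25 deterministic units over 5 classes", {
  lib <- material_library(0)
  expect_length(lib, 25)
  cls <- vapply(lib, `[[`, "", "allergen_class")
  expect_setequal(unique(cls),
                  c("gluten", "gluten-free", "peanut", "tree nut", "egg"))
  # class counts follow the material table (10 gluten units, 2 peanut ...)
  expect_equal(as.integer(table(cls)[c("gluten", "gluten-free", "peanut",
                                       "tree nut", "egg")]),
               c(10L, 7L, 2L, 3L, 3L))
  expect_identical(material_library(0), lib)
  expect_false(identical(material_library(1), lib))
})

test_that("gluten units carry a carbohydrate band in 1569-1604 nm", {
  lib <- material_library(0)
  for (u in lib[vapply(lib, `[[`, "", "allergen_class") == "gluten"]) {
    carb <- u$bands$center >= 1569 - 10 & u$bands$center <= 1604 + 10
    expect_true(any(carb & u$bands$amplitude > 0))
  }
})

test_that("band centers lie on the sensors' grids and amplitudes >= 0", {
  lib <- material_library(7)
  wl <- sensor_grid("both")
  for (u in lib) {
    expect_true(all(u$bands$amplitude >= 0))
    expect_true(all(u$bands$center >= min(wl) & u$bands$center <= max(wl)))
    expect_gte(nrow(u$bands), 1)
  }
})

test_that("zero-noise static simulation reproduces the template exactly", {
  lib <- material_library(2)
  sh <- motion_shift(sigma0 = 0)
  sp <- simulate_spectrum(lib[[4]], "static", sh, sensor = "S2.0")
  expect_equal(drop(sp$intensity),
               unit_template(lib[[4]], sensor_grid("S2.0")),
               ignore_attr = TRUE, tolerance = 0)
  expect_error(simulate_spectrum(lib[[4]], "warp", sh), "speed")
})

test_that("Monte-Carlo mean and variance match the closed forms", {
  # oracle: intensity = g*(template + off) + o + eps, eps ~ N(0,(s0*m)^2)
  lib <- material_library(3)
  unit <- lib[[10]]
  sh <- motion_shift(sigma0 = 0.01)
  wl <- sensor_grid("S2.0")
  g <- sh$gain[["fast"]]; o <- sh$offset[["fast"]]
  m <- sh$noise_mult[["fast"]]
  expected_mean <- g * unit_template(unit, wl) + o
  n <- 10000
  set.seed(99)
  draws <- matrix(0, n, length(wl))
  for (i in seq_len(n))
    draws[i, ] <- simulate_spectrum(unit, "fast", sh,
                                    sensor = "S2.0")$intensity
  se <- sh$sigma0 * m / sqrt(n)
  z <- abs(colMeans(draws) - expected_mean) / se
  # per-point z-scores: all within 4 se, at least 99% within 3 se
  expect_true(all(z < 4))
  expect_gte(mean(z < 3), 0.99)
  # per-point variance inside a chi-square 99% band
  v <- apply(draws, 2, stats::var)
  band <- stats::qchisq(c(0.005, 0.995), df = n - 1) / (n - 1)
  ratio <- v / (sh$sigma0 * m)^2
  expect_gt(mean(ratio > band[1] & ratio < band[2]), 0.98)
})

test_that("domain pair respects the samples-by-replicates design", {
  lib <- material_library(1)
  pair <- simulate_domain_pair(lib, "slow", n_samples = 1,
                               n_replicates = 1, sensor = "S2.0", seed = 2)
  expect_equal(n_spectra(pair$static), 25)
  expect_equal(n_spectra(pair$moving), 25)
  expect_equal(unique(pair$static$meta$domain_tag), "static")
  expect_equal(unique(pair$moving$meta$domain_tag), "slow")
  # deterministic from seed
  pair2 <- simulate_domain_pair(lib, "slow", n_samples = 1,
                                n_replicates = 1, sensor = "S2.0", seed = 2)
  expect_identical(pair$moving$intensity, pair2$moving$intensity)
  expect_error(simulate_domain_pair(list(), "slow"), "empty")
})

test_that("null shift makes static and moving distributionally identical", {
  lib <- material_library(4)[1:8]
  class(lib) <- "material_library"
  pair <- simulate_domain_pair(lib, "medium", n_samples = 3,
                               n_replicates = 5, shift = null_shift(),
                               sensor = "S2.0", seed = 5)
  p <- vapply(seq_along(pair$static$wavelengths), function(j) {
    stats::t.test(pair$static$intensity[, j],
                  pair$moving$intensity[, j])$p.value
  }, 0)
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("motion shift validates its invariants", {
  expect_error(motion_shift(noise_mult = c(slow = 3, medium = 2, fast = 4)),
               "nondecreasing")
  expect_error(motion_shift(noise_mult = c(slow = 0.5, medium = 1,
                                           fast = 1)), ">= 1")
  sh <- motion_shift()
  expect_equal(sh$gain[["static"]], 1)
  expect_equal(sh$offset[["static"]], 0)
  expect_equal(sh$noise_mult[["static"]], 1)
})

test_that("class separation is controllable by the separation dial", {
  # nearest-centroid classifier as an independent fixed probe
  nearest_centroid_acc <- function(train, test) {
    cls <- sort(unique(train$meta$allergen_class))
    cents <- t(vapply(cls, function(k)
      colMeans(train$intensity[train$meta$allergen_class == k, ,
                               drop = FALSE]),
      numeric(ncol(train$intensity))))
    d <- as.matrix(stats::dist(rbind(cents, test$intensity)))
    d <- d[-(seq_along(cls)), seq_along(cls), drop = FALSE]
    mean(cls[apply(d, 1, which.min)] == test$meta$allergen_class)
  }
  accs <- vapply(1:3, function(s) {
    vapply(c(0.1, 0.5, 1.5), function(sep) {
      lib <- material_library(s, separation = sep)
      pair <- simulate_domain_pair(lib, "slow", n_samples = 2,
                                   n_replicates = 2, sensor = "S2.0",
                                   seed = s)
      half <- seq_len(n_spectra(pair$static)) %% 2 == 0
      nearest_centroid_acc(pair$static[half], pair$static[!half])
    }, 0)
  }, numeric(3))
  expect_true(all(diff(rowMeans(accs)) >= 0))
})
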