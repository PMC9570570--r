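# Synthetic NIR spectra: Gaussian absorption-band mixtures over a linear
# baseline, with allergen-class band motifs anchored to the standard NIR
# assignments (carbohydrate O-H first overtone ~1569-1604 nm, long-chain
# fatty acid CH2 first overtone ~1725-1750 nm, water O-H ~1931-1951 nm,
# protein ~2111-2132 nm) plus a C-H combination band in the S2.5 range.

# class x motif base amplitudes (a.u.); rows in ALLERGEN_CLASSES order
motif_centers <- c(carbohydrate = 1586, fat = 1737, water = 1941,
                   protein = 2121, ch_comb = 2285)
motif_widths <- c(carbohydrate = 18, fat = 14, water = 12,
                  protein = 12, ch_comb = 26)
class_amplitudes <- function() {
  A <- rbind(
    "egg"         = c(0.08, 0.18, 0.30, 0.50, 0.18),
    "gluten"      = c(0.45, 0.10, 0.25, 0.20, 0.15),
    "gluten-free" = c(0.55, 0.08, 0.20, 0.08, 0.12),
    "peanut"      = c(0.15, 0.50, 0.15, 0.30, 0.25),
    "tree nut"    = c(0.20, 0.40, 0.12, 0.22, 0.30))
  colnames(A) <- names(motif_centers)
  A
}

unit_seed_for <- function(seed, i) {
  as.integer((as.double(seed) %% 1e6) * 1013 + 7919 * i) %% 2147483L + i
}

#' Default material library: 25 synthetic material-brand units
#'
#' Builds one spectral template per material-brand unit for the 19 powder
#' materials of [material_table()] (wheat, gluten-free white and almond
#' flours each in three brands, 25 units total). Units of the same allergen
#' class share the class's absorption-band motifs; each unit perturbs band
#' centers, widths and amplitudes and adds one minor unit-specific band, so
#' classes are separable while units within a class differ. Deterministic
#' from `seed`.
#'
#' @param seed Integer seed.
#' @param separation Scale factor on between-class amplitude differences.
#'   The default 0.35 is the frozen calibration under which a
#'   transfer-learning baseline trained on stationary spectra scores
#'   roughly 70--90% on moving spectra (source accuracy ~100%), so
#'   adaptation gains are measurable; larger values make classes easier
#'   to separate.
#' @return An object of class `material_library`: a list of 25 unit
#'   entries, each with `material_id`, `brand_id`, `allergen_class`,
#'   `bands` (data frame of center/width/amplitude), `baseline_intercept`,
#'   `baseline_slope` and `brand_offset`.
#' @export
material_library <- function(seed = 0, separation = 0.35) {
  vocab <- material_table()
  A <- class_amplitudes()
  Abar <- colMeans(A)
  units <- list()
  i <- 0L
  for (r in seq_len(nrow(vocab))) {
    for (b in seq_len(vocab$n_brands[r])) {
      i <- i + 1L
      set.seed(unit_seed_for(seed, i))
      cls <- vocab$allergen_class[r]
      amp <- Abar + separation * (A[cls, ] - Abar)
      amp <- pmax(amp * stats::runif(length(amp), 0.9, 1.1), 0)
      centers <- motif_centers + stats::runif(length(amp), -4, 4)
      widths <- motif_widths * stats::runif(length(amp), 0.9, 1.1)
      # one minor unit-specific band anywhere on either sensor grid
      extra_c <- sample(c(1560:1940, 2010:2440), 1)
      bands <- data.frame(
        center = c(centers, extra_c),
        width = c(widths, stats::runif(1, 10, 30)),
        amplitude = c(amp, stats::runif(1, 0.02, 0.07)),
        row.names = NULL)
      units[[i]] <- list(
        material_id = vocab$material_id[r],
        brand_id = b,
        allergen_class = cls,
        bands = bands,
        baseline_intercept = stats::runif(1, 0.15, 0.25),
        baseline_slope = stats::runif(1, -1e-4, 3e-4),
        brand_offset = 0.02 * (b - 1L))
    }
  }
  structure(units, class = "material_library", seed = seed,
            separation = separation)
}

#' @export
print.material_library <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "allergen_class")
  cat("Material library: ", length(x), " material-brand units, ",
      length(unique(cls)), " allergen classes (seed ",
      attr(x, "seed"), ")\n", sep = "")
  print(table(allergen_class = cls))
  invisible(x)
}

#' Motion-shift parameters for moving-sample acquisition
#'
#' Moving samples show speed-dependent changes in peak intensity and
#' increased spectral noise relative to stationary acquisition. The
#' generator models these per speed as a multiplicative gain `g`, an
#' additive baseline offset `o` (a.u.) and a noise standard-deviation
#' multiplier `m >= 1` on the base replicate noise `sigma0`; the stationary
#' condition is fixed at `g = 1, o = 0, m = 1`. The defaults were
#' calibrated once so that a plain transfer-learning baseline trained on
#' stationary spectra scores roughly 70--90% on moving spectra while
#' source accuracy is ~100%, leaving measurable headroom for adaptation.
#'
#' @param sigma0 Base replicate noise standard deviation (a.u.).
#' @param gain Named gains per speed (`slow`, `medium`, `fast`).
#' @param offset Named additive offsets per speed (a.u.).
#' @param noise_mult Named noise multipliers per speed, nondecreasing with
#'   speed and `>= 1`.
#' @param sample_sd Standard deviation of the sample-level baseline offset
#'   shared by all replicates of one physical sample (a.u.).
#' @param unit_jitter Optional per-unit relative jitter on gain and offset
#'   (0 = every unit shifts identically, the default).
#' @return An object of class `motion_shift`.
#' @export
motion_shift <- function(sigma0 = 0.004,
                         gain = c(slow = 1.03, medium = 1.05, fast = 1.08),
                         offset = c(slow = 0.35, medium = 0.50, fast = 0.65),
                         noise_mult = c(slow = 2, medium = 2, fast = 3),
                         sample_sd = 0.01,
                         unit_jitter = 0) {
  speeds <- c("slow", "medium", "fast")
  stopifnot(all(speeds %in% names(gain)), all(speeds %in% names(offset)),
            all(speeds %in% names(noise_mult)))
  if (sigma0 < 0) stop("sigma0 must be nonnegative")
  nm <- noise_mult[speeds]
  if (any(nm < 1)) stop("noise multipliers must be >= 1")
  if (any(diff(nm) < 0))
    stop("noise multiplier must be nondecreasing with speed")
  structure(list(sigma0 = sigma0,
                 gain = c(static = 1, gain[speeds]),
                 offset = c(static = 0, offset[speeds]),
                 noise_mult = c(static = 1, nm),
                 sample_sd = sample_sd,
                 unit_jitter = unit_jitter),
            class = "motion_shift")
}

#' Noise-free spectral template of one material-brand unit
#'
#' Linear baseline plus the unit's Gaussian bands, before any motion shift,
#' sample offset or noise.
#'
#' @param unit One entry of a [material_library()].
#' @param wavelengths Numeric grid in nm.
#' @return Numeric intensity vector.
#' @export
unit_template <- function(unit, wavelengths) {
  y <- unit$baseline_intercept + unit$brand_offset +
    unit$baseline_slope * (wavelengths - 1550)
  for (k in seq_len(nrow(unit$bands))) {
    bd <- unit$bands[k, ]
    y <- y + bd$amplitude * exp(-(wavelengths - bd$center)^2 /
                                  (2 * bd$width^2))
  }
  y
}

#' Simulate one spectrum of a material-brand unit
#'
#' The intensity model is
#' `g_s * (template(lambda) + sample_offset) + o_s + eps(lambda)` with
#' `eps ~ Normal(0, (sigma0 * m_s)^2)` independent per grid point, where
#' `(g_s, o_s, m_s)` are the motion-shift parameters of `speed`. Noise is
#' drawn from the current RNG stream; seed upstream for reproducibility.
#'
#' @param unit One entry of a [material_library()].
#' @param speed One of `"static"`, `"slow"`, `"medium"`, `"fast"`.
#' @param shift A [motion_shift()] object.
#' @param sensor Sensor grid to simulate on.
#' @param sample_offset Sample-level additive offset (a.u.).
#' @param sample_id,replicate_id Metadata identifiers.
#' @return A one-row [spectra] object.
#' @export
simulate_spectrum <- function(unit, speed = "static", shift = motion_shift(),
                              sensor = c("both", "S2.0", "S2.5"),
                              sample_offset = 0, sample_id = 1,
                              replicate_id = 1) {
  sensor <- match.arg(sensor)
  if (!speed %in% DOMAIN_TAGS) stop("unknown speed tag: ", speed)
  wl <- sensor_grid(sensor)
  g <- shift$gain[[speed]]
  o <- shift$offset[[speed]]
  m <- shift$noise_mult[[speed]]
  y <- g * (unit_template(unit, wl) + sample_offset) + o
  if (shift$sigma0 > 0)
    y <- y + stats::rnorm(length(wl), sd = shift$sigma0 * m)
  spectra(matrix(y, 1), data.frame(material_id = unit$material_id,
                                   brand_id = unit$brand_id,
                                   allergen_class = unit$allergen_class,
                                   domain_tag = speed,
                                   sample_id = sample_id,
                                   replicate_id = replicate_id),
          wl, sensor = sensor)
}

#' Simulate a paired stationary/moving study
#'
#' Emulates the study design: `n_samples` physical samples per
#' material-brand unit, `n_replicates` spectra per sample, measured once
#' stationary and once at the requested speed. Sample-level baseline
#' offsets are drawn per (unit, sample) and shared between the two
#' conditions (the same physical sample is measured twice); replicate
#' noise is independent. Each unit uses a sub-seed derived from `seed`, so
#' single units are reproducible in isolation. At the full study scale
#' (5 samples x 10 replicates) each condition yields 1250 spectra.
#'
#' @param library A [material_library()].
#' @param speed Moving condition: `"slow"`, `"medium"` or `"fast"`.
#' @param n_samples Physical samples per unit (default 5).
#' @param n_replicates Spectra per sample (default 10).
#' @param shift A [motion_shift()].
#' @param sensor Sensor grid.
#' @param seed Integer seed.
#' @return List with `spectra` elements `static` and `moving`.
#' @export
simulate_domain_pair <- function(library, speed = "medium", n_samples = 5,
                                 n_replicates = 10, shift = motion_shift(),
                                 sensor = c("both", "S2.0", "S2.5"),
                                 seed = 1) {
  sensor <- match.arg(sensor)
  if (length(library) == 0) stop("empty material library")
  if (!speed %in% c("slow", "medium", "fast"))
    stop("speed must be slow, medium or fast")
  stopifnot(n_samples >= 1, n_replicates >= 1)
  wl <- sensor_grid(sensor)
  p <- length(wl)
  n_per_unit <- n_samples * n_replicates
  n_total <- n_per_unit * length(library)
  X_st <- matrix(0, n_total, p)
  X_mv <- matrix(0, n_total, p)
  meta <- vector("list", length(library))
  local_seed(seed)
  for (i in seq_along(library)) {
    unit <- library[[i]]
    set.seed(unit_seed_for(seed, i) + 1L)
    offs <- stats::rnorm(n_samples, sd = shift$sample_sd)
    g <- shift$gain[[speed]]
    o <- shift$offset[[speed]]
    if (shift$unit_jitter > 0) {
      jz <- stats::rnorm(2)
      g <- g * (1 + shift$unit_jitter * jz[1])
      o <- o * (1 + shift$unit_jitter * jz[2])
    }
    m <- shift$noise_mult[[speed]]
    tmpl <- unit_template(unit, wl)
    row0 <- (i - 1L) * n_per_unit
    for (s in seq_len(n_samples)) {
      base <- tmpl + offs[s]
      for (r in seq_len(n_replicates)) {
        row <- row0 + (s - 1L) * n_replicates + r
        X_st[row, ] <- base +
          if (shift$sigma0 > 0) stats::rnorm(p, sd = shift$sigma0) else 0
        X_mv[row, ] <- g * base + o +
          if (shift$sigma0 > 0) stats::rnorm(p, sd = shift$sigma0 * m) else 0
      }
    }
    meta[[i]] <- data.frame(material_id = unit$material_id,
                            brand_id = unit$brand_id,
                            allergen_class = unit$allergen_class,
                            sample_id = rep(seq_len(n_samples),
                                            each = n_replicates),
                            replicate_id = rep(seq_len(n_replicates),
                                               n_samples))
  }
  meta <- do.call(rbind, meta)
  st_meta <- meta; st_meta$domain_tag <- "static"
  mv_meta <- meta; mv_meta$domain_tag <- speed
  list(static = spectra(X_st, st_meta, wl, sensor = sensor),
       moving = spectra(X_mv, mv_meta, wl, sensor = sensor))
}
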