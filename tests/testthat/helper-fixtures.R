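# Shared fixtures, generated in code. Heavy objects are built lazily and
# cached for the session so several test files can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small S2.0 dataset: a handful of units, few spectra, fast to simulate;
# units are taken round-robin across allergen classes so even tiny
# fixtures keep all five classes represented
small_pair <- function(seed = 1, sensor = "S2.0", n_units = 10,
                       n_samples = 2, n_replicates = 2, speed = "medium",
                       shift = motion_shift()) {
  lib <- material_library(seed)
  cls <- vapply(lib, `[[`, "", "allergen_class")
  rank_in_class <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  lib <- lib[order(rank_in_class, cls)][seq_len(n_units)]
  class(lib) <- "material_library"
  simulate_domain_pair(lib, speed, n_samples = n_samples,
                       n_replicates = n_replicates, shift = shift,
                       sensor = sensor, seed = seed)
}

small_split <- function(seed = 1, n_labelled = 0, ...) {
  pair <- small_pair(seed = seed, ...)
  make_domain_split(pair$static, pair$moving, n_labelled, seed = seed)
}

# a two-class library whose classes differ only inside one narrow planted
# band; used for the interpretability oracle. The band is kept ~1 grid
# point wide because per-wavelength permutation cannot expose a feature
# the model reads redundantly from many correlated columns.
planted_band_library <- function(seed, centre = 1715, width = 1,
                                 delta = 0.3) {
  base <- list(baseline_intercept = 0.2, baseline_slope = 1e-4,
               brand_offset = 0)
  unit <- function(material_id, cls, amp) {
    c(base, list(material_id = material_id, brand_id = 1L,
                 allergen_class = cls,
                 bands = data.frame(center = centre, width = width,
                                    amplitude = amp)))
  }
  lib <- list(unit("oat", "gluten", 0.1),
              unit("rice", "gluten-free", 0.1 + delta))
  class(lib) <- "material_library"
  attr(lib, "seed") <- seed
  lib
}

# motion shift with no gain/offset/noise change: moving == static in law
null_shift <- function() {
  motion_shift(gain = c(slow = 1, medium = 1, fast = 1),
               offset = c(slow = 0, medium = 0, fast = 0),
               noise_mult = c(slow = 1, medium = 1, fast = 1))
}

# noise-dominated mild shift on well-separated classes: the regime where
# ensemble errors are borderline cases rather than systematic, used for
# the confidence-calibration checks
calibration_shift <- function() {
  motion_shift(gain = c(slow = 1.05, medium = 1.10, fast = 1.12),
               offset = c(slow = 0.06, medium = 0.12, fast = 0.16),
               noise_mult = c(slow = 4, medium = 6, fast = 8))
}
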