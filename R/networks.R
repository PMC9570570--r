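#' Build the five-network suite for adversarial domain adaptation
#'
#' One shared feature extractor (four fully connected ReLU layers of 256,
#' 128, 64 and 32 units) feeds three single logistic-regression heads: the
#' allergen classifier (32 units to `n_classes`), a source-vs-target domain
#' discriminator (32 to 2) and a real-vs-generated discriminator (32 to 2).
#' A generator maps standard-normal latent vectors through five fully
#' connected layers (32, 64, 128, 256 units, then the spectrum length) to
#' fake spectra; its final layer is linear because intensities are
#' unbounded. Weights use fan-in scaled normal initialization, deterministic
#' from `seed`.
#'
#' @param input_dim Spectrum length: 401 (S2.0), 451 (S2.5) or 852 (both);
#'   other positive lengths are allowed for reduced fixtures.
#' @param n_classes Number of allergen classes (default 5).
#' @param latent_dim Generator input size (default 16).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `network_suite`.
#' @export
#' @examples
#' suite <- network_suite(401, seed = 1)
#' X <- matrix(rnorm(5 * 401), 5)
#' dim(suite_features(suite, X))     # 5 x 32
#' rowSums(suite_class_proba(suite, X))  # all 1
network_suite <- function(input_dim, n_classes = 5, latent_dim = 16,
                          seed = 1) {
  if (input_dim < 1 || n_classes < 2 || latent_dim < 1)
    stop("dimensions must be positive (and n_classes >= 2)")
  local_seed(seed)
  structure(list(
    feature_extractor = init_layers(c(input_dim, 256, 128, 64, 32)),
    classifier = init_layers(c(32, n_classes)),
    domain_discriminator = init_layers(c(32, 2)),
    realfake_discriminator = init_layers(c(32, 2)),
    generator = init_layers(c(latent_dim, 32, 64, 128, 256, input_dim)),
    input_dim = as.integer(input_dim),
    n_classes = as.integer(n_classes),
    latent_dim = as.integer(latent_dim),
    seed = seed
  ), class = "network_suite")
}

FE_ACTS <- rep("relu", 4)
HEAD_ACTS <- "linear"
GEN_ACTS <- c(rep("relu", 4), "linear")

#' @export
print.network_suite <- function(x, ...) {
  cat("Network suite (input ", x$input_dim, ", ", x$n_classes,
      " classes, latent ", x$latent_dim, ", seed ", x$seed, ")\n", sep = "")
  cat("  feature extractor: ", x$input_dim,
      " -> 256 -> 128 -> 64 -> 32 (ReLU)\n", sep = "")
  cat("  classifier / discriminators: logistic heads on the 32-unit",
      "features\n")
  cat("  generator: ", x$latent_dim, " -> 32 -> 64 -> 128 -> 256 -> ",
      x$input_dim, "\n", sep = "")
  invisible(x)
}

check_input <- function(suite, X) {
  X <- as.matrix(X)
  if (ncol(X) != suite$input_dim)
    stop("input has ", ncol(X), " features but the suite expects ",
         suite$input_dim)
  X
}

#' Shared 32-unit features of a spectrum batch
#' @param suite A [network_suite].
#' @param X Numeric matrix, one spectrum per row.
#' @return Matrix of 32 features per row.
#' @export
suite_features <- function(suite, X) {
  A <- forward_layers(suite$feature_extractor, FE_ACTS, check_input(suite, X))
  A[[length(A)]]
}

head_proba <- function(layers, feats) {
  softmax_rows(forward_layers(layers, HEAD_ACTS, feats)[[2]])
}

#' Class probabilities from the classifier head
#' @inheritParams suite_features
#' @return Matrix of `n_classes` probabilities per row (rows sum to 1).
#' @export
suite_class_proba <- function(suite, X) {
  head_proba(suite$classifier, suite_features(suite, X))
}

#' Domain (source vs target) probabilities from the domain discriminator
#' @inheritParams suite_features
#' @return Two-column probability matrix (source, target).
#' @export
suite_domain_proba <- function(suite, X) {
  p <- head_proba(suite$domain_discriminator, suite_features(suite, X))
  colnames(p) <- c("source", "target")
  p
}

#' Real-vs-generated probabilities from the real/fake discriminator
#' @inheritParams suite_features
#' @return Two-column probability matrix (real, fake).
#' @export
suite_realfake_proba <- function(suite, X) {
  p <- head_proba(suite$realfake_discriminator, suite_features(suite, X))
  colnames(p) <- c("real", "fake")
  p
}

#' Generate fake spectra from latent noise
#'
#' @param suite A [network_suite].
#' @param n Number of spectra to generate (draws latent standard normals
#'   from the current RNG stream), or supply `z` directly.
#' @param z Optional latent matrix (`n x latent_dim`).
#' @return Matrix of generated spectra (`n x input_dim`).
#' @export
suite_generate <- function(suite, n = 1, z = NULL) {
  if (is.null(z))
    z <- matrix(stats::rnorm(n * suite$latent_dim), n, suite$latent_dim)
  if (ncol(z) != suite$latent_dim)
    stop("latent input has ", ncol(z), " columns, expected ",
         suite$latent_dim)
  A <- forward_layers(suite$generator, GEN_ACTS, z)
  A[[length(A)]]
}
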