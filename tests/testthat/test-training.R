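test_that("adversarial transform matches its closed form", {
  expect_equal(adversarial_transform(1.0, eps = 0), -1)
  expect_equal(adversarial_transform(2.0, mode = "negation"), -2)
  expect_equal(adversarial_transform(0.5, eps = 0.5), -1)
  expect_error(adversarial_transform(-0.1), "nonnegative")
  # monotone increasing on (0, Inf); gradient magnitude decreasing, with
  # the step at L = 0.1 about 100x the step at L = 1.0
  L <- seq(0.05, 5, by = 0.05)
  tr <- adversarial_transform(L, eps = 0)
  expect_true(all(diff(tr) > 0))
  h <- 1e-6
  grad <- function(L) (adversarial_transform(L + h, eps = 0) -
                         adversarial_transform(L - h, eps = 0)) / (2 * h)
  g <- vapply(L, grad, 0)
  expect_true(all(diff(abs(g)) < 0))
  expect_equal(abs(grad(0.1)) / abs(grad(1.0)), 100, tolerance = 1e-3)
})

test_that("control validates its fields", {
  expect_error(da_control(batch_size = 0))
  expect_error(da_control(adversarial_eps = 0))
  expect_error(da_control(epochs = 0))
  ctl <- da_control(epochs = 5)
  expect_s3_class(ctl, "da_control")
  expect_equal(ctl$batch_size, 32L)
  expect_equal(ctl$learning_rate, 0.001)
})

test_that("transfer baseline fits labelled data and logs per-batch steps", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  fit <- da_train(sp, "tl", da_control(epochs = 600, seed = 1))
  expect_s3_class(fit, "da_model")
  expect_equal(fit$method, "TL")
  # the protocol's fit-to-train check: source training accuracy reaches 100%
  expect_equal(accuracy(predict(fit, sp$source_labelled),
                        sp$source_labelled$meta$allergen_class), 100)
  # bookkeeping: one logged iteration per mini-batch
  one <- da_train(sp, "tl", da_control(epochs = 1, seed = 1))
  expect_equal(nrow(one$loss_history),
               ceiling(n_spectra(sp$source_labelled) / 32))
  # determinism
  fit2 <- da_train(sp, "tl", da_control(epochs = 600, seed = 1))
  expect_identical(fit$suite$feature_extractor,
                   fit2$suite$feature_extractor)
})

test_that("trainers refuse degenerate splits", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  empty_unlab <- sp
  empty_unlab$target_unlabelled <- sp$target_unlabelled[integer(0)]
  expect_error(da_train(empty_unlab, "dann", da_control(epochs = 1)),
               "tl")
  empty_src <- sp
  empty_src$source_labelled <- sp$source_labelled[integer(0)]
  expect_error(da_train(empty_src, "tl", da_control(epochs = 1)), "empty")
})

test_that("loss histories carry the named sequential losses", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  ctl <- da_control(epochs = 2, seed = 3)
  h_dann <- da_train(sp, "dann", ctl)$loss_history
  expect_true(all(c("classification", "domain_disc_labelled",
                    "domain_confusion_labelled", "domain_disc_unlabelled",
                    "domain_confusion_unlabelled") %in% colnames(h_dann)))
  h_sgan <- da_train(sp, "sgan", ctl)$loss_history
  expect_true(all(c("classification", "realfake_real_labelled",
                    "realfake_fake", "generator",
                    "realfake_real_unlabelled") %in% colnames(h_sgan)))
  h_comb <- da_train(sp, "combined", ctl)$loss_history
  loss_cols <- setdiff(colnames(h_comb), c("epoch", "iteration"))
  expect_gte(length(loss_cols), 5)
  expect_true(all(stats::complete.cases(h_comb[, loss_cols])))
})

test_that("disabling adversarial branches reduces every method to TL", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  ctl_tl <- da_control(epochs = 30, seed = 5)
  base <- da_train(sp, "tl", ctl_tl)
  for (meth in c("dann", "sgan", "combined")) {
    ctl <- da_control(epochs = 30, seed = 5, adversarial = FALSE)
    fit <- da_train(sp, meth, ctl)
    expect_identical(fit$suite$feature_extractor,
                     base$suite$feature_extractor)
    expect_identical(fit$suite$classifier, base$suite$classifier)
  }
})

test_that("prediction outputs normalized probabilities equivariantly", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  fit <- cached("fit_tl40",
                da_train(sp, "tl", da_control(epochs = 40, seed = 2)))
  P <- predict(fit, sp$target_test, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_equal(colnames(P), fit$class_levels)
  # permuting rows permutes predictions identically
  idx <- rev(seq_len(n_spectra(sp$target_test)))
  lab <- predict(fit, sp$target_test, type = "class")
  lab_perm <- predict(fit, sp$target_test[idx], type = "class")
  expect_identical(lab_perm, lab[idx])
  expect_error(predict(fit, matrix(0, 2, 7)), "features")
})

test_that("DANN training runs and updates the domain discriminator", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  fit <- da_train(sp, "dann", da_control(epochs = 30, seed = 4))
  expect_equal(fit$method, "DANN")
  h <- fit$loss_history
  # discriminator losses move away from their initial value
  expect_false(isTRUE(all.equal(h$domain_disc_labelled[1],
                                utils::tail(h$domain_disc_labelled, 1))))
  # determinism under a fixed seed
  fit2 <- da_train(sp, "dann", da_control(epochs = 30, seed = 4))
  expect_identical(fit$suite$feature_extractor,
                   fit2$suite$feature_extractor)
})

test_that("SGAN generated batches have the grid shape and move toward the
          target domain", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  dists <- vapply(1:3, function(s) {
    ctl <- da_control(epochs = 400, seed = s)
    fit <- da_train(sp, "sgan", ctl)
    g_trained <- simulate(fit, 64, seed = 100 + s)
    expect_equal(dim(g_trained), c(64L, 401L))
    suite0 <- network_suite(401, latent_dim = ctl$latent_dim, seed = s)
    local({
      set.seed(100 + s)
      g_un <- suite_generate(suite0, 64)
      target_mean <- colMeans(sp$target_unlabelled$intensity)
      c(trained = sqrt(sum((colMeans(g_trained) - target_mean)^2)),
        untrained = sqrt(sum((colMeans(g_un) - target_mean)^2)))
    })
  }, numeric(2))
  expect_true(all(dists["trained", ] < dists["untrained", ]))
})

test_that("training is reproducible end to end for every method", {
  sp <- cached("sp_train", small_split(seed = 1, n_units = 10))
  for (meth in c("sgan", "combined")) {
    a <- da_train(sp, meth, da_control(epochs = 10, seed = 11))
    b <- da_train(sp, meth, da_control(epochs = 10, seed = 11))
    expect_identical(a$suite, b$suite)
  }
})
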