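#' Training control parameters
#'
#' Defaults follow the study protocol: mini-batches of 32, learning rate
#' 0.001, Adam, 10,000 epochs (one epoch = one pass over the labelled set;
#' reduce `epochs` for experimentation — the examples and tests in this
#' package use a few hundred). `adversarial_mode` selects how a
#' discriminator loss is transformed before the confused module ascends it:
#' `"reciprocal"` (the negative-inverse transform, default) or `"negation"`
#' (plain sign flip, kept for ablation). Setting `adversarial = FALSE`
#' disables every adversarial branch, reducing all methods to the
#' transfer-learning baseline.
#'
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Passes over the labelled data (default 10000).
#' @param adversarial_eps Stabilizer added to the loss in the reciprocal
#'   transform (default 1e-6).
#' @param adversarial_mode `"reciprocal"` or `"negation"`.
#' @param adversarial_clip Upper bound on the reciprocal transform's
#'   gradient magnitude `1/(L + eps)^2` (default 100, reached at
#'   `L = 0.1`); prevents a nearly perfect discriminator from issuing an
#'   unbounded confusing update.
#' @param adversarial Enable adversarial branches (default `TRUE`).
#' @param max_grad_norm Optional global gradient-norm ceiling applied to
#'   every module update after the adversarial scale (default `Inf`, i.e.
#'   off); available as an extra guard against runaway adversarial
#'   dynamics.
#' @param adversarial_lr Peak step size of the plain-gradient ascent used
#'   for the feature extractor's confusing updates (default 0.006, the
#'   frozen calibration).
#' @param adversarial_ramp Scale the confusing step size by a triangular
#'   schedule — zero at the start, peaking at `adversarial_lr` mid-training
#'   and relaxing back to zero (default `TRUE`). The warm-up lets class
#'   structure form before alignment pressure is applied; the cool-down
#'   hands the final epochs back to the classifier so the returned weights
#'   are taken after it has re-converged on the aligned features.
#' @param generator_lr Step size of the generator's confusing update;
#'   defaults to `learning_rate` (kept smaller than `adversarial_lr` so
#'   the generator cannot outrun the real/fake discriminator and flood the
#'   shared extractor with extreme inputs).
#' @param auxiliary_scale Fraction of `learning_rate` at which the
#'   real/fake objective moves the shared feature extractor (default 0.1);
#'   the real/fake heads themselves always train at the full rate. Keeps
#'   the semisupervised auxiliary task from outvoting the one
#'   classification update per iteration.
#' @param confusion_optimizer Optimizer for the confusing updates:
#'   `"sgd"` (default) applies plain scaled gradient steps so the
#'   transformed loss's magnitude schedule is preserved; `"adam"` is kept
#'   for ablation (its per-coordinate normalization erases the schedule).
#' @param latent_dim Generator latent dimension (default 16).
#' @param seed Integer seed for initialization, shuffling and latent draws.
#' @return A list of class `da_control`.
#' @export
da_control <- function(batch_size = 32, learning_rate = 0.001,
                       epochs = 10000, adversarial_eps = 1e-6,
                       adversarial_mode = c("reciprocal", "negation"),
                       adversarial_clip = 100, adversarial = TRUE,
                       max_grad_norm = Inf, adversarial_lr = 0.006,
                       adversarial_ramp = TRUE,
                       generator_lr = learning_rate,
                       auxiliary_scale = 0.1,
                       confusion_optimizer = c("sgd", "adam"),
                       latent_dim = 16, seed = 1) {
  confusion_optimizer <- match.arg(confusion_optimizer)
  adversarial_mode <- match.arg(adversarial_mode)
  stopifnot(batch_size >= 1, epochs >= 1, adversarial_eps > 0,
            learning_rate > 0, latent_dim >= 1, adversarial_clip > 0,
            max_grad_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 adversarial_eps = adversarial_eps,
                 adversarial_mode = adversarial_mode,
                 adversarial_clip = adversarial_clip,
                 adversarial = isTRUE(adversarial),
                 max_grad_norm = max_grad_norm,
                 adversarial_lr = adversarial_lr,
                 adversarial_ramp = isTRUE(adversarial_ramp),
                 generator_lr = generator_lr,
                 auxiliary_scale = auxiliary_scale,
                 confusion_optimizer = confusion_optimizer,
                 latent_dim = as.integer(latent_dim),
                 seed = as.integer(seed)),
            class = "da_control")
}

#' Negative-inverse adversarial loss transform
#'
#' Maps a discriminator loss `L >= 0` to the value a confused module
#' ascends: `-1/(L + eps)` in `"reciprocal"` mode or `-L` in `"negation"`
#' mode. The reciprocal transform's gradient magnitude `1/(L + eps)^2`
#' grows as the discriminator gets more accurate (small `L`), so an
#' accurate discriminator triggers a large confusing step and a weak one a
#' small step.
#'
#' @param loss_value Nonnegative scalar loss.
#' @param eps Positive stabilizer (reciprocal mode).
#' @param mode `"reciprocal"` or `"negation"`.
#' @return Transformed scalar.
#' @export
#' @examples
#' adversarial_transform(1.0, eps = 0)    # -1
#' adversarial_transform(2.0, mode = "negation")  # -2
adversarial_transform <- function(loss_value, eps = 1e-6,
                                  mode = c("reciprocal", "negation")) {
  mode <- match.arg(mode)
  if (any(loss_value < 0)) stop("loss must be nonnegative")
  if (mode == "reciprocal") {
    if (eps < 0 || (eps == 0 && any(loss_value == 0)))
      stop("eps must be positive (or loss strictly positive)")
    -1 / (loss_value + eps)
  } else {
    -loss_value
  }
}

# |d transform / d loss|: the magnitude schedule of the confusing step,
# clipped so a near-zero discriminator loss cannot produce an unbounded
# update (standard adversarial gradient clipping).
adversarial_scale <- function(loss_value, eps, mode, clip = Inf) {
  if (mode == "reciprocal") min(1 / (loss_value + eps)^2, clip) else 1
}

#' Fit a domain-adaptation model
#'
#' Trains the shared feature extractor and classifier on a [domain
#' split][make_domain_split] by one of four procedures:
#'
#' * `"tl"` — transfer-learning baseline: cross-entropy on all labelled
#'   spectra (source plus any labelled target); unlabelled data unused.
#' * `"dann"` — domain-adversarial training. Each iteration runs three
#'   losses sequentially: (1) feature extractor + classifier on the
#'   labelled classification task; (2) the domain discriminator learns the
#'   domain of the labelled batch while the feature extractor ascends the
#'   transformed loss to confuse it; (3) the same adversarial pair on an
#'   unlabelled target batch.
#' * `"sgan"` — semisupervised GAN. Each iteration: the labelled
#'   classification loss, then three real/fake losses — (1) labelled data
#'   scored real, (2) generated spectra scored fake with the generator
#'   ascending the transformed loss, (3) unlabelled target data scored
#'   real. The generator maps latent normal noise to spectra, and its
#'   output passes through the shared feature extractor before the
#'   real/fake head.
#' * `"combined"` — the classification step once, then the DANN
#'   adversarial steps, then the SGAN real/fake steps, per iteration.
#'
#' Confusing updates are gradient ascent on [adversarial_transform()] of
#' the just-measured discriminator loss, applied in a second pass after the
#' discriminator's own descent step. All randomness (weight initialization,
#' batch shuffling, latent draws) derives from `control$seed`; identical
#' data, control and seed give identical weights.
#'
#' @param split A `domain_split` from [make_domain_split()].
#' @param method `"tl"`, `"dann"`, `"sgan"` or `"combined"`.
#' @param control A [da_control()].
#' @return An object of class `da_model` with elements `suite` (trained
#'   [network_suite]), `method`, `control`, `class_levels` and
#'   `loss_history` (one row per optimization iteration).
#' @seealso [predict.da_model()], [da_ensemble()]
#' @export
da_train <- function(split, method = c("tl", "dann", "sgan", "combined"),
                     control = da_control()) {
  method <- match.arg(method)
  stopifnot(inherits(split, "domain_split"), inherits(control, "da_control"))
  if (n_spectra(split$source_labelled) == 0)
    stop("source_labelled is empty; nothing to train on")
  use_dann <- control$adversarial && method %in% c("dann", "combined")
  use_sgan <- control$adversarial && method %in% c("sgan", "combined")
  needs_unlab <- method %in% c("dann", "sgan", "combined")
  if (needs_unlab && n_spectra(split$target_unlabelled) == 0)
    stop("target_unlabelled is empty; use method = \"tl\" instead")

  X_lab <- split$source_labelled$intensity
  dom_lab <- rep(1L, nrow(X_lab))
  y_chr <- split$source_labelled$meta$allergen_class
  if (n_spectra(split$target_labelled) > 0) {
    X_lab <- rbind(X_lab, split$target_labelled$intensity)
    dom_lab <- c(dom_lab, rep(2L, n_spectra(split$target_labelled)))
    y_chr <- c(y_chr, split$target_labelled$meta$allergen_class)
  }
  class_levels <- sort(unique(y_chr))
  y_lab <- match(y_chr, class_levels)
  X_un <- split$target_unlabelled$intensity
  n_lab <- nrow(X_lab)
  bs <- control$batch_size
  eps <- control$adversarial_eps
  mode <- control$adversarial_mode
  clip <- if (is.null(control$adversarial_clip)) 100
          else control$adversarial_clip
  maxn <- if (is.null(control$max_grad_norm)) Inf
          else control$max_grad_norm
  lr <- control$learning_rate
  lr_adv_max <- if (is.null(control$adversarial_lr)) lr
                else control$adversarial_lr
  ramp <- !isFALSE(control$adversarial_ramp)
  lr_adv <- if (ramp) 0 else lr_adv_max
  lr_gen <- if (is.null(control$generator_lr)) lr
            else control$generator_lr
  aux_scale <- if (is.null(control$auxiliary_scale)) 0.1
               else control$auxiliary_scale

  local_seed(control$seed)
  suite <- network_suite(ncol(X_lab), length(class_levels),
                         control$latent_dim, seed = control$seed)
  # private copies: the optimizer mutates parameters in place
  fe <- copy_layers(suite$feature_extractor)
  cls <- copy_layers(suite$classifier)
  dom <- copy_layers(suite$domain_discriminator)
  rf <- copy_layers(suite$realfake_discriminator)
  gen <- copy_layers(suite$generator)
  # One Adam state per (module, objective) pair, mirroring the one
  # optimizer instance per training step a framework implementation would
  # construct; the shared extractor keeps independent moment estimates for
  # the classification, confusion and real/fake objectives so the very
  # differently scaled adversarial gradients do not distort each other's
  # adaptive step sizes.
  st <- list(fe_cls = adam_state(fe), fe_rf = adam_state(fe),
             fe_conf = adam_state(fe), cls = adam_state(cls),
             dom = adam_state(dom), rf = adam_state(rf),
             gen = adam_state(gen))
  conf_opt <- if (is.null(control$confusion_optimizer)) "sgd"
              else control$confusion_optimizer

  # joint descent of the extractor and a softmax head on cross-entropy;
  # fe_lr lets auxiliary objectives move the shared extractor more gently
  # than their own head
  supervised_step <- function(head, head_name, X, y, fe_state, fe_lr = lr) {
    Af <- forward_layers(fe, FE_ACTS, X)
    feats <- Af[[length(Af)]]
    Ah <- forward_layers(head, HEAD_ACTS, feats)
    P <- softmax_rows(Ah[[2]])
    loss <- cross_entropy(P, y)
    bh <- backward_layers(head, HEAD_ACTS, Ah, ce_score_grad(P, y))
    dZ <- bh$dX * (feats > 0)
    bf <- backward_layers(fe, FE_ACTS, Af, dZ)
    up <- adam_step(head, bh$grads, st[[head_name]], lr, max_norm = maxn)
    assign_head(head_name, up$layers); st[[head_name]] <<- up$state
    up <- adam_step(fe, bf$grads, st[[fe_state]], fe_lr, max_norm = maxn)
    fe <<- up$layers; st[[fe_state]] <<- up$state
    loss
  }
  # descent of the head alone on cross-entropy (extractor frozen)
  head_step <- function(head, head_name, feats, y) {
    Ah <- forward_layers(head, HEAD_ACTS, feats)
    P <- softmax_rows(Ah[[2]])
    loss <- cross_entropy(P, y)
    bh <- backward_layers(head, HEAD_ACTS, Ah, ce_score_grad(P, y))
    up <- adam_step(head, bh$grads, st[[head_name]], lr, max_norm = maxn)
    assign_head(head_name, up$layers); st[[head_name]] <<- up$state
    loss
  }
  # ascent of the extractor on the transformed discriminator loss
  confuse_step <- function(head, X, y) {
    Af <- forward_layers(fe, FE_ACTS, X)
    feats <- Af[[length(Af)]]
    Ah <- forward_layers(head, HEAD_ACTS, feats)
    P <- softmax_rows(Ah[[2]])
    loss <- cross_entropy(P, y)
    bh <- backward_layers(head, HEAD_ACTS, Ah, ce_score_grad(P, y))
    dZ <- bh$dX * (feats > 0)
    bf <- backward_layers(fe, FE_ACTS, Af, dZ)
    sc <- -adversarial_scale(loss, eps, mode, clip)  # ascend the transform
    if (conf_opt == "adam") {
      up <- adam_step(fe, bf$grads, st$fe_conf, lr_adv, scale = sc,
                      max_norm = maxn)
      fe <<- up$layers; st$fe_conf <<- up$state
    } else {
      fe <<- sgd_step(fe, bf$grads, lr_adv, scale = sc)
    }
    loss
  }
  assign_head <- function(name, layers) {
    switch(name,
           cls = cls <<- layers,
           dom = dom <<- layers,
           rf = rf <<- layers)
    invisible(NULL)
  }

  # cyclic unlabelled batch iterator; consumes RNG only when called
  un_order <- integer(0); un_ptr <- 0L
  next_unlab <- function(n) {
    idx <- integer(0)
    while (length(idx) < n) {
      if (un_ptr >= length(un_order)) {
        un_order <<- sample.int(nrow(X_un))
        un_ptr <<- 0L
      }
      take <- min(n - length(idx), length(un_order) - un_ptr)
      idx <- c(idx, un_order[un_ptr + seq_len(take)])
      un_ptr <<- un_ptr + take
    }
    X_un[idx, , drop = FALSE]
  }

  history <- list()
  hrow <- 0L
  for (epoch in seq_len(control$epochs)) {
    # triangular warm-up/cool-down: alignment pressure peaks mid-training
    # and relaxes before the end, so the final weights are taken after the
    # classifier has re-converged on the aligned features
    if (ramp) lr_adv <- lr_adv_max *
        (1 - abs(2 * epoch / control$epochs - 1))
    ord <- sample.int(n_lab)
    n_batches <- ceiling(n_lab / bs)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n_lab)]
      Xb <- X_lab[idx, , drop = FALSE]
      yb <- y_lab[idx]
      losses <- c(classification =
                    supervised_step(cls, "cls", Xb, yb, "fe_cls"))

      if (use_dann) {
        # A domain discriminator only receives an informative loss from a
        # two-class batch, so each step's named data is contrasted with a
        # same-size draw from the other domain.
        # step 2: domain of the labelled batch (source, plus any labelled
        # target), contrasted with unlabelled target; then confusion
        Xu <- next_unlab(nrow(Xb))
        X2 <- rbind(Xb, Xu)
        d2 <- c(dom_lab[idx], rep(2L, nrow(Xu)))
        losses["domain_disc_labelled"] <-
          head_step(dom, "dom", suite_feats(fe, X2), d2)
        losses["domain_confusion_labelled"] <- confuse_step(dom, X2, d2)
        # step 3: domain of an unlabelled target batch, contrasted with
        # labelled source; then confusion
        Xu <- next_unlab(bs)
        ic <- sample.int(n_lab, min(nrow(Xu), n_lab))
        X3 <- rbind(Xu, X_lab[ic, , drop = FALSE])
        d3 <- c(rep(2L, nrow(Xu)), dom_lab[ic])
        losses["domain_disc_unlabelled"] <-
          head_step(dom, "dom", suite_feats(fe, X3), d3)
        losses["domain_confusion_unlabelled"] <- confuse_step(dom, X3, d3)
      }
      if (use_sgan) {
        # step 1: labelled data are real (extractor + discriminator)
        # the real/fake task moves the shared extractor at a reduced
        # auxiliary rate so it cannot swamp the classification updates
        fe_lr_rf <- lr * aux_scale
        losses["realfake_real_labelled"] <-
          supervised_step(rf, "rf", Xb, rep(1L, nrow(Xb)), "fe_rf",
                          fe_lr_rf)
        # step 2: generated spectra are fake; generator confuses
        z <- matrix(stats::rnorm(bs * suite$latent_dim), bs)
        Ag <- forward_layers(gen, GEN_ACTS, z)
        Xg <- Ag[[length(Ag)]]
        losses["realfake_fake"] <-
          supervised_step(rf, "rf", Xg, rep(2L, nrow(Xg)), "fe_rf",
                          fe_lr_rf)
        losses["generator"] <- {
          # fresh pass with the updated extractor/discriminator
          Ag <- forward_layers(gen, GEN_ACTS, z)
          Xg <- Ag[[length(Ag)]]
          Af <- forward_layers(fe, FE_ACTS, Xg)
          feats <- Af[[length(Af)]]
          Ah <- forward_layers(rf, HEAD_ACTS, feats)
          P <- softmax_rows(Ah[[2]])
          loss <- cross_entropy(P, rep(2L, nrow(Xg)))
          bh <- backward_layers(rf, HEAD_ACTS, Ah,
                                ce_score_grad(P, rep(2L, nrow(Xg))))
          dZ <- bh$dX * (feats > 0)
          bf <- backward_layers(fe, FE_ACTS, Af, dZ)
          dZg <- bf$dX  # gradient wrt generated spectra (linear output)
          bg <- backward_layers(gen, GEN_ACTS, Ag, dZg)
          sc <- -adversarial_scale(loss, eps, mode, clip)
          if (conf_opt == "adam") {
            up <- adam_step(gen, bg$grads, st$gen, lr_gen, scale = sc,
                            max_norm = maxn)
            gen <- up$layers; st$gen <- up$state
          } else {
            gen <- sgd_step(gen, bg$grads, lr_gen, scale = sc)
          }
          loss
        }
        # step 3: unlabelled target data are real
        Xu <- next_unlab(bs)
        losses["realfake_real_unlabelled"] <-
          supervised_step(rf, "rf", Xu, rep(1L, nrow(Xu)), "fe_rf",
                          fe_lr_rf)
      }
      hrow <- hrow + 1L
      history[[hrow]] <- c(epoch = epoch, iteration = hrow, losses)
    }
  }

  suite$feature_extractor <- fe
  suite$classifier <- cls
  suite$domain_discriminator <- dom
  suite$realfake_discriminator <- rf
  suite$generator <- gen
  loss_history <- as.data.frame(rbind_fill(history))
  structure(list(suite = suite, method = method_tag(method),
                 control = control, class_levels = class_levels,
                 loss_history = loss_history,
                 n_labelled = n_lab,
                 n_unlabelled = nrow(X_un)),
            class = "da_model")
}

suite_feats <- function(fe, X) {
  A <- forward_layers(fe, FE_ACTS, X)
  A[[length(A)]]
}

method_tag <- function(method) {
  c(tl = "TL", dann = "DANN", sgan = "SGAN", combined = "SGAN+DANN")[[method]]
}

# rbind a list of possibly differently named numeric vectors, filling NA
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(rows)) out[i, names(rows[[i]])] <- rows[[i]]
  out
}

#' @export
print.da_model <- function(x, ...) {
  cat("Domain-adaptation model (", x$method, ")\n", sep = "")
  cat("  input dim ", x$suite$input_dim, ", classes: ",
      paste(x$class_levels, collapse = ", "), "\n", sep = "")
  cat("  trained ", max(x$loss_history[, "epoch"]), " epochs on ",
      x$n_labelled, " labelled / ", x$n_unlabelled,
      " unlabelled spectra (seed ", x$control$seed, ")\n", sep = "")
  cat("  final classification loss: ",
      signif(utils::tail(x$loss_history[, "classification"], 1), 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.da_model <- function(object, ...) {
  h <- object$loss_history
  loss_cols <- setdiff(colnames(h), c("epoch", "iteration"))
  final <- vapply(loss_cols, function(cn) {
    v <- h[, cn]; v <- v[!is.na(v)]
    if (length(v)) utils::tail(v, 1) else NA_real_
  }, 0)
  out <- list(method = object$method, control = object$control,
              class_levels = object$class_levels,
              iterations = nrow(h), final_losses = final)
  class(out) <- "summary.da_model"
  out
}

#' @export
print.summary.da_model <- function(x, ...) {
  cat("Method: ", x$method, " (", x$iterations, " iterations, seed ",
      x$control$seed, ")\n", sep = "")
  cat("Final losses:\n")
  print(signif(x$final_losses, 4))
  invisible(x)
}

#' Predict allergen classes for new spectra
#'
#' @param object A fitted [da_train()] model.
#' @param newdata A [spectra] object or numeric matrix on the model's grid.
#' @param type `"class"` for labels, `"prob"` for the probability matrix,
#'   `"both"` for a list of the two.
#' @param ... Unused.
#' @return Character vector of class labels, probability matrix, or both.
#' @export
predict.da_model <- function(object, newdata,
                             type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra")) newdata$intensity
       else as.matrix(newdata)
  if (ncol(X) != object$suite$input_dim)
    stop("newdata has ", ncol(X), " features but the model expects ",
         object$suite$input_dim)
  P <- suite_class_proba(object$suite, X)
  colnames(P) <- object$class_levels
  labels <- object$class_levels[max.col(P, ties.method = "first")]
  switch(type, class = labels, prob = P,
         both = list(class = labels, prob = P))
}

#' Draw generated spectra from a fitted model's generator
#'
#' Only meaningful for SGAN-trained models, where the generator was pushed
#' toward the target-domain distribution; for other methods it returns the
#' untrained generator's output.
#'
#' @param object A `da_model`.
#' @param nsim Number of spectra to draw.
#' @param seed Optional seed for the latent draws.
#' @param ... Unused.
#' @return Matrix of `nsim` generated spectra.
#' @export
simulate.da_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) local_seed(seed)
  suite_generate(object$suite, nsim)
}

#' Plot training loss trajectories
#'
#' @param x A `da_model`.
#' @param losses Which loss columns to draw (default all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.da_model <- function(x, losses = NULL, ...) {
  h <- x$loss_history
  cols <- setdiff(colnames(h), c("epoch", "iteration"))
  if (!is.null(losses)) cols <- intersect(cols, losses)
  graphics::matplot(h[, "iteration"], h[, cols, drop = FALSE], type = "l",
                    lty = 1, xlab = "iteration", ylab = "loss",
                    main = paste("Training losses:", x$method), ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, cex = 0.7)
  invisible(x)
}
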