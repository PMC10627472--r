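#' Training configuration
#'
#' All hyperparameters of the adversarial training loop in one validated
#' record. Defaults follow the published setup: adversarial scaling
#' `alpha = 0.5`, compound-loss weights `lambda1 = 1`, `lambda2 = 100`,
#' Adam with learning rate `0.002`, `beta1 = 0.5`, `beta2 = 0.999`, and
#' batch size 16.
#'
#' @param alpha discriminator loss scaling factor.
#' @param lambda1,lambda2 generator compound-loss weights.
#' @param learning_rate Adam step size for both networks.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size minibatch size (capped at the dataset size).
#' @param epochs passes over the dataset; steps = epochs x floor(n / batch).
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param checkpoint_every write a numbered checkpoint every so many steps
#'   (0 = never).
#' @param eps clamp bound for log arguments.
#' @param reconstruction_mode `"mean"` or `"sum"` (see
#'   [reconstruction_loss()]).
#' @param saturating use the saturating generator adversarial form.
#' @return A `train_config` list.
#' @export
train_config <- function(alpha = 0.5, lambda1 = 1, lambda2 = 100,
                         learning_rate = 0.002, beta1 = 0.5, beta2 = 0.999,
                         batch_size = 16, epochs = 10, seed = 1,
                         checkpoint_every = 0, eps = 1e-7,
                         reconstruction_mode = c("mean", "sum"),
                         saturating = FALSE) {
  structure(list(
    alpha = check_number(alpha, "alpha", lower = 0),
    lambda1 = check_number(lambda1, "lambda1", lower = 0),
    lambda2 = check_number(lambda2, "lambda2", lower = 0),
    learning_rate = check_number(learning_rate, "learning_rate", lower = 1e-12),
    beta1 = check_number(beta1, "beta1", lower = 0, upper = 1),
    beta2 = check_number(beta2, "beta2", lower = 0, upper = 1),
    batch_size = check_count(batch_size, "batch_size", lower = 1),
    epochs = check_count(epochs, "epochs", lower = 1),
    seed = check_count(seed, "seed"),
    checkpoint_every = check_count(checkpoint_every, "checkpoint_every"),
    eps = check_number(eps, "eps", lower = 0, upper = 0.5),
    reconstruction_mode = match.arg(reconstruction_mode),
    saturating = isTRUE(saturating)), class = "train_config")
}

pairs_to_batch <- function(pairs, idx) {
  h <- pairs[[idx[1]]]$image$height
  w <- pairs[[idx[1]]]$image$width
  n <- length(idx)
  xb <- array(0, c(h, w, 3L, n))
  yb <- array(0, c(h, w, 1L, n))
  for (k in seq_along(idx)) {
    p <- pairs[[idx[k]]]
    xb[, , , k] <- p$image$pixels
    yb[, , 1L, k] <- p$mask$pixels
  }
  list(x = xb, y = yb)
}

# gradient of -mean(log(clamp(s))) w.r.t. s, times `scale`
grad_neglog <- function(s, eps, scale = 1) {
  g <- array(0, dim(s))
  inside <- s > eps & s < 1 - eps
  g[inside] <- -scale / (length(s) * s[inside])
  g
}

# gradient of -mean(log(clamp(1 - s))) w.r.t. s, times `scale`
grad_neglog1m <- function(s, eps, scale = 1) {
  g <- array(0, dim(s))
  inside <- s > eps & s < 1 - eps
  g[inside] <- scale / (length(s) * (1 - s[inside]))
  g
}

#' Train the segmentation GAN
#'
#' Alternating optimization: at each step a minibatch is drawn, the
#' discriminator is updated on the real `(x, y)` and generated
#' `(x, G(x))` batches under the scaled adversarial loss, then the
#' generator is updated against the just-updated discriminator under the
#' compound loss. Both networks use Adam. A fixed held-out batch is scored
#' after every step and the generator achieving the lowest compound loss
#' on it is retained as the best model.
#'
#' @param pairs list of [sample_pair] objects, all at the generator's
#'   `input_side`.
#' @param gcfg a [generator_config()].
#' @param dcfg a [discriminator_config()].
#' @param tcfg a [train_config()].
#' @param out_dir optional run directory; receives `history.tsv`,
#'   `ckpt_step<N>.rds`, `ckpt_best.rds` and `config.yaml`.
#' @param verbose print a progress line per epoch.
#' @return A list with `history` (one row of loss components per step),
#'   `generator`, `discriminator` (final), `best` (generator with the
#'   lowest held-out compound loss) and `best_step`.
#' @export
train_gan <- function(pairs, gcfg = generator_config(),
                      dcfg = discriminator_config(), tcfg = train_config(),
                      out_dir = NULL, verbose = FALSE) {
  if (!length(pairs)) stop_validation("empty training set")
  stopifnot(inherits(gcfg, "generator_config"),
            inherits(dcfg, "discriminator_config"),
            inherits(tcfg, "train_config"))
  side <- gcfg$input_side
  for (p in pairs)
    if (p$image$height != side || p$image$width != side)
      stop_validation("pair '%s' is %d x %d but the generator expects %d x %d",
                      p$id, p$image$height, p$image$width, side, side)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n <- length(pairs)
  b <- min(tcfg$batch_size, n)
  steps_per_epoch <- max(1L, n %/% b)

  with_seed(tcfg$seed, {
    gen <- build_generator(gcfg)
    disc <- build_discriminator(dcfg)
    g_opt <- adam_state_new(gen$par)
    d_opt <- adam_state_new(disc$par)
    held_idx <- sample.int(n, b)
    held <- pairs_to_batch(pairs, held_idx)

    history <- vector("list", tcfg$epochs * steps_per_epoch)
    best <- NULL
    best_loss <- Inf
    best_step <- NA_integer_
    step <- 0L

    for (epoch in seq_len(tcfg$epochs)) {
      perm <- sample.int(n)
      for (sb in seq_len(steps_per_epoch)) {
        step <- step + 1L
        idx <- perm[((sb - 1L) * b + 1L):(sb * b)]
        batch <- pairs_to_batch(pairs, idx)

        ## --- discriminator update ---------------------------------------
        gfw <- gen_forward_impl(gen, batch$x, training = TRUE)
        gen <- gfw$model
        fake <- gfw$out
        rfw <- disc_forward_impl(disc, batch$x, batch$y, training = TRUE)
        disc <- rfw$model
        ffw <- disc_forward_impl(disc, batch$x, fake, training = TRUE)
        disc <- ffw$model
        terms <- adversarial_terms(rfw$out, ffw$out, eps = tcfg$eps)
        d_total <- discriminator_loss(terms$d_real, terms$d_fake, tcfg$alpha)

        dr <- grad_neglog(rfw$out, tcfg$eps, scale = tcfg$alpha)
        df <- grad_neglog1m(ffw$out, tcfg$eps, scale = tcfg$alpha)
        br <- disc_backward_impl(disc, rfw$cache, dr, want_input_grad = FALSE)
        bf <- disc_backward_impl(disc, ffw$cache, df, want_input_grad = FALSE)
        dgr <- br$grads
        for (nm in names(bf$grads)) dgr[[nm]] <- acc_grad(dgr[[nm]], bf$grads[[nm]])
        upd <- adam_step(disc$par, dgr, d_opt, tcfg$learning_rate,
                         tcfg$beta1, tcfg$beta2)
        disc$par <- upd$par
        d_opt <- upd$state

        ## --- generator update -------------------------------------------
        ffw2 <- disc_forward_impl(disc, batch$x, fake, training = TRUE)
        disc <- ffw2$model
        at <- adversarial_terms(rfw$out, ffw2$out, eps = tcfg$eps,
                                saturating = tcfg$saturating)
        g_adv <- at$g_adv
        g_rec <- reconstruction_loss(batch$y, fake,
                                     mode = tcfg$reconstruction_mode)
        g_total <- generator_loss(g_adv, g_rec, tcfg$lambda1, tcfg$lambda2)

        dscore <- if (tcfg$saturating)
          -grad_neglog1m(ffw2$out, tcfg$eps, scale = tcfg$lambda1)
        else grad_neglog(ffw2$out, tcfg$eps, scale = tcfg$lambda1)
        dbk <- disc_backward_impl(disc, ffw2$cache, dscore, want_input_grad = TRUE)
        drec <- -sign(batch$y - fake)
        if (tcfg$reconstruction_mode == "mean") drec <- drec / length(fake)
        dg <- dbk$dmask + tcfg$lambda2 * drec
        ggr <- gen_backward_impl(gen, gfw$cache, dg)
        upd <- adam_step(gen$par, ggr, g_opt, tcfg$learning_rate,
                         tcfg$beta1, tcfg$beta2)
        gen$par <- upd$par
        g_opt <- upd$state

        if (!all(is.finite(c(d_total, g_total))))
          stop(errorCondition(
            sprintf("training diverged (non-finite loss) at step %d", step),
            class = c("woundseg_divergence_error", "error")))

        history[[step]] <- data.frame(
          step = step, d_real = terms$d_real, d_fake = terms$d_fake,
          d_total = d_total, g_adv = g_adv, g_rec = g_rec, g_total = g_total)

        ## --- held-out score and checkpoints -----------------------------
        hv <- gen_forward_impl(gen, held$x, training = FALSE)
        hd <- disc_forward_impl(disc, held$x, hv$out, training = FALSE)
        hterms <- adversarial_terms(hd$out, hd$out, eps = tcfg$eps,
                                    saturating = tcfg$saturating)
        hrec <- reconstruction_loss(held$y, hv$out,
                                    mode = tcfg$reconstruction_mode)
        hloss <- generator_loss(hterms$g_adv, hrec, tcfg$lambda1, tcfg$lambda2)
        if (is.finite(hloss) && hloss < best_loss) {
          best_loss <- hloss
          best <- gen
          best_step <- step
          if (!is.null(out_dir))
            save_checkpoint(file.path(out_dir, "ckpt_best.rds"),
                            gen, disc, gcfg, dcfg, tcfg, step)
        }
        if (!is.null(out_dir) && tcfg$checkpoint_every > 0L &&
            step %% tcfg$checkpoint_every == 0L)
          save_checkpoint(file.path(out_dir, sprintf("ckpt_step%d.rds", step)),
                          gen, disc, gcfg, dcfg, tcfg, step)
      }
      if (verbose) {
        h <- history[[step]]
        message(sprintf("epoch %d/%d  step %d  d %.4f  g %.4f (adv %.4f rec %.4f)",
                        epoch, tcfg$epochs, step, h$d_total, h$g_total,
                        h$g_adv, h$g_rec))
      }
    }

    history <- do.call(rbind, history)
    if (!is.null(out_dir)) {
      write.table(history, file.path(out_dir, "history.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      yaml::write_yaml(list(generator = unclass(gcfg),
                            discriminator = unclass(dcfg),
                            train = unclass(tcfg)),
                       file.path(out_dir, "config.yaml"))
    }
    list(history = history, generator = gen, discriminator = disc,
         best = best %||% gen, best_step = best_step)
  })
}

save_checkpoint <- function(path, gen, disc, gcfg, dcfg, tcfg, step) {
  saveRDS(list(generator = gen, discriminator = disc, gcfg = gcfg,
               dcfg = dcfg, tcfg = tcfg, step = step), path)
}

#' Load a training checkpoint
#'
#' @param path an `.rds` checkpoint written by [train_gan()].
#' @return The checkpoint list (`generator`, `discriminator`, configs,
#'   `step`).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: %s", path)
  ck <- readRDS(path)
  if (!inherits(ck$generator, "generator"))
    stop_io("'%s' is not a woundseg checkpoint", path)
  ck
}

#' Segment a wound image with a trained generator
#'
#' The image is resized to the generator's input side (bilinear), passed
#' through the network in evaluation mode, and thresholded.
#'
#' @param gen a trained `generator`, or a checkpoint list/path from
#'   [train_gan()].
#' @param image a [wound_image].
#' @param threshold binarization threshold in `(0, 1)`.
#' @return A list with `prob` ([probability_mask]) and `mask`
#'   ([binary_mask]) at the generator's resolution.
#' @export
segment_image <- function(gen, image, threshold = 0.5) {
  if (is.character(gen)) gen <- load_checkpoint(gen)
  if (is.list(gen) && !inherits(gen, "generator") && inherits(gen$generator, "generator"))
    gen <- gen$generator
  stopifnot(inherits(gen, "generator"), inherits(image, "wound_image"))
  side <- gen$cfg$input_side
  if (image$height != side || image$width != side)
    image <- resize_image(image, side)
  prob <- generator_forward(gen, image, training = FALSE)
  list(prob = prob, mask = binarize(prob, threshold = threshold))
}

#' Mean overlap metrics of a generator on a set of pairs
#'
#' Runs the generator in evaluation mode on every pair, binarizes at the
#' threshold, and returns per-pair precision/recall/Dice/IoU plus their
#' means.
#'
#' @param gen a trained `generator`.
#' @param pairs list of [sample_pair] objects at the generator resolution.
#' @param threshold binarization threshold.
#' @return A list with `per_pair` (data frame) and `mean` (named vector).
#' @export
evaluate_generator <- function(gen, pairs, threshold = 0.5) {
  stopifnot(inherits(gen, "generator"))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    pr <- generator_forward(gen, p$image, training = FALSE)
    cm <- confusion(binarize(pr, threshold), p$mask)
    data.frame(id = p$id, precision = precision(cm), recall = recall(cm),
               dice = dice(cm), iou = iou(cm))
  })
  per <- do.call(rbind, rows)
  list(per_pair = per,
       mean = colMeans(per[, c("precision", "recall", "dice", "iou")]))
}
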