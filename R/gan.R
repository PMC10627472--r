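#' Generator (U-Net) configuration
#'
#' The generator is a symmetric encoder-decoder. Each encoder level is a
#' stride-2 4x4 convolution (batch norm on all but the first level, leaky
#' rectifier slope 0.2) that halves the resolution; each decoder level is a
#' stride-2 4x4 transposed convolution (batch norm on all but the last
#' level, plain rectifier) that doubles it, with the same-resolution encoder
#' activation concatenated as a skip connection. The final level outputs one
#' channel through a sigmoid, so predictions are per-pixel wound
#' probabilities in `[0, 1]`. Dropout (rate 0.5) acts on the innermost
#' `dropout_levels` decoder levels during training.
#'
#' @param input_side input resolution in pixels; must be divisible by
#'   `2^depth`.
#' @param depth number of encoder/decoder levels.
#' @param base_filters filters of the first encoder level; level `i` uses
#'   `min(base_filters * 2^min(i-1, 3), 512)`.
#' @param dropout_levels how many innermost decoder levels use dropout.
#' @return A `generator_config` list.
#' @export
generator_config <- function(input_side = 256, depth = 6, base_filters = 64,
                             dropout_levels = 3) {
  input_side <- check_count(input_side, "input_side", lower = 8)
  depth <- check_count(depth, "depth", lower = 1)
  base_filters <- check_count(base_filters, "base_filters", lower = 1)
  dropout_levels <- check_count(dropout_levels, "dropout_levels", lower = 0)
  if (input_side %% 2^depth != 0)
    stop_validation("input_side (%d) must be divisible by 2^depth (%d)",
                    input_side, 2^depth)
  structure(list(input_side = input_side, depth = depth,
                 base_filters = base_filters,
                 dropout_levels = min(dropout_levels, depth - 1L)),
            class = "generator_config")
}

#' Patch discriminator configuration
#'
#' Six stacks of 4x4 convolutions score overlapping patches of the
#' (image, mask) pair as real or fake. Stacks 1-5 use batch normalization
#' and a leaky rectifier; the last stack is a single-filter convolution
#' followed by a sigmoid, producing the patch-score matrix. All stacks use
#' same-style padding, so a 256 px input yields a 16 x 16 score map after
#' the four stride-2 stacks.
#'
#' @param filters filter counts of the six stacks (last must be 1).
#' @param strides strides of the six stacks.
#' @param kernel convolution kernel side.
#' @param leaky_slope negative-slope of the leaky rectifier.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(filters = c(64, 128, 256, 512, 512, 1),
                                 strides = c(2, 2, 2, 2, 1, 1),
                                 kernel = 4, leaky_slope = 0.2) {
  if (length(filters) != 6L || length(strides) != 6L)
    stop_validation("the discriminator has exactly six stacks")
  if (filters[6] != 1L)
    stop_validation("the last stack must have a single filter (got %d)", filters[6])
  kernel <- check_count(kernel, "kernel", lower = 1)
  leaky_slope <- check_number(leaky_slope, "leaky_slope", lower = 0, upper = 1)
  structure(list(stacks = 6L, filters = as.integer(filters),
                 strides = as.integer(strides), kernel = kernel,
                 leaky_slope = leaky_slope),
            class = "discriminator_config")
}

gen_filters <- function(cfg) {
  pmin(cfg$base_filters * 2^pmin(seq_len(cfg$depth) - 1L, 3L), 512L)
}

#' Build a generator with freshly initialized weights
#'
#' Weights are drawn from `N(0, 0.02)` using the current RNG stream; seed
#' the stream (or use [train_gan()], which seeds it) for reproducibility.
#'
#' @param cfg a [generator_config()].
#' @return A `generator` model object holding the configuration, the flat
#'   list of trainable tensors, and batch-norm running statistics.
#' @export
build_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  D <- cfg$depth
  f <- gen_filters(cfg)
  par <- list()
  bn <- list()
  for (i in seq_len(D)) {
    cin <- if (i == 1L) 3L else f[i - 1L]
    par[[paste0("enc", i)]] <- nn_init_conv(4L, cin, f[i])
    if (i > 1L) {
      par[[paste0("enc", i, "_bn")]] <- nn_init_bn(f[i])
      bn[[paste0("enc", i, "_bn")]] <- bn_state_new(f[i])
    }
  }
  for (j in seq_len(D)) {
    cin <- if (j == 1L) f[D] else {
      fprev <- if (j - 1L < D) f[D - j + 1L] else 1L
      fprev + f[D - j + 1L]
    }
    fout <- if (j < D) f[D - j] else 1L
    par[[paste0("dec", j)]] <- nn_init_deconv(4L, cin, fout)
    if (j < D) {
      par[[paste0("dec", j, "_bn")]] <- nn_init_bn(fout)
      bn[[paste0("dec", j, "_bn")]] <- bn_state_new(fout)
    }
  }
  structure(list(cfg = cfg, par = flatten_par(par), bn = bn), class = "generator")
}

# flatten list(layer = list(w=, b=)) to list("layer.w" = , ...)
flatten_par <- function(nested) {
  out <- list()
  for (lname in names(nested))
    for (tname in names(nested[[lname]]))
      out[[paste0(lname, ".", tname)]] <- nested[[lname]][[tname]]
  out
}

par_of <- function(par, layer) {
  list(w = par[[paste0(layer, ".w")]], b = par[[paste0(layer, ".b")]],
       gamma = par[[paste0(layer, ".gamma")]], beta = par[[paste0(layer, ".beta")]])
}

#' Run the generator
#'
#' @param gen a `generator` built by [build_generator()] (possibly trained).
#' @param x a [wound_image] (or an `H x W x 3 x N` batch array) whose side
#'   equals the configured `input_side`.
#' @param training logical; training mode uses batch statistics in batch
#'   norm and samples dropout, evaluation mode is deterministic.
#' @return For a single [wound_image], a [probability_mask]; for a batch
#'   array, an `H x W x 1 x N` array of probabilities.
#' @export
generator_forward <- function(gen, x, training = FALSE) {
  stopifnot(inherits(gen, "generator"))
  single <- inherits(x, "wound_image")
  xb <- if (single) array(x$pixels, c(dim(x$pixels), 1L)) else x
  d <- dim(xb)
  side <- gen$cfg$input_side
  if (length(d) != 4L || d[1] != side || d[2] != side || d[3] != 3L)
    stop_validation("generator expects %d x %d x 3 input, got [%s]",
                    side, side, paste(d, collapse = ", "))
  fw <- gen_forward_impl(gen, xb, training = training)
  if (single) probability_mask(fw$out[, , 1L, 1L]) else fw$out
}

gen_forward_impl <- function(gen, xb, training = FALSE) {
  cfg <- gen$cfg
  D <- cfg$depth
  pad <- c(1L, 1L, 1L, 1L)
  h <- xb
  enc_act <- vector("list", D)
  cache <- list(enc = vector("list", D), dec = vector("list", D))
  bn <- gen$bn
  for (i in seq_len(D)) {
    lname <- paste0("enc", i)
    p <- par_of(gen$par, lname)
    z <- conv_fwd(p, h, 4L, 2L, pad)
    cc <- list(x_in = h)
    if (i > 1L) {
      bname <- paste0(lname, "_bn")
      bp <- par_of(gen$par, bname)
      bf <- bn_fwd(bp, bn[[bname]], z, training)
      bn[[bname]] <- bf$state
      cc$bn <- bf$cache
      z <- bf$y
    }
    lf <- lrelu_fwd(z, 0.2)
    cc$act <- lf
    enc_act[[i]] <- lf$y
    cache$enc[[i]] <- cc
    h <- lf$y
  }
  for (j in seq_len(D)) {
    lname <- paste0("dec", j)
    p <- par_of(gen$par, lname)
    hd <- dim(h)
    z <- deconv_fwd(p, h, 4L, 2L, pad, 2L * hd[1], 2L * hd[2])
    cc <- list(x_in = h)
    if (j < D) {
      bname <- paste0(lname, "_bn")
      bp <- par_of(gen$par, bname)
      bf <- bn_fwd(bp, bn[[bname]], z, training)
      bn[[bname]] <- bf$state
      cc$bn <- bf$cache
      z <- bf$y
      if (training && j <= cfg$dropout_levels) {
        df <- dropout_fwd(z, 0.5)
        cc$drop <- df$mask
        z <- df$y
      }
      lf <- lrelu_fwd(z, 0)           # plain rectifier
      cc$act <- lf
      skip <- enc_act[[D - j]]
      cc$split <- dim(lf$y)[3]
      h <- abind4(lf$y, skip)
    } else {
      y <- sigmoid_fwd(z)
      cc$sig <- y
      h <- y
    }
    cache$dec[[j]] <- cc
  }
  gen$bn <- bn
  list(out = h, cache = cache, model = gen)
}

# channel-wise concatenation of two (H,W,C,N) arrays
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

gen_backward_impl <- function(gen, cache, dout) {
  cfg <- gen$cfg
  D <- cfg$depth
  pad <- c(1L, 1L, 1L, 1L)
  grads <- list()
  skip_grad <- vector("list", D)       # grads flowing into encoder activations
  dh <- dout
  for (j in rev(seq_len(D))) {
    lname <- paste0("dec", j)
    cc <- cache$dec[[j]]
    p <- par_of(gen$par, lname)
    if (j < D) {
      ns <- cc$split
      dskip <- dh[, , ns + seq_len(dim(dh)[3] - ns), , drop = FALSE]
      skip_grad[[D - j]] <- acc_grad(skip_grad[[D - j]], dskip)
      dz <- dh[, , seq_len(ns), , drop = FALSE]
      dz <- lrelu_bwd(cc$act, dz)
      if (!is.null(cc$drop)) dz <- dz * cc$drop
      bname <- paste0(lname, "_bn")
      bb <- bn_bwd(par_of(gen$par, bname), cc$bn, dz)
      grads[[paste0(bname, ".gamma")]] <- bb$dgamma
      grads[[paste0(bname, ".beta")]] <- bb$dbeta
      dz <- bb$dx
    } else {
      dz <- sigmoid_bwd(cc$sig, dh)
    }
    bw <- deconv_bwd(p, cc$x_in, dz, 4L, 2L, pad)
    grads[[paste0(lname, ".w")]] <- bw$dw
    grads[[paste0(lname, ".b")]] <- bw$db
    dh <- bw$du
  }
  for (i in rev(seq_len(D))) {
    lname <- paste0("enc", i)
    cc <- cache$enc[[i]]
    p <- par_of(gen$par, lname)
    if (!is.null(skip_grad[[i]])) dh <- dh + skip_grad[[i]]
    dz <- lrelu_bwd(cc$act, dh)
    if (i > 1L) {
      bname <- paste0(lname, "_bn")
      bb <- bn_bwd(par_of(gen$par, bname), cc$bn, dz)
      grads[[paste0(bname, ".gamma")]] <- bb$dgamma
      grads[[paste0(bname, ".beta")]] <- bb$dbeta
      dz <- bb$dx
    }
    bw <- conv_bwd(p, cc$x_in, dz, 4L, 2L, pad)
    grads[[paste0(lname, ".w")]] <- bw$dw
    grads[[paste0(lname, ".b")]] <- bw$db
    dh <- bw$dx
  }
  grads
}

#' Build a patch discriminator with freshly initialized weights
#'
#' @param cfg a [discriminator_config()].
#' @return A `discriminator` model object.
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "discriminator_config"))
  par <- list()
  bn <- list()
  cin <- 4L                             # image (3) + mask (1), channel-wise
  for (i in 1:6) {
    f <- cfg$filters[i]
    par[[paste0("stack", i)]] <- nn_init_conv(cfg$kernel, cin, f)
    if (i < 6L) {
      par[[paste0("stack", i, "_bn")]] <- nn_init_bn(f)
      bn[[paste0("stack", i, "_bn")]] <- bn_state_new(f)
    }
    cin <- f
  }
  structure(list(cfg = cfg, par = flatten_par(par), bn = bn),
            class = "discriminator")
}

#' Score image/mask patches with the discriminator
#'
#' The image and the (target or generated) mask are concatenated
#' channel-wise and passed through the six stacks; the result is a matrix
#' of per-patch real/fake probabilities.
#'
#' @param disc a `discriminator` model.
#' @param x a [wound_image] or `H x W x 3 x N` batch array.
#' @param m a [binary_mask], [probability_mask], or `H x W x 1 x N` array,
#'   spatially matching `x`.
#' @param training logical; see [generator_forward()].
#' @return For single inputs, a `patch_score_map` (matrix of scores in
#'   `(0, 1)` with the stride schedule's geometry); for batches, an
#'   `h x w x 1 x N` score array.
#' @export
discriminator_forward <- function(disc, x, m, training = FALSE) {
  stopifnot(inherits(disc, "discriminator"))
  single <- inherits(x, "wound_image")
  xb <- if (single) array(x$pixels, c(dim(x$pixels), 1L)) else x
  mb <- if (inherits(m, c("binary_mask", "probability_mask")))
    array(m$pixels, c(dim(m$pixels), 1L, 1L)) else m
  dx <- dim(xb); dm <- dim(mb)
  if (dx[1] != dm[1] || dx[2] != dm[2] || dx[4] != dm[4])
    stop_validation("image [%s] and mask [%s] shapes do not match",
                    paste(dx, collapse = ", "), paste(dm, collapse = ", "))
  fw <- disc_forward_impl(disc, xb, mb, training = training)
  if (single) {
    structure(list(scores = fw$out[, , 1L, 1L]), class = "patch_score_map")
  } else fw$out
}

disc_forward_impl <- function(disc, xb, mb, training = FALSE) {
  cfg <- disc$cfg
  h <- abind4(xb, mb)
  cache <- vector("list", 6L)
  bn <- disc$bn
  for (i in 1:6) {
    lname <- paste0("stack", i)
    p <- par_of(disc$par, lname)
    pad <- pad_same(cfg$kernel, cfg$strides[i])
    z <- conv_fwd(p, h, cfg$kernel, cfg$strides[i], pad)
    cc <- list(x_in = h, pad = pad)
    if (i < 6L) {
      bname <- paste0(lname, "_bn")
      bf <- bn_fwd(par_of(disc$par, bname), bn[[bname]], z, training)
      bn[[bname]] <- bf$state
      cc$bn <- bf$cache
      lf <- lrelu_fwd(bf$y, cfg$leaky_slope)
      cc$act <- lf
      h <- lf$y
    } else {
      y <- sigmoid_fwd(z)
      cc$sig <- y
      h <- y
    }
    cache[[i]] <- cc
  }
  disc$bn <- bn
  list(out = h, cache = cache, model = disc)
}

# returns parameter grads plus the gradient w.r.t. the mask input channel
disc_backward_impl <- function(disc, cache, dout, want_input_grad = TRUE) {
  cfg <- disc$cfg
  grads <- list()
  dh <- dout
  for (i in 6:1) {
    lname <- paste0("stack", i)
    cc <- cache[[i]]
    p <- par_of(disc$par, lname)
    if (i < 6L) {
      dz <- lrelu_bwd(cc$act, dh)
      bname <- paste0(lname, "_bn")
      bb <- bn_bwd(par_of(disc$par, bname), cc$bn, dz)
      grads[[paste0(bname, ".gamma")]] <- bb$dgamma
      grads[[paste0(bname, ".beta")]] <- bb$dbeta
      dz <- bb$dx
    } else {
      dz <- sigmoid_bwd(cc$sig, dh)
    }
    bw <- conv_bwd(p, cc$x_in, dz, cfg$kernel, cfg$strides[i], cc$pad)
    grads[[paste0(lname, ".w")]] <- bw$dw
    grads[[paste0(lname, ".b")]] <- bw$db
    dh <- bw$dx
  }
  dmask <- if (want_input_grad) dh[, , 4L, , drop = FALSE] else NULL
  list(grads = grads, dmask = dmask)
}

#' Patch-out: collapse a patch-score map to one scalar
#'
#' The arithmetic mean of all per-patch scores; the discriminator's single
#' real/fake probability for the whole input.
#'
#' @param map a `patch_score_map` (from [discriminator_forward()]) or a
#'   numeric matrix/array of patch scores.
#' @return A single number in `(0, 1)`.
#' @export
patch_out <- function(map) {
  s <- if (inherits(map, "patch_score_map")) map$scores else map
  if (length(s) == 0L) stop_validation("empty patch-score map")
  mean(s)
}
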