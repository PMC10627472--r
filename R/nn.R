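# Internal neural-network primitives.
#
# Convolutions run through the compiled im2col/GEMM kernels; batch
# normalization, activations, dropout and Adam live here. Activations are
# (H, W, C, N) arrays. Trainable tensors of a model are kept in one flat
# named list (`par`) so the optimizer is a simple tensor-wise walk; batch
# norm running statistics live in a parallel `bn` list and are updated only
# in training mode.

nn_init_conv <- function(k, cin, f, sd = 0.02) {
  list(w = matrix(rnorm(k * k * cin * f, 0, sd), nrow = k * k * cin, ncol = f),
       b = numeric(f))
}

# deconv weights: (k*k*f_out) x cin
nn_init_deconv <- function(k, cin, f, sd = 0.02) {
  list(w = matrix(rnorm(k * k * f * cin, 0, sd), nrow = k * k * f, ncol = cin),
       b = numeric(f))
}

nn_init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

bn_state_new <- function(c) list(mean = numeric(c), var = rep(1, c), n = 0L)

# "same"-style padding for even kernels: stride 2 halves the side
# (pad 1+1), stride 1 preserves it (pad 1+2, extra at bottom/right).
pad_same <- function(k, stride) {
  total <- k - stride
  if (total < 0) total <- 0
  c(floor(total / 2), ceiling(total / 2), floor(total / 2), ceiling(total / 2))
}

conv_fwd <- function(par, x, k, stride, pad) {
  .conv2d_fwd(x, par$w, par$b, k, k, stride, pad[1], pad[2], pad[3], pad[4])
}

conv_bwd <- function(par, x, dy, k, stride, pad) {
  .conv2d_bwd(x, par$w, dy, k, k, stride, pad[1], pad[2], pad[3], pad[4])
}

deconv_fwd <- function(par, x, k, stride, pad, oh, ow) {
  .deconv2d_fwd(x, par$w, par$b, k, k, stride, pad[1], pad[2], pad[3], pad[4], oh, ow)
}

deconv_bwd <- function(par, x, dy, k, stride, pad) {
  .deconv2d_bwd(x, par$w, dy, k, k, stride, pad[1], pad[2], pad[3], pad[4])
}

# Batch normalization over (H, W, N) per channel. Training mode normalizes
# with batch statistics and updates the running averages; evaluation mode
# uses the running averages (fall back to batch statistics before any
# training step has been taken).
bn_fwd <- function(par, state, x, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  ch <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = ch)
  use_batch <- training || state$n == 0L
  if (use_batch) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    if (training) {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v
      state$n <- state$n + 1L
    }
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(xm, 2, mu, "-")
  xhat <- sweep(xhat, 2, inv_std, "*")
  ym <- sweep(xhat, 2, par$gamma, "*")
  ym <- sweep(ym, 2, par$beta, "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], ch)), c(1, 2, 4, 3))
  list(y = y, state = state,
       cache = list(xhat = xhat, inv_std = inv_std, dims = d,
                    batch_stats = use_batch))
}

bn_bwd <- function(par, cache, dy) {
  d <- cache$dims
  ch <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = ch)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, par$gamma, "*")
  if (cache$batch_stats) {
    m <- nrow(dym)
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dxm <- sweep(t1 - t2, 2, cache$inv_std, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$inv_std, "*")
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], ch)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  list(y = x, neg = neg, slope = slope)
}

lrelu_bwd <- function(cache, dy) {
  dy[cache$neg] <- cache$slope * dy[cache$neg]
  dy
}

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

sigmoid_bwd <- function(y, dy) dy * y * (1 - y)

dropout_fwd <- function(x, p = 0.5) {
  keep <- 1 - p
  m <- array((runif(length(x)) < keep) / keep, dim(x))
  list(y = x * m, mask = m)
}

adam_state_new <- function(par) {
  list(t = 0L,
       m = lapply(par, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(par, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(par, grad, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = st)
}

# elementwise accumulate possibly-NULL gradients
acc_grad <- function(a, b) if (is.null(a)) b else a + b
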