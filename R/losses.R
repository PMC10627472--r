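#' L1 reconstruction loss between target and generated masks
#'
#' Pixel-level comparison of the generated mask against the target:
#' `sum_i |y_i - g_i|`, optionally divided by the number of pixels.
#' The mean form keeps the balance between the reconstruction weight and
#' the adversarial term independent of image resolution; the raw sum is
#' available via `mode = "sum"`.
#'
#' @param y target [binary_mask] (or numeric array).
#' @param g generated [probability_mask] (or numeric array of equal shape).
#' @param mode `"mean"` (default) or `"sum"`.
#' @return A non-negative number.
#' @export
reconstruction_loss <- function(y, g, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  yv <- if (inherits(y, c("binary_mask", "probability_mask"))) y$pixels else y
  gv <- if (inherits(g, c("binary_mask", "probability_mask"))) g$pixels else g
  if (!identical(dim(yv), dim(gv)))
    stop_validation("mask shapes differ: [%s] vs [%s]",
                    paste(dim(yv), collapse = ", "),
                    paste(dim(gv), collapse = ", "))
  s <- sum(abs(yv - gv))
  if (mode == "sum") s else s / length(yv)
}

#' Adversarial loss terms from patch-score maps
#'
#' Given the discriminator's patch scores on a real pair and on a generated
#' pair, returns the three cross-entropy terms of the minimax game, each an
#' expectation over all patches (and batch samples):
#' `d_real = -mean(log D(x, y))`, `d_fake = -mean(log(1 - D(x, G(x))))`,
#' and the generator's non-saturating surrogate
#' `g_adv = -mean(log D(x, G(x)))`. `d_real + d_fake` is the negated
#' adversarial objective restricted to the batch — the quantity the
#' discriminator minimizes. Log arguments are clamped to `[eps, 1 - eps]`.
#'
#' @param real_map patch scores on the real pair (`patch_score_map`, matrix
#'   or array).
#' @param fake_map patch scores on the generated pair.
#' @param eps log-clamp bound.
#' @param saturating if `TRUE`, use the saturating generator form
#'   `g_adv = mean(log(1 - D(x, G(x))))` instead of the non-saturating
#'   surrogate.
#' @return A list with non-negative `d_real`, `d_fake`, and `g_adv`
#'   (the saturating form can be negative).
#' @export
adversarial_terms <- function(real_map, fake_map, eps = 1e-7,
                              saturating = FALSE) {
  r <- if (inherits(real_map, "patch_score_map")) real_map$scores else real_map
  f <- if (inherits(fake_map, "patch_score_map")) fake_map$scores else fake_map
  if (length(r) == 0L || length(f) == 0L)
    stop_validation("empty patch-score map")
  eps <- check_number(eps, "eps", lower = 0, upper = 0.5)
  clamp <- function(v) pmin(pmax(v, eps), 1 - eps)
  list(d_real = -mean(log(clamp(r))),
       d_fake = -mean(log(clamp(1 - f))),
       g_adv = if (saturating) mean(log(clamp(1 - f))) else -mean(log(clamp(f))))
}

#' Discriminator loss
#'
#' The adversarial loss with scaling factor `alpha` applied to the sum of
#' the real and fake terms.
#'
#' @param d_real,d_fake cross-entropy terms from [adversarial_terms()].
#' @param alpha scaling factor (default 0.5).
#' @return `alpha * (d_real + d_fake)`.
#' @export
discriminator_loss <- function(d_real, d_fake, alpha = 0.5) {
  alpha * (d_real + d_fake)
}

#' Generator compound loss
#'
#' Weighted combination of the adversarial term and the reconstruction
#' term: `lambda1 * g_adv + lambda2 * g_rec`, with default weights 1
#' and 100.
#'
#' @param g_adv adversarial term (see [adversarial_terms()]).
#' @param g_rec reconstruction term (see [reconstruction_loss()]).
#' @param lambda1,lambda2 loss weights.
#' @return The compound loss.
#' @export
generator_loss <- function(g_adv, g_rec, lambda1 = 1, lambda2 = 100) {
  lambda1 * g_adv + lambda2 * g_rec
}
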