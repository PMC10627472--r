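test_that("generator output matches input resolution with sigmoid range", {
  set.seed(1)
  for (cfg in list(tiny_gcfg(side = 16, depth = 2),
                   generator_config(input_side = 64, depth = 4,
                                    base_filters = 4, dropout_levels = 1))) {
    gen <- build_generator(cfg)
    img <- wound_image(array(runif(cfg$input_side^2 * 3),
                             c(cfg$input_side, cfg$input_side, 3)))
    out <- generator_forward(gen, img)
    expect_s3_class(out, "probability_mask")
    expect_equal(dim(out$pixels), c(cfg$input_side, cfg$input_side))
    expect_gte(min(out$pixels), 0)
    expect_lte(max(out$pixels), 1)
  }
  expect_error(generator_config(input_side = 100, depth = 3),
               "divisible", class = "woundseg_validation_error")
  gen <- build_generator(tiny_gcfg(side = 16))
  bad <- wound_image(array(0.5, c(32, 32, 3)))
  expect_error(generator_forward(gen, bad), "16",
               class = "woundseg_validation_error")
})

test_that("discriminator walks the stride schedule and scores in (0,1)", {
  set.seed(2)
  disc <- build_discriminator(tiny_dcfg())
  img64 <- wound_image(array(runif(64 * 64 * 3), c(64, 64, 3)))
  msk64 <- binary_mask(matrix(as.numeric(runif(64 * 64) > 0.5), 64, 64))
  map <- discriminator_forward(disc, img64, msk64)
  # four stride-2 stacks then two stride-1: 64 -> 4 x 4, walked by hand
  expect_equal(dim(map$scores), c(4, 4))
  expect_true(all(map$scores > 0 & map$scores < 1))

  # evaluation mode is deterministic
  map2 <- discriminator_forward(disc, img64, msk64)
  expect_identical(map$scores, map2$scores)

  msk32 <- binary_mask(matrix(0, 32, 32))
  expect_error(discriminator_forward(disc, img64, msk32),
               class = "woundseg_validation_error")
  expect_error(discriminator_config(filters = c(4, 8, 8, 8, 8, 2)),
               class = "woundseg_validation_error")
})

test_that("patch_out is the mean and permutation-invariant", {
  expect_equal(patch_out(matrix(0.5, 3, 3)), 0.5)
  expect_equal(patch_out(matrix(c(0.1, 0.9, 0.3, 0.7), 2, 2)), 0.5)
  expect_equal(patch_out(matrix(0.42, 1, 1)), 0.42)
  set.seed(3)
  v <- runif(36)
  expect_equal(patch_out(matrix(v, 6, 6)),
               patch_out(matrix(sample(v), 6, 6)))
  expect_error(patch_out(matrix(numeric(0), 0, 0)),
               class = "woundseg_validation_error")
})

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("woundseg")
  set.seed(4)
  eps <- 1e-6

  gen <- build_generator(tiny_gcfg(side = 8, depth = 2))
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  fw <- ns$gen_forward_impl(gen, x, training = TRUE)
  gr <- ns$gen_backward_impl(gen, fw$cache, cos(fw$out))
  loss <- function(g) sum(sin(ns$gen_forward_impl(g, x, training = TRUE)$out))
  for (nm in names(gen$par)) {
    v <- gen$par[[nm]]
    for (i in sample(seq_along(v), min(3, length(v)))) {
      g1 <- gen; g1$par[[nm]][i] <- v[i] + eps
      g2 <- gen; g2$par[[nm]][i] <- v[i] - eps
      expect_equal(gr[[nm]][i], (loss(g1) - loss(g2)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }

  disc <- build_discriminator(tiny_dcfg())
  m <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fd <- ns$disc_forward_impl(disc, x, m, training = TRUE)
  bd <- ns$disc_backward_impl(disc, fd$cache, cos(fd$out))
  dloss <- function(d, mm) sum(sin(ns$disc_forward_impl(d, x, mm, training = TRUE)$out))
  for (nm in names(disc$par)) {
    v <- disc$par[[nm]]
    for (i in sample(seq_along(v), min(2, length(v)))) {
      d1 <- disc; d1$par[[nm]][i] <- v[i] + eps
      d2 <- disc; d2$par[[nm]][i] <- v[i] - eps
      expect_equal(bd$grads[[nm]][i], (dloss(d1, m) - dloss(d2, m)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  for (i in sample(seq_along(m), 8)) {
    m1 <- m; m1[i] <- m[i] + eps
    m2 <- m; m2[i] <- m[i] - eps
    expect_equal(bd$dmask[i], (dloss(disc, m1) - dloss(disc, m2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("one adversarial step moves the generator toward fooling D", {
  ns <- asNamespace("woundseg")
  set.seed(5)
  gen <- build_generator(tiny_gcfg(side = 16, depth = 2))
  disc <- build_discriminator(tiny_dcfg())
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  eps <- 1e-7

  g_adv_of <- function(g) {
    fake <- ns$gen_forward_impl(g, x, training = TRUE)$out
    s <- ns$disc_forward_impl(disc, x, fake, training = TRUE)$out
    -mean(log(pmin(pmax(s, eps), 1 - eps)))
  }
  before <- g_adv_of(gen)

  fw <- ns$gen_forward_impl(gen, x, training = TRUE)
  fd <- ns$disc_forward_impl(disc, x, fw$out, training = TRUE)
  dscore <- ns$grad_neglog(fd$out, eps)
  dmask <- ns$disc_backward_impl(disc, fd$cache, dscore)$dmask
  gr <- ns$gen_backward_impl(gen, fw$cache, dmask)
  for (nm in names(gen$par)) gen$par[[nm]] <- gen$par[[nm]] - 0.05 * gr[[nm]]

  expect_lt(g_adv_of(gen), before)
})
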