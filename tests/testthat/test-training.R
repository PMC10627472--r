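test_that("reconstruction loss matches hand values and a loop oracle", {
  y <- matrix(1, 2, 2)
  g <- matrix(0.75, 2, 2)
  expect_equal(reconstruction_loss(y, g, mode = "sum"), 1.0)
  expect_equal(reconstruction_loss(y, g, mode = "mean"), 0.25)
  expect_equal(reconstruction_loss(y, y), 0)
  y2 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(reconstruction_loss(y2, 1 - y2, mode = "mean"), 1.0)
  expect_error(reconstruction_loss(matrix(1, 2, 2), matrix(1, 3, 3)),
               class = "woundseg_validation_error")

  # brute-force elementwise oracle on random 8x8 fixtures
  set.seed(10)
  for (k in 1:20) {
    yy <- random_mask(8)
    gg <- matrix(runif(64), 8, 8)
    acc <- 0
    for (i in 1:8) for (j in 1:8) acc <- acc + abs(yy[i, j] - gg[i, j])
    expect_equal(reconstruction_loss(yy, gg, mode = "sum"), acc,
                 tolerance = 1e-6)
    expect_equal(reconstruction_loss(yy, gg, mode = "mean"), acc / 64,
                 tolerance = 1e-6)
    # symmetry of the absolute difference under label complement
    expect_equal(reconstruction_loss(yy, gg), reconstruction_loss(1 - yy, 1 - gg))
  }
})

test_that("adversarial terms reproduce the minimax objective by hand", {
  half <- matrix(0.5, 4, 4)
  at <- adversarial_terms(half, half)
  expect_equal(at$d_real, log(2), tolerance = 1e-9)
  expect_equal(at$d_fake, log(2), tolerance = 1e-9)
  expect_equal(at$g_adv, log(2), tolerance = 1e-9)
  expect_equal(at$d_real + at$d_fake, -(log(0.5) + log(0.5)), tolerance = 1e-9)

  eps <- 1e-7
  perfect <- adversarial_terms(matrix(1 - eps, 2, 2), matrix(eps, 2, 2), eps = eps)
  expect_lt(perfect$d_real, 1e-6)
  expect_lt(perfect$d_fake, 1e-6)
  fooled <- adversarial_terms(half, matrix(1 - eps, 2, 2), eps = eps)
  expect_lt(fooled$g_adv, 1e-6)

  # loop oracle on random maps
  set.seed(11)
  r <- matrix(runif(16, 0.1, 0.9), 4, 4)
  f <- matrix(runif(16, 0.1, 0.9), 4, 4)
  at <- adversarial_terms(r, f)
  dr <- 0; df <- 0; ga <- 0
  for (v in r) dr <- dr - log(v) / 16
  for (v in f) { df <- df - log(1 - v) / 16; ga <- ga - log(v) / 16 }
  expect_equal(at$d_real, dr, tolerance = 1e-6)
  expect_equal(at$d_fake, df, tolerance = 1e-6)
  expect_equal(at$g_adv, ga, tolerance = 1e-6)
  # saturating form
  expect_equal(adversarial_terms(r, f, saturating = TRUE)$g_adv, -df,
               tolerance = 1e-9)
})

test_that("scaled discriminator and compound generator losses are linear", {
  expect_equal(discriminator_loss(log(2), log(2), 0.5), log(2), tolerance = 1e-9)
  expect_equal(discriminator_loss(0, 0, 0.5), 0)
  expect_equal(discriminator_loss(1, 3, 0.5), 2)
  expect_equal(generator_loss(0.6931, 0.25, 1, 100), 25.6931, tolerance = 1e-9)
  expect_equal(generator_loss(0.37, 0, 1, 100), 0.37)
  expect_equal(generator_loss(0, 0.021, 1, 100), 2.1)
})

test_that("short training runs are seeded, counted and internally consistent", {
  pairs <- generate_dataset(8, side = 32, seed = 3)
  gcfg <- generator_config(input_side = 32, depth = 3, base_filters = 4,
                           dropout_levels = 1)
  dcfg <- tiny_dcfg()
  tcfg <- train_config(batch_size = 4, epochs = 2, seed = 9,
                       checkpoint_every = 2)

  d <- withr::local_tempdir()
  res <- train_gan(pairs, gcfg, dcfg, tcfg, out_dir = d)

  # epochs x floor(n / batch) recorded steps
  expect_equal(nrow(res$history), 4)
  expect_true(all(is.finite(as.matrix(res$history))))

  # the loss identities hold exactly at every step
  expect_equal(res$history$d_total,
               tcfg$alpha * (res$history$d_real + res$history$d_fake))
  expect_equal(res$history$g_total,
               tcfg$lambda1 * res$history$g_adv +
                 tcfg$lambda2 * res$history$g_rec)
  expect_true(all(res$history$g_rec >= 0))

  # run directory artifacts
  expect_true(file.exists(file.path(d, "history.tsv")))
  expect_true(file.exists(file.path(d, "ckpt_best.rds")))
  expect_true(file.exists(file.path(d, "ckpt_step2.rds")))
  ck <- load_checkpoint(file.path(d, "ckpt_best.rds"))
  expect_s3_class(ck$generator, "generator")

  # same fixture and seed reproduce the loss history
  res2 <- train_gan(pairs, gcfg, dcfg, tcfg)
  expect_equal(res$history, res2$history, tolerance = 1e-12)

  # a single-pair fine fixture still validates batch arithmetic
  expect_error(train_gan(list(), gcfg, dcfg, tcfg),
               class = "woundseg_validation_error")
})

test_that("segment_image runs a trained checkpoint end to end", {
  pairs <- generate_dataset(4, side = 32, seed = 13)
  gcfg <- generator_config(input_side = 32, depth = 2, base_filters = 4,
                           dropout_levels = 0)
  res <- train_gan(pairs, gcfg, tiny_dcfg(),
                   train_config(batch_size = 4, epochs = 2, seed = 1))
  seg <- segment_image(res$generator, pairs[[1]]$image)
  expect_s3_class(seg$prob, "probability_mask")
  expect_s3_class(seg$mask, "binary_mask")
  expect_equal(dim(seg$mask$pixels), c(32, 32))
  # larger input is resized into the model
  big <- fixture_disk(radius = 20, side = 128)
  seg2 <- segment_image(res$generator, big$image)
  expect_equal(dim(seg2$mask$pixels), c(32, 32))
})
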