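test_that("mask save/load round trip is exact and load_pair binarizes", {
  d <- withr::local_tempdir()
  sc <- fixture_disk(radius = 12, side = 64)
  img_p <- file.path(d, "img.png")
  msk_p <- file.path(d, "msk.png")
  save_image(sc$image, img_p)
  save_mask(sc$mask, msk_p)

  pair <- load_pair(img_p, msk_p)
  expect_identical(pair$mask$pixels, sc$mask$pixels)
  expect_equal(sum(pair$mask$pixels), sum(sc$mask$pixels))
  expect_true(all(pair$image$pixels >= 0 & pair$image$pixels <= 1))

  # all-black mask file decodes to the empty mask
  save_mask(binary_mask(matrix(0, 64, 64)), msk_p)
  expect_equal(sum(load_pair(img_p, msk_p)$mask$pixels), 0)

  # dimension mismatch is a validation error naming both shapes
  sc2 <- fixture_disk(radius = 6, side = 32)
  save_mask(sc2$mask, msk_p)
  expect_error(load_pair(img_p, msk_p), "64 x 64.*32 x 32",
               class = "woundseg_validation_error")
  expect_error(load_pair(file.path(d, "absent.png"), msk_p),
               class = "woundseg_io_error")
})

test_that("resize_to_model halves 512 to 256, is idempotent, keeps masks binary", {
  sc <- fixture_disk(radius = 60, side = 512)
  pair <- sample_pair(sc$image, sc$mask, "big")
  small <- resize_to_model(pair, side = 256)
  expect_equal(c(small$image$height, small$image$width), c(256, 256))
  expect_equal(c(small$mask$height, small$mask$width), c(256, 256))
  expect_true(all(small$mask$pixels %in% c(0, 1)))

  # already at target: identical pixels returned
  again <- resize_to_model(small, side = 256)
  expect_identical(again$image$pixels, small$image$pixels)
  expect_identical(again$mask$pixels, small$mask$pixels)

  # constant mask stays constant: foreground fraction exactly preserved
  ones <- sample_pair(wound_image(array(0.5, c(512, 512, 3))),
                      binary_mask(matrix(1, 512, 512)), "ones")
  expect_equal(mean(resize_to_model(ones, 256)$mask$pixels), 1)

  expect_error(resize_to_model(pair, side = 0),
               class = "woundseg_validation_error")
})

test_that("binarize thresholds with >= winning ties", {
  expect_equal(binarize(probability_mask(matrix(0.7, 4, 4)))$pixels,
               matrix(1, 4, 4))
  expect_equal(binarize(probability_mask(matrix(0.5, 4, 4)), 0.5)$pixels,
               matrix(1, 4, 4))
  p <- matrix(c(0.2, 0.5, 0.8, 0.49), 2, 2, byrow = TRUE)
  expect_equal(binarize(probability_mask(p))$pixels,
               matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_error(binarize(probability_mask(p), threshold = 1),
               class = "woundseg_validation_error")
})

test_that("augment_dataset multiplies counts and applies paired transforms", {
  sc <- fixture_disk(radius = 10, side = 48)
  pair <- sample_pair(sc$image, sc$mask, "p1")

  expect_length(augment_dataset(list(pair),
                                augmentation_policy(variants_per_image = 0)), 1)
  out <- augment_dataset(list(pair, pair, pair), augmentation_policy(seed = 3))
  expect_length(out, 12)
  expect_error(augment_dataset(list(), augmentation_policy()),
               class = "woundseg_validation_error")

  # every variant's mask equals the recorded transform applied to the original
  for (v in out) {
    if (is.null(v$transform)) next
    replay <- apply_transform(pair, v$transform)
    cm <- confusion(replay$mask, v$mask)
    expect_equal(dice(cm), 1.0)
    if (v$transform$kind %in% c("brightness", "saturation"))
      expect_identical(v$mask$pixels, pair$mask$pixels)
  }

  # a flip-only policy gives the mirrored mask
  flip_pol <- augmentation_policy(variants_per_image = 1,
                                  brightness_range = NULL,
                                  saturation_range = NULL,
                                  rotation_angles = numeric(),
                                  allow_vflip = FALSE, seed = 1)
  two <- augment_dataset(list(pair), flip_pol)
  expect_length(two, 2)
  flipped <- pair$mask$pixels[, ncol(pair$mask$pixels):1]
  expect_identical(two[[2]]$mask$pixels, flipped)

  # deterministic under a fixed policy seed
  again <- augment_dataset(list(pair, pair, pair), augmentation_policy(seed = 3))
  expect_identical(lapply(out, function(p) p$image$pixels),
                   lapply(again, function(p) p$image$pixels))

  # more variants than enabled techniques cannot be drawn without replacement
  expect_error(augmentation_policy(variants_per_image = 6),
               class = "woundseg_validation_error")
})

test_that("dataset directory layout and manifest both load", {
  d <- withr::local_tempdir()
  pairs <- generate_dataset(3, side = 32, seed = 5)
  write_dataset(pairs, d)
  expect_true(file.exists(file.path(d, "truth.tsv")))

  back <- read_dataset(d)
  expect_length(back, 3)
  expect_identical(back[[1]]$mask$pixels, pairs[[1]]$mask$pixels)

  mf <- file.path(d, "manifest.tsv")
  writeLines(paste(file.path(d, "images", "scene0001.png"),
                   file.path(d, "masks", "scene0001.png"), sep = "\t"), mf)
  one <- read_dataset(mf)
  expect_length(one, 1)
  expect_identical(one[[1]]$mask$pixels, pairs[[1]]$mask$pixels)
})
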