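test_that("clean_mask removes speckle, fills holes, and is idempotent", {
  m <- matrix(0, 64, 64)
  m[20:39, 20:39] <- 1                     # 20x20 square
  speck <- m
  speck[cbind(c(3, 5, 60, 50, 10), c(3, 55, 8, 50, 30))] <- 1
  cleaned <- clean_mask(binary_mask(speck))
  expect_identical(cleaned$pixels, m)      # the square only

  holed <- m
  holed[28:29, 28:29] <- 0                 # interior 2x2 hole
  expect_identical(clean_mask(binary_mask(holed))$pixels, m)

  # idempotence on the clean rectangle and on random masks
  expect_identical(clean_mask(cleaned)$pixels, cleaned$pixels)
  set.seed(8)
  for (k in 1:5) {
    r <- binary_mask(random_mask(48, 0.4))
    once <- clean_mask(r)
    expect_identical(clean_mask(once)$pixels, once$pixels)
  }
})

test_that("label_regions measures counts, boxes and contours", {
  m <- matrix(0, 50, 70)
  m[5:14, 5:24] <- 1                       # 20 wide x 10 tall
  m[30:45, 40:55] <- 1
  regs <- label_regions(binary_mask(m))
  expect_length(regs, 2)
  expect_true(regs[[1]]$area >= regs[[2]]$area)  # area-ranked

  # axis-aligned rectangle: exact pixel geometry
  expect_equal(regs[[1]]$area + regs[[2]]$area, sum(m))
  rect <- regs[[which.min(vapply(regs, function(r) r$area, 0))]]
  expect_equal(rect$area, 200)
  expect_equal(rect$width, 20)
  expect_equal(rect$length, 10)
  expect_equal(unname(rect$bbox), c(5, 15, 5, 25))

  # empty mask: empty list, not an error
  expect_length(label_regions(binary_mask(matrix(0, 8, 8))), 0)

  # disk contour arc length approaches the continuous perimeter
  disk <- fixture_disk(radius = 30)
  reg <- label_regions(disk$mask)[[1]]
  expect_lt(abs(reg$perimeter / (2 * pi * 30) - 1), 0.05)

  # 4- vs 8-connectivity: diagonal pixels split or join
  dm <- matrix(0, 10, 10)
  dm[2, 2] <- 1; dm[3, 3] <- 1
  expect_length(label_regions(binary_mask(dm), connectivity = 8), 1)
  expect_length(label_regions(binary_mask(dm), connectivity = 4), 2)
})

test_that("moment axes agree with an independent image-analysis oracle", {
  ell <- fixture_ellipse(a = 25, b = 15, orientation = 35, side = 112)
  reg <- label_regions(ell$mask)[[1]]
  lab <- EBImage::bwlabel(EBImage::Image(t(ell$mask$pixels)))
  ft <- EBImage::computeFeatures.moment(lab)
  expect_equal(reg$major_axis, unname(ft[1, "m.majoraxis"]), tolerance = 0.01)
  expect_equal(eccentricity(reg), unname(ft[1, "m.eccentricity"]),
               tolerance = 0.01)
})

test_that("shape descriptors converge to their closed forms", {
  # disk: circularity within 10% of 1/(4 pi); equivalent diameter within 2%
  disk <- fixture_disk(radius = 30)
  reg <- measure_regions(label_regions(disk$mask))[[1]]
  expect_lt(abs(reg$circularity / (1 / (4 * pi)) - 1), 0.10)
  expect_lt(abs(reg$equivalent_diameter / 60 - 1), 0.02)
  expect_lt(reg$eccentricity, 0.1)
  # rectangularity of a disk ~ pi / 4
  expect_lt(abs(reg$rectangularity / (pi / 4) - 1), 0.05)

  # axis-aligned rectangle: rectangularity exactly 1
  rect <- fixture_rect(width = 40, height = 20)
  rreg <- measure_regions(label_regions(rect$mask))[[1]]
  expect_equal(rreg$rectangularity, 1.0)
  expect_equal(rreg$width, 40)
  expect_equal(rreg$length, 20)

  # ellipse with full axes (50, 30): e = sqrt(1 - 0.6^2) = 0.8
  ell <- fixture_ellipse(a = 25, b = 15, orientation = 0, side = 112)
  ereg <- measure_regions(label_regions(ell$mask))[[1]]
  expect_equal(ereg$eccentricity, 0.8, tolerance = 0.03 / 0.8)
  expect_equal(ereg$major_axis, 50, tolerance = 0.03)
  expect_equal(ereg$minor_axis, 30, tolerance = 0.03)

  # eccentricity edge cases from the definition
  line <- matrix(0, 20, 20); line[10, 3:17] <- 1
  lreg <- label_regions(binary_mask(line))[[1]]
  expect_equal(eccentricity(lreg), 1)
  expect_equal(eccentricity(list(major_axis = 10, minor_axis = 6)), 0.8)

  # isoperimetric bound with rasterization slack
  set.seed(12)
  for (k in 1:5) {
    blob <- clean_mask(binary_mask(random_mask(48, 0.55)))
    for (r in measure_regions(label_regions(blob)))
      expect_lt(r$circularity, 1 / (4 * pi) * 1.15)
  }
})

test_that("shape calls recover the generating kind", {
  thr <- shape_thresholds()
  rect <- measure_regions(label_regions(fixture_rect(width = 36, height = 24,
                                                     corner_radius = 4)$mask))[[1]]
  expect_equal(rect$shape_call, "rectangle")
  disk <- measure_regions(label_regions(fixture_disk(radius = 18)$mask))[[1]]
  expect_equal(disk$shape_call, "circle")
  ell <- measure_regions(label_regions(fixture_ellipse(a = 22, b = 11,
                                                       orientation = 40)$mask))[[1]]
  expect_equal(ell$shape_call, "ellipse")    # e ~ 0.866, psi ~ pi/4

  # seeded jitter-free suite: >= 95% of calls match the planted kind
  acc <- shape_suite_accuracy(n_scenes = 60, side = 128, seed = 11)
  expect_gte(acc$accuracy, 0.95)
})

test_that("report_dimensions picks the fields of the called shape", {
  disk <- measure_regions(label_regions(fixture_disk(radius = 30)$mask))[[1]]
  rep <- report_dimensions(disk)
  expect_true("diameter" %in% names(rep))
  expect_lt(abs(rep$diameter / 60 - 1), 0.02)

  rect <- measure_regions(label_regions(fixture_rect(40, 20)$mask))[[1]]
  rep <- report_dimensions(rect)
  expect_equal(rep$width, 40)
  expect_equal(rep$length, 20)

  ell <- measure_regions(label_regions(fixture_ellipse(25, 15, 0)$mask))[[1]]
  rep <- report_dimensions(ell)
  expect_equal(rep$major_axis, 50, tolerance = 0.03)
  expect_equal(rep$minor_axis, 30, tolerance = 0.03)
})

test_that("annotate draws ranked boundary colors and analyze_mask assembles a table", {
  s1 <- shape_spec("disk", center = c(30, 30), size = list(radius = 14),
                   boundary_jitter = 0)
  s2 <- shape_spec("disk", center = c(90, 40), size = list(radius = 10),
                   boundary_jitter = 0)
  s3 <- shape_spec("disk", center = c(60, 95), size = list(radius = 7),
                   boundary_jitter = 0)
  sc <- render_scene(scene_spec(128, list(s1, s2, s3), seed = 2))

  res <- analyze_mask(sc$mask, image = sc$image)
  expect_equal(nrow(res$table), 3)
  expect_equal(res$table$shape_call, rep("circle", 3))

  # largest wound green, second yellow, third blue, at the traced contours
  regs <- res$regions
  px <- res$overlay$pixels
  cols <- list(c(0, 1, 0), c(1, 1, 0), c(0, 0, 1))
  for (i in 1:3) {
    ct <- regs[[i]]$contour[1, , drop = FALSE]
    expect_equal(as.numeric(px[ct[1], ct[2], ]), cols[[i]])
  }

  # no regions: untouched image, empty table
  blank <- analyze_mask(binary_mask(matrix(0, 32, 32)),
                        image = wound_image(array(0.4, c(32, 32, 3))))
  expect_equal(nrow(blank$table), 0)
  expect_identical(blank$overlay$pixels, array(0.4, c(32, 32, 3)))

  # mm-per-px scaling multiplies lengths and areas
  scaled <- analyze_mask(sc$mask, mm_per_px = 2)
  expect_equal(scaled$table$area_px, res$table$area_px * 4)
  expect_equal(scaled$table$perimeter_px, res$table$perimeter_px * 2)
})
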