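# Fixtures are generated in code; nothing is read from disk except what a
# test itself writes to a tempdir.

# jitter-free single-shape scene, centered
fixture_scene <- function(kind, side, size, seed = 1) {
  ctr <- c(side / 2 + 0.5, side / 2 + 0.5)  # half-integer: even extents rasterize exactly
  s <- shape_spec(kind, center = ctr, size = size, boundary_jitter = 0)
  render_scene(scene_spec(side, list(s), seed = seed))
}

fixture_disk <- function(radius = 30, side = 2 * radius + 21, seed = 1)
  fixture_scene("disk", side, list(radius = radius), seed)

fixture_ellipse <- function(a = 25, b = 15, orientation = 0, side = 96, seed = 1)
  fixture_scene("ellipse", side, list(a = a, b = b, orientation = orientation), seed)

fixture_rect <- function(width = 40, height = 20, corner_radius = 1e-9,
                         side = 80, seed = 1)
  fixture_scene("rounded_rectangle", side,
                list(width = width, height = height,
                     corner_radius = corner_radius), seed)

# tiny random binary masks for metric property tests
random_mask <- function(side = 16, p = 0.5) {
  matrix(as.numeric(runif(side * side) < p), side, side)
}

# small configurations for fast network tests
tiny_gcfg <- function(side = 16, depth = 2)
  generator_config(input_side = side, depth = depth, base_filters = 4,
                   dropout_levels = 0)

tiny_dcfg <- function()
  discriminator_config(filters = c(4, 8, 8, 8, 8, 1))

# the overfit training fixture: 8 synthetic 64x64 scenes, seed 7
overfit_fixture <- function() {
  list(pairs = generate_dataset(8, side = 64, seed = 7),
       gcfg = generator_config(input_side = 64, depth = 4, base_filters = 16,
                               dropout_levels = 0),
       dcfg = discriminator_config(filters = c(16, 32, 64, 64, 64, 1)),
       tcfg = train_config(batch_size = 4, epochs = 150, seed = 7))
}

# score shape calls of a jitter-free scene suite against the generating kinds
shape_suite_accuracy <- function(n_scenes = 200, side = 128, seed = 11) {
  pairs <- generate_dataset(n_scenes, side = side, seed = seed,
                            size_frac = c(0.18, 0.35), jitter = 0)
  truth <- attr(pairs, "truth")
  kind_map <- c(disk = "circle", ellipse = "ellipse",
                rounded_rectangle = "rectangle")
  hits <- 0L
  total <- 0L
  for (p in pairs) {
    regs <- measure_regions(label_regions(p$mask))
    tr <- truth[truth$id == p$id, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      ctr <- c(tr$center_row[j], tr$center_col[j])
      dists <- vapply(regs, function(r) sqrt(sum((r$centroid - ctr)^2)), 0)
      reg <- regs[[which.min(dists)]]
      total <- total + 1L
      if (identical(reg$shape_call, unname(kind_map[tr$kind[j]])))
        hits <- hits + 1L
    }
  }
  list(accuracy = hits / total, n = total)
}
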