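#' Specification of one synthetic wound shape
#'
#' Supported kinds: `disk` (size = `radius`), `ellipse` (size =
#' semi-axes `a`, `b` plus `orientation` in degrees) and
#' `rounded_rectangle` (size = `width` x `height` plus `corner_radius`;
#' always axis-aligned). `boundary_jitter` perturbs the outline with a
#' smooth low-frequency radial modulation, expressed as a fraction of the
#' shape size, so rendered wounds are not perfect conics.
#'
#' @param kind one of `"disk"`, `"ellipse"`, `"rounded_rectangle"`.
#' @param center `(row, col)` center in pixels.
#' @param size named list of kind-specific dimensions (see above), in
#'   pixels.
#' @param boundary_jitter jitter amplitude as a fraction of size.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(kind = c("disk", "ellipse", "rounded_rectangle"),
                       center, size, boundary_jitter = 0.03) {
  kind <- match.arg(kind)
  if (length(center) != 2L || any(!is.finite(center)))
    stop_validation("`center` must be (row, col)")
  boundary_jitter <- check_number(boundary_jitter, "boundary_jitter",
                                  lower = 0, upper = 0.5)
  need <- switch(kind,
    disk = "radius",
    ellipse = c("a", "b", "orientation"),
    rounded_rectangle = c("width", "height", "corner_radius"))
  if (!all(need %in% names(size)))
    stop_validation("size for a %s needs fields: %s", kind,
                    paste(need, collapse = ", "))
  for (nm in setdiff(need, "orientation"))
    if (size[[nm]] <= 0) stop_validation("size field `%s` must be positive", nm)
  if (kind == "ellipse" && size$b > size$a)
    stop_validation("ellipse semi-axes need a >= b")
  if (kind == "rounded_rectangle" &&
      size$corner_radius > min(size$width, size$height) / 2)
    stop_validation("corner radius exceeds half the shorter side")
  structure(list(kind = kind, center = as.numeric(center), size = size,
                 boundary_jitter = boundary_jitter),
            class = "shape_spec")
}

# conservative outer radius of a shape, jitter included
shape_extent <- function(s) {
  r <- switch(s$kind,
    disk = s$size$radius,
    ellipse = s$size$a,
    rounded_rectangle = sqrt(s$size$width^2 + s$size$height^2) / 2)
  r * (1 + s$boundary_jitter) + 1
}

#' Specification of a synthetic wound scene
#'
#' @param side image side in pixels.
#' @param shapes list of 1-3 [shape_spec()] objects; shapes must fit inside
#'   the image with a 2-pixel margin and be pairwise separated by at least
#'   3 pixels.
#' @param skin_tone background base RGB (each in `[0, 1]`).
#' @param noise_level standard deviation of the additive texture noise.
#' @param seed RNG seed; rendering is fully deterministic given the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(side, shapes, skin_tone = c(0.72, 0.55, 0.45),
                       noise_level = 0.02, seed = 1) {
  side <- check_count(side, "side", lower = 16)
  if (!length(shapes) || length(shapes) > 3L)
    stop_validation("a scene holds 1-3 shapes, got %d", length(shapes))
  for (s in shapes) stopifnot(inherits(s, "shape_spec"))
  if (length(skin_tone) != 3L || any(skin_tone < 0 | skin_tone > 1))
    stop_validation("`skin_tone` must be an RGB triple in [0, 1]")
  noise_level <- check_number(noise_level, "noise_level", lower = 0, upper = 1)
  structure(list(side = side, shapes = shapes, skin_tone = as.numeric(skin_tone),
                 noise_level = noise_level, seed = check_count(seed, "seed")),
            class = "scene_spec")
}

# smooth periodic modulation in [-1, 1]: a few low-order harmonics with
# random phases, normalized amplitudes
jitter_fun <- function() {
  ks <- 2:4
  amp <- runif(3, 0.3, 1)
  amp <- amp / sum(amp)
  phase <- runif(3, 0, 2 * pi)
  function(theta) {
    out <- 0
    for (i in 1:3) out <- out + amp[i] * cos(ks[i] * theta + phase[i])
    out
  }
}

# rasterize one shape on the pixel grid; RNG supplies the jitter harmonics
rasterize_shape <- function(s, side) {
  rr <- matrix(seq_len(side), side, side) - s$center[1]
  cc <- matrix(seq_len(side), side, side, byrow = TRUE) - s$center[2]
  jf <- if (s$boundary_jitter > 0) jitter_fun() else function(theta) 0
  if (s$kind == "disk") {
    theta <- atan2(rr, cc)
    rho <- sqrt(rr^2 + cc^2)
    inside <- rho <= s$size$radius * (1 + s$boundary_jitter * jf(theta))
  } else if (s$kind == "ellipse") {
    ang <- s$size$orientation * pi / 180
    u <- cos(ang) * cc + sin(ang) * rr
    v <- -sin(ang) * cc + cos(ang) * rr
    theta <- atan2(v, u)
    rho <- sqrt((u / s$size$a)^2 + (v / s$size$b)^2)
    inside <- rho <= 1 + s$boundary_jitter * jf(theta)
  } else {
    hw <- s$size$width / 2
    hh <- s$size$height / 2
    cr <- s$size$corner_radius
    qx <- abs(cc) - (hw - cr)
    qy <- abs(rr) - (hh - cr)
    sd_out <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0) - cr
    theta <- atan2(rr, cc)
    inside <- sd_out <= s$boundary_jitter * min(hw, hh) * jf(theta)
  }
  inside + 0
}

#' Render a synthetic wound scene
#'
#' The ground-truth mask is the exact rasterization of the (jittered)
#' shapes; wound interiors are rendered reddish over a noisy skin-toned
#' background, so the red channel is systematically elevated inside the
#' wound — the cue a segmentation network can learn. Rendering is
#' deterministic for a fixed spec (including its seed).
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` ([wound_image]), `mask` ([binary_mask]) and
#'   `shapes` (the input [shape_spec()] list).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  side <- spec$side
  with_seed(spec$seed, {
    shape_masks <- lapply(spec$shapes, rasterize_shape, side = side)
    for (i in seq_along(spec$shapes)) {
      m <- shape_masks[[i]]
      if (!sum(m)) stop_validation("shape %d rasterizes to nothing", i)
      fg <- which(m == 1, arr.ind = TRUE)
      if (min(fg) <= 2 || max(fg[, 1]) > side - 2 || max(fg[, 2]) > side - 2)
        stop_validation("shape %d does not fit inside the image with a 2-px margin", i)
    }
    if (length(shape_masks) > 1L) {
      brush <- EBImage::makeBrush(7, "disc")     # radius-3 disk
      for (i in seq_along(shape_masks)) {
        dil <- EBImage::dilate(EBImage::Image(t(shape_masks[[i]])), brush)
        dil <- t(EBImage::imageData(dil))
        for (j in seq_along(shape_masks)) {
          if (j == i) next
          if (any(dil * shape_masks[[j]] > 0))
            stop_validation("shapes %d and %d overlap or sit closer than 3 px", i, j)
        }
      }
    }
    mask <- Reduce(`+`, shape_masks)
    mask[mask > 1] <- 1

    img <- array(0, c(side, side, 3))
    for (ch in 1:3)
      img[, , ch] <- spec$skin_tone[ch] +
        matrix(rnorm(side * side, 0, spec$noise_level), side, side)
    wound_base <- c(0.92, 0.15, 0.18)
    for (i in seq_along(shape_masks)) {
      col <- pmin(pmax(wound_base + rnorm(3, 0, 0.02), 0), 1)
      idx <- shape_masks[[i]] == 1
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- col[ch] + rnorm(sum(idx), 0, spec$noise_level)
        img[, , ch] <- plane
      }
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = wound_image(img), mask = binary_mask(mask), shapes = spec$shapes)
  })
}

sample_shape <- function(side, kind, size_frac, jitter, margin = 4) {
  ext_frac <- runif(1, size_frac[1], size_frac[2])
  ext <- ext_frac * side / 2                     # half of the full extent
  size <- switch(kind,
    disk = list(radius = ext),
    ellipse = list(a = ext, b = ext * runif(1, 0.45, 0.8),
                   orientation = runif(1, 0, 180)),
    rounded_rectangle = {
      w <- 2 * ext
      h <- w * runif(1, 0.5, 1)
      if (runif(1) < 0.5) { tmp <- w; w <- h; h <- tmp }
      list(width = w, height = h,
           corner_radius = runif(1, 0.10, 0.25) * min(w, h))
    })
  s <- shape_spec(kind, center = c(side / 2, side / 2), size = size,
                  boundary_jitter = jitter)
  reach <- shape_extent(s) + margin
  if (reach >= side / 2) reach <- side / 2 - 1
  s$center <- runif(2, reach + 1, side - reach)
  s
}

#' Generate a seeded synthetic dataset
#'
#' Each scene holds 1-3 non-overlapping shapes with randomized kinds,
#' sizes, positions and skin tones. The generating shape parameters are
#' attached as a `truth` attribute (one row per shape) so downstream shape
#' calls can be scored against the ground truth.
#'
#' @param n number of scenes.
#' @param side image side in pixels.
#' @param seed RNG seed; the same seed reproduces the dataset bit for bit.
#' @param shapes_per_scene integer range of shape counts.
#' @param size_frac range of shape extents as a fraction of `side`.
#' @param jitter boundary jitter fraction (0 gives exact conics).
#' @param kinds shape kinds to sample from (uniformly).
#' @return A list of [sample_pair] objects with attribute `truth`, a data
#'   frame with columns `id`, `shape`, `kind`, `center_row`, `center_col`
#'   and the size parameters.
#' @export
generate_dataset <- function(n, side = 256, seed = 1,
                             shapes_per_scene = c(1L, 3L),
                             size_frac = c(0.10, 0.30), jitter = 0.03,
                             kinds = c("disk", "ellipse", "rounded_rectangle")) {
  n <- check_count(n, "n", lower = 1)
  side <- check_count(side, "side", lower = 16)
  with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
    pairs <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("scene%04d", i)
      k <- sample(seq(shapes_per_scene[1], shapes_per_scene[2]), 1)
      shapes <- list()
      tries <- 0L
      while (length(shapes) < k && tries < 400L) {
        tries <- tries + 1L
        cand <- sample_shape(side, sample(kinds, 1), size_frac, jitter)
        ok <- TRUE
        for (s in shapes) {
          d <- sqrt(sum((cand$center - s$center)^2))
          if (d < shape_extent(cand) + shape_extent(s) + 4) { ok <- FALSE; break }
        }
        if (ok) shapes[[length(shapes) + 1L]] <- cand
      }
      tone <- pmin(pmax(c(0.72, 0.55, 0.45) + rnorm(3, 0, 0.03), 0), 1)
      sc <- scene_spec(side, shapes, skin_tone = tone,
                       seed = scene_seeds[i])
      r <- render_scene(sc)
      pairs[[i]] <- sample_pair(r$image, r$mask, id = id)
      truth[[i]] <- do.call(rbind, lapply(seq_along(shapes), function(j) {
        s <- shapes[[j]]
        data.frame(id = id, shape = j, kind = s$kind,
                   center_row = s$center[1], center_col = s$center[2],
                   radius = s$size$radius %||% NA_real_,
                   a = s$size$a %||% NA_real_, b = s$size$b %||% NA_real_,
                   orientation = s$size$orientation %||% NA_real_,
                   width = s$size$width %||% NA_real_,
                   height = s$size$height %||% NA_real_,
                   corner_radius = s$size$corner_radius %||% NA_real_)
      }))
    }
    structure(pairs, truth = do.call(rbind, truth))
  })
}
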