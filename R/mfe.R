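#' Mask cleanup parameters
#'
#' Controls the noise and hole removal applied to a predicted mask before
#' measurement: morphological opening with a disk (removes speckle),
#' filling of interior holes, and removal of components smaller than a
#' fraction of the image area.
#'
#' @param opening_radius disk radius of the opening in pixels (0 skips it).
#' @param min_area minimum component area as a fraction of the image area.
#' @param fill_holes fill background regions not reachable from the image
#'   border.
#' @param connectivity pixel adjacency for component analysis (4 or 8).
#' @return A `cleanup_params` list.
#' @export
cleanup_params <- function(opening_radius = 2, min_area = 5e-4,
                           fill_holes = TRUE, connectivity = 8) {
  opening_radius <- check_count(opening_radius, "opening_radius")
  min_area <- check_number(min_area, "min_area", lower = 0, upper = 1 - 1e-12)
  if (!connectivity %in% c(4, 8))
    stop_validation("connectivity must be 4 or 8")
  structure(list(opening_radius = opening_radius, min_area = min_area,
                 fill_holes = isTRUE(fill_holes),
                 connectivity = as.integer(connectivity)),
            class = "cleanup_params")
}

#' Shape-call thresholds
#'
#' The decision rule is: rectangle if rectangularity >= `tau_rect`,
#' otherwise circle if eccentricity <= `tau_circ_ecc`, otherwise ellipse.
#'
#' @param tau_rect rectangularity threshold.
#' @param tau_circ_ecc eccentricity threshold separating circles from
#'   ellipses.
#' @return A `shape_thresholds` list.
#' @export
shape_thresholds <- function(tau_rect = 0.85, tau_circ_ecc = 0.40) {
  tau_rect <- check_number(tau_rect, "tau_rect", lower = 1e-9, upper = 1 - 1e-9)
  tau_circ_ecc <- check_number(tau_circ_ecc, "tau_circ_ecc",
                               lower = 1e-9, upper = 1 - 1e-9)
  structure(list(tau_rect = tau_rect, tau_circ_ecc = tau_circ_ecc),
            class = "shape_thresholds")
}

#' Clean a binary mask for measurement
#'
#' Speckle is removed by opening-by-reconstruction with a disk of
#' `opening_radius`: components that vanish under a plain opening are
#' dropped, while surviving components keep their exact shape (a plain
#' opening would also shave single-pixel extremities off small round
#' regions and distort their descriptors). Then interior holes are
#' filled and components below the area floor removed. The operation is
#' idempotent: applying it twice equals applying it once.
#'
#' @param mask a [binary_mask].
#' @param params a [cleanup_params()].
#' @return The cleaned [binary_mask].
#' @export
clean_mask <- function(mask, params = cleanup_params()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(params, "cleanup_params"))
  m <- mask$pixels
  if (params$opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$opening_radius + 1L, "disc")
    opened <- t(EBImage::imageData(EBImage::opening(EBImage::Image(t(m)), brush)))
    lab <- .label_components(matrix(as.integer(m), nrow(m), ncol(m)),
                             params$connectivity)
    survivors <- unique(lab[opened > 0 & lab > 0])
    m[!(lab %in% survivors)] <- 0
  }
  if (params$fill_holes)
    m <- .fill_holes(matrix(as.integer(m), nrow(m), ncol(m))) + 0
  if (params$min_area > 0) {
    lab <- .label_components(matrix(as.integer(m), nrow(m), ncol(m)),
                             params$connectivity)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0], nbins = max(lab))
      drop <- which(areas < params$min_area * length(m))
      if (length(drop)) m[lab %in% drop] <- 0
    }
  }
  binary_mask(m + 0)
}

#' Label wound regions and measure their geometry
#'
#' One record per connected foreground component, ordered by decreasing
#' area. Area is the pixel count; the perimeter is the closed
#' outer-contour arc length (unit steps for 4-neighbor moves, sqrt(2) for
#' diagonals); the bounding box is half-open `[r0, r1) x [c0, c1)` with
#' `width` the column extent and `length` the row extent; major/minor axes
#' are the full axes of the moment-equivalent ellipse (from central second
#' moments).
#'
#' @param mask a cleaned [binary_mask].
#' @param connectivity 4 or 8.
#' @return A list of `region_measurement` records (descriptors unset until
#'   [measure_regions()] fills them); empty list for an empty mask.
#' @export
label_regions <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(4, 8)) stop_validation("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask$pixels), mask$height, mask$width)
  lab <- .label_components(m, as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  ord <- order(areas, decreasing = TRUE)
  out <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    l <- ord[k]
    px <- which(lab == l, arr.ind = TRUE)
    A <- nrow(px)
    tc <- .trace_contour(lab, l)
    r0 <- min(px[, 1]); r1 <- max(px[, 1]) + 1L
    c0 <- min(px[, 2]); c1 <- max(px[, 2]) + 1L
    mu_r <- mean(px[, 1]); mu_c <- mean(px[, 2])
    m20 <- mean((px[, 1] - mu_r)^2)
    m02 <- mean((px[, 2] - mu_c)^2)
    m11 <- mean((px[, 1] - mu_r) * (px[, 2] - mu_c))
    tr2 <- (m20 + m02) / 2
    det <- sqrt(((m20 - m02) / 2)^2 + m11^2)
    l1 <- tr2 + det
    l2 <- max(tr2 - det, 0)
    out[[k]] <- structure(list(
      label = k, area = A, perimeter = tc$perimeter,
      bbox = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1),
      width = c1 - c0, length = r1 - r0,
      major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
      equivalent_diameter = 2 * sqrt(A / pi),
      centroid = c(mu_r, mu_c), contour = tc$contour,
      eccentricity = NA_real_, circularity = NA_real_,
      rectangularity = NA_real_, shape_call = NA_character_),
      class = "region_measurement")
  }
  out
}

#' Shape descriptors of a measured region
#'
#' Eccentricity is the standard ellipse eccentricity of the
#' moment-equivalent ellipse, `sqrt(major^2 - minor^2) / major` (the
#' inter-focal distance over the major axis length), 0 for a circle and 1
#' for a line. Circularity is `area / perimeter^2`, maximized at
#' `1 / (4 * pi)` by a disk. Rectangularity is the region area over its
#' bounding-box area, exactly 1 for an axis-aligned rectangle.
#'
#' @param reg a `region_measurement` from [label_regions()].
#' @return A number.
#' @export
eccentricity <- function(reg) {
  if (reg$major_axis <= 0) return(0)
  if (reg$minor_axis <= 0) return(1)
  sqrt(max(reg$major_axis^2 - reg$minor_axis^2, 0)) / reg$major_axis
}

#' @rdname eccentricity
#' @export
circularity <- function(reg) {
  if (reg$perimeter <= 0) stop_validation("perimeter must be positive")
  reg$area / reg$perimeter^2
}

#' @rdname eccentricity
#' @export
rectangularity <- function(reg) {
  reg$area / (reg$width * reg$length)
}

#' Call the approximate shape of a region
#'
#' Rectangle if the bounding box is nearly filled
#' (`rectangularity >= tau_rect`), else circle if the moment ellipse is
#' nearly isotropic (`eccentricity <= tau_circ_ecc`), else ellipse. The
#' call suggests the dressing shape for the wound.
#'
#' @param reg a `region_measurement` with descriptors computed (see
#'   [measure_regions()]).
#' @param thr a [shape_thresholds()].
#' @return One of `"rectangle"`, `"circle"`, `"ellipse"`.
#' @export
classify_shape <- function(reg, thr = shape_thresholds()) {
  e <- if (is.na(reg$eccentricity)) eccentricity(reg) else reg$eccentricity
  psi <- if (is.na(reg$rectangularity)) rectangularity(reg) else reg$rectangularity
  if (psi >= thr$tau_rect) "rectangle"
  else if (e <= thr$tau_circ_ecc) "circle"
  else "ellipse"
}

#' Fill descriptors and shape calls of labeled regions
#'
#' @param regions list from [label_regions()].
#' @param thr a [shape_thresholds()].
#' @return The list with `eccentricity`, `circularity`, `rectangularity`
#'   and `shape_call` set.
#' @export
measure_regions <- function(regions, thr = shape_thresholds()) {
  lapply(regions, function(reg) {
    reg$eccentricity <- eccentricity(reg)
    reg$circularity <- circularity(reg)
    reg$rectangularity <- rectangularity(reg)
    reg$shape_call <- classify_shape(reg, thr)
    reg
  })
}

#' Dimensions to display for a region, per its shape call
#'
#' Circles report the equivalent diameter, ellipses their major/minor
#' axes, rectangles their bounding-box width and length; all include area
#' and perimeter.
#'
#' @param reg a measured `region_measurement` with `shape_call` set.
#' @return A named list of display dimensions.
#' @export
report_dimensions <- function(reg) {
  if (is.na(reg$shape_call)) stop_validation("shape_call not set; run measure_regions()")
  base <- list(area = reg$area, perimeter = reg$perimeter)
  c(switch(reg$shape_call,
           circle = list(diameter = reg$equivalent_diameter),
           ellipse = list(major_axis = reg$major_axis,
                          minor_axis = reg$minor_axis),
           rectangle = list(width = reg$width, length = reg$length)),
    base)
}

region_table <- function(regions, mm_per_px = NULL) {
  if (!length(regions))
    return(data.frame(label = integer(), shape_call = character(),
                      area_px = numeric(), perimeter_px = numeric(),
                      width = numeric(), length = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      equivalent_diameter = numeric(), eccentricity = numeric(),
                      circularity = numeric(), rectangularity = numeric()))
  s <- if (is.null(mm_per_px)) 1 else mm_per_px
  do.call(rbind, lapply(regions, function(r) data.frame(
    label = r$label, shape_call = r$shape_call,
    area_px = r$area * s^2, perimeter_px = r$perimeter * s,
    width = r$width * s, length = r$length * s,
    major_axis = r$major_axis * s, minor_axis = r$minor_axis * s,
    equivalent_diameter = r$equivalent_diameter * s,
    eccentricity = r$eccentricity, circularity = r$circularity,
    rectangularity = r$rectangularity)))
}

#' Analyze a segmentation mask: cleanup, labeling, descriptors, overlay
#'
#' The full post-processing pipeline: the mask is cleaned, connected
#' regions are labeled and measured, shape descriptors and calls are
#' computed, and (when an image is supplied) region boundaries are drawn
#' over it, cycling green, yellow, blue by area rank.
#'
#' @param mask a [binary_mask] (for instance from [segment_image()]).
#' @param image optional [wound_image] for the overlay.
#' @param params a [cleanup_params()].
#' @param thr a [shape_thresholds()].
#' @param mm_per_px optional scale; lengths in the table are multiplied by
#'   it (and areas by its square).
#' @return A list with `regions` (measured records), `table` (one row per
#'   region) and `overlay` (annotated [wound_image] or `NULL`).
#' @export
analyze_mask <- function(mask, image = NULL, params = cleanup_params(),
                         thr = shape_thresholds(), mm_per_px = NULL) {
  cleaned <- clean_mask(mask, params)
  regions <- measure_regions(label_regions(cleaned, params$connectivity), thr)
  overlay <- if (!is.null(image)) annotate(image, regions)$image else NULL
  list(regions = regions, table = region_table(regions, mm_per_px),
       overlay = overlay, cleaned = cleaned)
}

#' Draw region boundaries over an image
#'
#' Boundaries are colored green, yellow, blue cycling by area rank (the
#' largest wound is green). Region dimensions are returned as a
#' tab-separable table rather than rendered text.
#'
#' @param image a [wound_image].
#' @param regions measured regions from [measure_regions()].
#' @return A list with `image` (the annotated [wound_image]) and `table`.
#' @export
annotate <- function(image, regions) {
  stopifnot(inherits(image, "wound_image"))
  px <- image$pixels
  cols <- list(c(0, 1, 0), c(1, 1, 0), c(0, 0, 1))   # green, yellow, blue
  for (i in seq_along(regions)) {
    col <- cols[[(i - 1) %% 3 + 1]]
    ct <- regions[[i]]$contour
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[ct] <- col[ch]
      px[, , ch] <- plane
    }
  }
  list(image = wound_image(px), table = region_table(regions))
}
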