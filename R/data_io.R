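# Reading, writing, preprocessing and paired augmentation of image/mask data.
# PNG/JPEG decoding, resizing and encoding are delegated to EBImage; note
# EBImage stores images x-major, so pixels are transposed at the boundary to
# the package's row-major (origin top-left) convention.

ebimage_to_array <- function(img) {
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) t(px) else aperm(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                              c(2, 1, 3))
}

array_to_ebimage <- function(px) {
  if (is.matrix(px)) EBImage::Image(t(px))
  else EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
}

#' Load an image/mask pair from disk
#'
#' The image is scaled to `[0, 1]`; the mask is converted to luminance and
#' binarized (pixels brighter than half of full scale become wound). Both
#' files must decode to the same spatial dimensions.
#'
#' @param image_path path to a PNG/JPEG photograph.
#' @param mask_path path to the paired mask image (single-channel or RGB).
#' @param id identifier; defaults to the image file name.
#' @return A [sample_pair].
#' @export
load_pair <- function(image_path, mask_path,
                      id = tools::file_path_sans_ext(basename(image_path))) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop_io("file not found: %s", p)
  img <- tryCatch(EBImage::readImage(image_path),
                  error = function(e) stop_io("cannot decode '%s': %s",
                                              image_path, conditionMessage(e)))
  msk <- tryCatch(EBImage::readImage(mask_path),
                  error = function(e) stop_io("cannot decode '%s': %s",
                                              mask_path, conditionMessage(e)))
  ia <- ebimage_to_array(img)
  ma <- ebimage_to_array(msk)
  if (is.matrix(ia)) ia <- array(rep(ia, 3), c(dim(ia), 3))
  ia[ia < 0] <- 0; ia[ia > 1] <- 1
  lum <- if (is.matrix(ma)) ma else (ma[, , 1] + ma[, , 2] + ma[, , 3]) / 3
  sample_pair(wound_image(ia, source_path = image_path),
              binary_mask((lum > 0.5) + 0), id = id)
}

#' Write an image or mask to disk
#'
#' Masks are always written as 8-bit single-channel PNG with foreground
#' 255, so a save/load round trip reproduces the mask exactly.
#'
#' @param x a [wound_image] or [binary_mask].
#' @param path output file (`.png` or `.jpg`).
#' @export
save_image <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  px <- if (inherits(x, "wound_image")) x$pixels
  else if (inherits(x, c("binary_mask", "probability_mask"))) x$pixels
  else x
  EBImage::writeImage(array_to_ebimage(px), path)
  invisible(path)
}

#' @rdname save_image
#' @export
save_mask <- save_image

#' Resize a pair to the model resolution
#'
#' The photograph is interpolated bilinearly; the mask uses nearest
#' neighbor and is re-binarized, so it stays strictly 0/1. A pair already
#' at the target side is returned unchanged.
#'
#' @param pair a [sample_pair].
#' @param side target side in pixels (default 256).
#' @return The resized [sample_pair].
#' @export
resize_to_model <- function(pair, side = 256) {
  stopifnot(inherits(pair, "sample_pair"))
  side <- check_count(side, "side", lower = 8)
  if (pair$image$height == side && pair$image$width == side) return(pair)
  img <- resize_image(pair$image, side)
  mm <- EBImage::resize(array_to_ebimage(pair$mask$pixels), w = side, h = side,
                        filter = "none")
  mask <- binary_mask((ebimage_to_array(mm) > 0.5) + 0)
  sample_pair(img, mask, id = pair$id)
}

resize_image <- function(image, side) {
  im <- EBImage::resize(array_to_ebimage(image$pixels), w = side, h = side,
                        filter = "bilinear")
  px <- ebimage_to_array(im)
  px[px < 0] <- 0; px[px > 1] <- 1
  wound_image(px, source_path = image$source_path)
}

#' Threshold a probability mask
#'
#' @param prob a [probability_mask] (or numeric matrix in `[0, 1]`).
#' @param threshold cut point in `(0, 1)`; pixels with probability greater
#'   than or equal to it become wound.
#' @return A [binary_mask].
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop_validation("`threshold` must lie strictly inside (0, 1)")
  p <- if (inherits(prob, "probability_mask")) prob$pixels else prob
  binary_mask((p >= threshold) + 0)
}

#' Paired augmentation policy
#'
#' Each augmented variant of an image applies exactly one transform, drawn
#' without replacement from the enabled techniques: multiplicative
#' brightness, saturation scaling, right-angle rotation, horizontal flip,
#' vertical flip. Geometric transforms are applied identically to image
#' and mask; photometric ones touch the image only. With the default
#' `variants_per_image = 3`, a dataset of n pairs grows to 4n.
#'
#' @param variants_per_image augmented copies per original.
#' @param brightness_range,saturation_range multiplicative factor
#'   intervals; `NULL` disables the technique.
#' @param rotation_angles rotation angles in degrees (multiples of 90);
#'   empty disables rotation.
#' @param allow_hflip,allow_vflip enable the flips.
#' @param seed RNG seed making the augmentation deterministic.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(variants_per_image = 3,
                                brightness_range = c(0.8, 1.2),
                                saturation_range = c(0.8, 1.2),
                                rotation_angles = c(90, 180, 270),
                                allow_hflip = TRUE, allow_vflip = TRUE,
                                seed = 1) {
  variants_per_image <- check_count(variants_per_image, "variants_per_image")
  for (nm in c("brightness_range", "saturation_range")) {
    rg <- get(nm)
    if (!is.null(rg) && (length(rg) != 2L || any(rg <= 0) || rg[2] < rg[1]))
      stop_validation("`%s` must be a positive interval", nm)
  }
  if (length(rotation_angles) && any(rotation_angles %% 90 != 0))
    stop_validation("rotation angles must be multiples of 90 degrees")
  enabled <- c(
    if (!is.null(brightness_range)) "brightness",
    if (!is.null(saturation_range)) "saturation",
    if (length(rotation_angles)) "rotation",
    if (isTRUE(allow_hflip)) "hflip",
    if (isTRUE(allow_vflip)) "vflip")
  if (variants_per_image > length(enabled))
    stop_validation("variants_per_image (%d) exceeds the %d enabled techniques",
                    variants_per_image, length(enabled))
  structure(list(variants_per_image = variants_per_image,
                 brightness_range = brightness_range,
                 saturation_range = saturation_range,
                 rotation_angles = rotation_angles,
                 allow_hflip = isTRUE(allow_hflip),
                 allow_vflip = isTRUE(allow_vflip),
                 enabled = enabled,
                 seed = check_count(seed, "seed")),
            class = "augmentation_policy")
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rotate_matrix <- function(m, angle) {
  k <- (angle / 90) %% 4
  while (k > 0) { m <- rot90_ccw(m); k <- k - 1 }
  m
}

apply_channelwise <- function(px, f) {
  chans <- lapply(1:3, function(ch) f(px[, , ch]))
  array(unlist(chans), c(dim(chans[[1]]), 3))
}

#' Apply a recorded augmentation transform to a pair
#'
#' Used internally by [augment_dataset()] and exposed so a recorded
#' transform can be replayed (for instance to check that a variant's mask
#' equals the transformed original mask).
#'
#' @param pair a [sample_pair].
#' @param transform a list with `kind` (one of `brightness`, `saturation`,
#'   `rotation`, `hflip`, `vflip`) and `param` (factor or angle, where
#'   applicable).
#' @return The transformed [sample_pair].
#' @export
apply_transform <- function(pair, transform) {
  px <- pair$image$pixels
  mk <- pair$mask$pixels
  kind <- transform$kind
  param <- transform$param
  if (kind == "brightness") {
    px <- pmin(pmax(px * param, 0), 1)
  } else if (kind == "saturation") {
    gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    for (ch in 1:3) px[, , ch] <- gray + param * (px[, , ch] - gray)
    px <- pmin(pmax(px, 0), 1)
  } else if (kind == "rotation") {
    px <- apply_channelwise(px, function(m) rotate_matrix(m, param))
    mk <- rotate_matrix(mk, param)
  } else if (kind == "hflip") {
    px <- px[, dim(px)[2]:1, , drop = FALSE]
    mk <- mk[, ncol(mk):1, drop = FALSE]
  } else if (kind == "vflip") {
    px <- px[dim(px)[1]:1, , , drop = FALSE]
    mk <- mk[nrow(mk):1, , drop = FALSE]
  } else stop_validation("unknown transform kind '%s'", kind)
  out <- sample_pair(wound_image(px), binary_mask(mk),
                     id = paste0(pair$id, "_", kind))
  out$transform <- transform
  out
}

#' Augment a dataset of image/mask pairs
#'
#' Every original is retained and followed by `variants_per_image`
#' augmented copies, each applying one technique drawn (without
#' replacement, seeded) from the policy. The applied transform is recorded
#' in each variant's `transform` field.
#'
#' @param pairs non-empty list of [sample_pair] objects.
#' @param policy an [augmentation_policy()].
#' @return A list of `length(pairs) * (1 + variants_per_image)` pairs.
#' @export
augment_dataset <- function(pairs, policy = augmentation_policy()) {
  if (!length(pairs)) stop_validation("empty input list")
  stopifnot(inherits(policy, "augmentation_policy"))
  with_seed(policy$seed, {
    out <- vector("list", length(pairs) * (1L + policy$variants_per_image))
    k <- 0L
    for (p in pairs) {
      out[[k <- k + 1L]] <- p
      if (policy$variants_per_image == 0L) next
      kinds <- sample(policy$enabled, policy$variants_per_image)
      for (kind in kinds) {
        param <- switch(kind,
          brightness = runif(1, policy$brightness_range[1], policy$brightness_range[2]),
          saturation = runif(1, policy$saturation_range[1], policy$saturation_range[2]),
          rotation = if (length(policy$rotation_angles) == 1L)
            policy$rotation_angles else sample(policy$rotation_angles, 1),
          NULL)
        out[[k <- k + 1L]] <- apply_transform(p, list(kind = kind, param = param))
      }
    }
    out
  })
}

#' Write a dataset in the images/ + masks/ layout
#'
#' @param pairs list of [sample_pair] objects (for instance from
#'   [generate_dataset()]); a `truth` attribute, when present, is written
#'   as `truth.tsv`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    save_image(p$image, file.path(dir, "images", paste0(p$id, ".png")))
    save_mask(p$mask, file.path(dir, "masks", paste0(p$id, ".png")))
  }
  truth <- attr(pairs, "truth")
  if (!is.null(truth))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset from an images/ + masks/ directory or a manifest
#'
#' A directory must contain `images/` and `masks/` with matching file
#' names; alternatively a manifest file with one
#' `image_path<TAB>mask_path` per line is accepted.
#'
#' @param path dataset directory or manifest file.
#' @return A list of [sample_pair] objects.
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) {
    imgs <- sort(list.files(file.path(path, "images"), full.names = TRUE))
    if (!length(imgs)) stop_io("no images under %s/images", path)
    masks <- file.path(path, "masks", basename(imgs))
    missing <- !file.exists(masks)
    if (any(missing))
      stop_io("missing mask(s) for: %s",
              paste(basename(imgs)[missing], collapse = ", "))
    Map(load_pair, imgs, masks, USE.NAMES = FALSE)
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    lapply(parts, function(pp) {
      if (length(pp) != 2L) stop_io("manifest lines must be image<TAB>mask")
      load_pair(pp[1], pp[2])
    })
  } else stop_io("dataset path not found: %s", path)
}
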