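#' Wound image
#'
#' A wound photograph held as an `H x W x 3` numeric array with channel
#' values in `[0, 1]`, row-major with the origin at the top-left corner.
#' This is the conditioning input to the segmentation network.
#'
#' @param pixels numeric `H x W x 3` array in `[0, 1]`.
#' @param source_path optional path the image was read from.
#' @return An object of class `wound_image` with fields `pixels`, `height`,
#'   `width` and `source_path`.
#' @export
wound_image <- function(pixels, source_path = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("a wound image needs an H x W x 3 pixel array, got dims [%s]",
                    paste(dim(pixels), collapse = ", "))
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    stop_validation("image too small: %d x %d (need at least 8 x 8)", d[1], d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_validation("image channel values must lie in [0, 1]")
  structure(list(pixels = pixels, height = d[1], width = d[2],
                 source_path = source_path),
            class = "wound_image")
}

#' Binary segmentation mask
#'
#' A per-pixel wound (1) / background (0) labeling, stored as a numeric
#' `H x W` matrix holding exactly 0s and 1s.
#'
#' @param pixels numeric matrix with values in `{0, 1}`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels))
    stop_validation("a binary mask must be a matrix")
  if (anyNA(pixels) || !all(pixels == 0 | pixels == 1))
    stop_validation("mask values must be exactly 0 or 1")
  structure(list(pixels = pixels + 0, height = nrow(pixels), width = ncol(pixels)),
            class = "binary_mask")
}

#' Probability mask
#'
#' The generator's soft segmentation output: an `H x W` matrix of wound
#' probabilities in `[0, 1]`.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @return An object of class `probability_mask`.
#' @export
probability_mask <- function(pixels) {
  if (!is.matrix(pixels))
    stop_validation("a probability mask must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_validation("probability values must lie in [0, 1]")
  structure(list(pixels = pixels + 0, height = nrow(pixels), width = ncol(pixels)),
            class = "probability_mask")
}

#' Paired image and ground-truth mask
#'
#' One training/evaluation sample: a wound photograph with its binary
#' target mask; both must share the same spatial dimensions.
#'
#' @param image a [wound_image].
#' @param mask a [binary_mask].
#' @param id identifier text.
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(image, mask, id = "") {
  if (!inherits(image, "wound_image")) stop_validation("`image` must be a wound_image")
  if (!inherits(mask, "binary_mask")) stop_validation("`mask` must be a binary_mask")
  if (image$height != mask$height || image$width != mask$width)
    stop_validation("image (%d x %d) and mask (%d x %d) dimensions differ",
                    image$height, image$width, mask$height, mask$width)
  structure(list(image = image, mask = mask, id = id), class = "sample_pair")
}

#' @export
print.wound_image <- function(x, ...) {
  cat(sprintf("<wound_image %d x %d>\n", x$height, x$width))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              x$height, x$width, sum(x$pixels)))
  invisible(x)
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf("<sample_pair '%s' %d x %d, %d wound px>\n",
              x$id, x$image$height, x$image$width, sum(x$mask$pixels)))
  invisible(x)
}
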