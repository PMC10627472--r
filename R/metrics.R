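#' Pixel confusion counts between a predicted and a target mask
#'
#' @param pred,target [binary_mask] objects (or 0/1 matrices) of equal
#'   shape.
#' @return A `confusion_counts` list with fields `tp`, `fp`, `fn`, `tn`
#'   summing to the pixel count.
#' @export
confusion <- function(pred, target) {
  p <- if (inherits(pred, "binary_mask")) pred$pixels else pred
  t <- if (inherits(target, "binary_mask")) target$pixels else target
  if (!identical(dim(p), dim(t)))
    stop_validation("mask shapes differ: [%s] vs [%s]",
                    paste(dim(p), collapse = ", "),
                    paste(dim(t), collapse = ", "))
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop_validation("confusion counts need strictly binary masks")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- length(p) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

# Degenerate-denominator convention: if both masks are empty the comparison
# is a perfect (if trivial) agreement and every metric is 1; otherwise any
# 0/0 ratio is taken as 0. Both cases are flagged with a warning.
metric_ratio <- function(num, den, c) {
  if (c$tp + c$fp + c$fn == 0) {
    warning("both masks empty: metrics reported as 1 by convention",
            call. = FALSE)
    return(1)
  }
  if (den == 0) {
    warning("degenerate denominator: metric reported as 0 by convention",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Overlap metrics from confusion counts
#'
#' Precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, Dice
#' `2TP / (2TP + FP + FN)` and IoU `TP / (TP + FP + FN)`. Note the exact
#' identity `dice = 2 * iou / (1 + iou)`, hence `iou <= dice` always.
#'
#' @param c a `confusion_counts` from [confusion()].
#' @return A fraction in `[0, 1]`.
#' @export
precision <- function(c) metric_ratio(c$tp, c$tp + c$fp, c)

#' @rdname precision
#' @export
recall <- function(c) metric_ratio(c$tp, c$tp + c$fn, c)

#' @rdname precision
#' @export
dice <- function(c) metric_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, c)

#' @rdname precision
#' @export
iou <- function(c) metric_ratio(c$tp, c$tp + c$fp + c$fn, c)

#' Per-image and mean overlap metrics for two sets of masks
#'
#' @param preds,truths equal-length lists of [binary_mask] objects.
#' @param ids optional identifiers (default index).
#' @return A data frame with one row per image plus a final `mean` row.
#' @export
evaluate_masks <- function(preds, truths, ids = NULL) {
  if (length(preds) != length(truths))
    stop_validation("prediction and truth counts differ (%d vs %d)",
                    length(preds), length(truths))
  if (is.null(ids)) ids <- as.character(seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cm <- confusion(preds[[i]], truths[[i]])
    data.frame(id = ids[i], precision = precision(cm), recall = recall(cm),
               dice = dice(cm), iou = iou(cm))
  })
  per <- do.call(rbind, rows)
  rbind(per, data.frame(id = "mean",
                        precision = mean(per$precision),
                        recall = mean(per$recall),
                        dice = mean(per$dice),
                        iou = mean(per$iou)))
}
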