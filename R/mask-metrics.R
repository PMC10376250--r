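#' @title Pixel-level segmentation accuracy metrics
#' @description
#' Binary segmentation of a raster is a pixel-wise two-class problem: every
#' pixel is either foreground (e.g. polyp) or background. Comparing a
#' predicted mask `A` against a ground-truth mask `B` yields the four
#' confusion counts TP/FP/TN/FN, from which the five standard accuracy
#' metrics are computed:
#' \deqn{IoU = TP/(TP+FP+FN)}
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{RE  = TP/(TP+FN), \quad PR = TP/(TP+FP)}
#' \deqn{F1  = 2 \cdot PR \cdot RE / (PR + RE)}
#' All five lie in [0, 1]; IoU and F1 are linked by the algebraic identity
#' IoU = F1 / (2 - F1).
#' @name mask_metrics
NULL

# -- validation helpers -------------------------------------------------------

#' Coerce an object to a binary mask
#'
#' A binary mask is a logical matrix with at least one cell; numeric input is
#' accepted when every entry is exactly 0 or 1.
#'
#' @param x logical or 0/1 numeric matrix.
#' @return A logical matrix.
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) stop("mask must be a matrix", call. = FALSE)
  if (length(x) < 1L) stop("mask must contain at least one pixel", call. = FALSE)
  if (is.logical(x)) {
    if (anyNA(x)) stop("mask contains NA pixels", call. = FALSE)
    return(x)
  }
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1)))
      stop("numeric mask must contain only 0 and 1", call. = FALSE)
    return(array(x == 1, dim = dim(x)))
  }
  stop("mask must be logical or 0/1 numeric", call. = FALSE)
}

#' Validate a probability map
#'
#' @param x numeric matrix with all values in [0, 1].
#' @return The validated numeric matrix.
#' @export
as_probability_map <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("probability map must be a numeric matrix", call. = FALSE)
  if (length(x) < 1L) stop("probability map must contain at least one pixel", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  x
}

# -- operations ---------------------------------------------------------------

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is greater than or equal to the
#' threshold, so ties at exactly the threshold count as positive.
#'
#' @param map numeric matrix of per-pixel foreground probabilities in [0, 1].
#' @param threshold scalar in the open interval (0, 1); default 0.5.
#' @return A logical matrix of the same shape.
#' @examples
#' binarize(matrix(c(0.49, 0.5, 0.51, 0), 2, 2))
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  map <- as_probability_map(map)
  array(map >= threshold, dim = dim(map))
}

#' Confusion counts constructor
#'
#' @param tp,fp,tn,fn non-negative integer pixel counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  counts <- as.integer(round(counts))
  structure(list(tp = counts[1], fp = counts[2], tn = counts[3], fn = counts[4]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Pixel confusion counts between predicted and ground-truth masks
#'
#' @param pred predicted binary mask.
#' @param truth ground-truth binary mask of identical shape.
#' @return A `confusion_counts` object; the four counts sum to the number of
#'   pixels.
#' @examples
#' p <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
#' confusion(p, p)
#' @export
confusion <- function(pred, truth) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(pred), ncol(pred), nrow(truth), ncol(truth)), call. = FALSE)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- length(pred) - tp - fp - fn
  confusion_counts(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Segmentation accuracy metrics from confusion counts
#'
#' Degenerate denominators follow the perfect-agreement convention: when both
#' masks contain no positives (tp = fp = fn = 0) the overlap metrics iou, re,
#' pr and f1 are defined as 1; a zero denominator in the presence of any
#' disagreement yields 0.
#'
#' @param counts a `confusion_counts` object (or a list with tp/fp/tn/fn).
#' @return Named numeric vector with elements `iou`, `acc`, `re`, `pr`, `f1`,
#'   each in [0, 1].
#' @examples
#' metrics_from_counts(confusion_counts(tp = 2, fp = 1, tn = 13, fn = 0))
#' @export
metrics_from_counts <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(tp = counts$tp, fp = counts$fp,
                               tn = counts$tn, fn = counts$fn)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("all four confusion counts are zero", call. = FALSE)

  ratio <- function(num, den) {
    if (den > 0) return(num / den)
    # den == 0: both-empty convention scores 1, disagreement scores 0
    if (tp + fp + fn == 0) 1 else 0
  }
  pr <- ratio(tp, tp + fp)
  re <- ratio(tp, tp + fn)
  c(iou = ratio(tp, tp + fp + fn),
    acc = (tp + tn) / n,
    re  = re,
    pr  = pr,
    f1  = if (pr + re > 0) 2 * pr * re / (pr + re) else ratio(0, 0))
}

#' Aggregate metrics over a set of mask pairs
#'
#' Each pair is `list(pred, truth)` where `pred` is either a binary mask or a
#' probability map (thresholded at `threshold`). Micro pooling sums confusion
#' counts over all pairs before computing the metrics, making the result
#' robust to varying image sizes; `per_image_mean` averages the per-image
#' metric vectors with equal weight per image.
#'
#' @param pairs non-empty list of `list(pred, truth)` pairs.
#' @param threshold binarization threshold applied to probability maps.
#' @param pooling `"micro"` (default) or `"per_image_mean"`.
#' @return Named numeric metric vector as in [metrics_from_counts()].
#' @export
evaluate_mask_set <- function(pairs, threshold = 0.5,
                              pooling = c("micro", "per_image_mean")) {
  pooling <- match.arg(pooling)
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("pairs must be a non-empty list", call. = FALSE)
  counts <- lapply(pairs, function(pair) {
    pred <- pair[[1]]
    if (is.numeric(pred) && !all(pred %in% c(0, 1)))
      pred <- binarize(pred, threshold)
    confusion(pred, pair[[2]])
  })
  if (pooling == "micro") {
    pooled <- confusion_counts(tp = sum(vapply(counts, `[[`, 0, "tp")),
                               fp = sum(vapply(counts, `[[`, 0, "fp")),
                               tn = sum(vapply(counts, `[[`, 0, "tn")),
                               fn = sum(vapply(counts, `[[`, 0, "fn")))
    metrics_from_counts(pooled)
  } else {
    per_image <- vapply(counts, metrics_from_counts, numeric(5))
    rowMeans(per_image)
  }
}
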