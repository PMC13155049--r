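# Agreement between saliency maps and ground-truth annotation masks.

as_mask <- function(x, what = "mask") {
  if (is.matrix(x)) return(x > 0)
  stop_validation(what, " must be a matrix")
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop_validation("mask shapes differ: ", paste(dim(a), collapse = "x"),
                    " vs ", paste(dim(b), collapse = "x"))
  }
}

#' Binarize a saliency map at a fraction of its maximum
#'
#' A pixel is kept iff `map >= frac * max(map)` (inclusive comparison, so the
#' maximal pixel always survives for any `frac < 1`). An all-zero map yields
#' an all-false mask. The default fraction is the conventional 30%-of-max
#' threshold used for Grad-CAM evaluation.
#'
#' @param map an HxW nonnegative saliency map.
#' @param frac threshold fraction in (0, 1).
#' @return HxW logical matrix.
#' @export
binarize_saliency <- function(map, frac = 0.30) {
  if (!is.numeric(frac) || frac <= 0 || frac >= 1) {
    stop_config("frac must lie strictly between 0 and 1")
  }
  m <- max(map)
  if (m <= 0) return(matrix(FALSE, nrow(map), ncol(map)))
  unclass(map) >= frac * m
}

#' Intersection over union of two binary masks
#'
#' `|A and B| / |A or B|`; defined as 1 when both masks are empty (perfect
#' agreement by convention).
#'
#' @param a,b HxW logical/0-1 matrices of the same shape.
#' @return a number in \[0, 1\].
#' @export
iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Dice coefficient of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @inheritParams iou
#' @return a number in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}

#' Pointing game: does the saliency peak hit the annotation?
#'
#' Returns 1 iff the most activated pixel lies inside the ground-truth region.
#' Ties are broken by the first maximum in row-major order (top row scanned
#' left to right first). Images with an empty ground truth have no defined
#' target and raise an error -- benign images are excluded from pointing-game
#' averages.
#'
#' @param map an HxW saliency map.
#' @param gt HxW ground-truth mask, nonempty.
#' @return 0 or 1.
#' @export
pointing_game <- function(map, gt) {
  gt <- as_mask(gt, "gt")
  check_same_shape(map, gt)
  if (!any(gt)) {
    stop_validation("pointing game is undefined for an empty ground-truth mask")
  }
  m <- unclass(map)
  ind <- which(m == max(m), arr.ind = TRUE)
  first <- ind[order(ind[, 1], ind[, 2])[1], ]
  as.integer(gt[first[1], first[2]])
}

#' Fraction of saliency mass inside the annotation
#'
#' `sum(map over gt pixels) / sum(map over all pixels)`: the normalized
#' overlap of the saliency with the annotated region. 0 when `gt` is empty;
#' an all-zero map has no mass to distribute and raises an error.
#'
#' @inheritParams pointing_game
#' @param gt HxW ground-truth mask (may be empty).
#' @return a number in \[0, 1\].
#' @export
normalized_overlap <- function(map, gt) {
  gt <- as_mask(gt, "gt")
  check_same_shape(map, gt)
  tot <- sum(map)
  if (tot <= 0) stop_validation("normalized overlap is undefined for an all-zero map")
  sum(unclass(map)[gt]) / tot
}

#' Class-stratified mean and dispersion of a metric batch
#'
#' @param values numeric metric values, one per image.
#' @param class optional parallel class labels for stratification.
#' @return data frame with columns class, n, mean, sd (sd is 0 for a single
#'   item). For 0/1 metrics such as the pointing game the mean is the
#'   proportion of hits.
#' @export
aggregate_metrics <- function(values, class = NULL) {
  if (length(values) == 0) stop_config("empty metric batch")
  if (is.null(class)) class <- rep("all", length(values))
  if (length(class) != length(values)) {
    stop_validation("class labels must parallel the values")
  }
  out <- do.call(rbind, lapply(split(seq_along(values), class), function(ix) {
    v <- values[ix]
    data.frame(class = class[ix[1]], n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
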