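# The five reported metrics between a predicted and a ground-truth binary
# volume: precision, recall, Dice, average Hausdorff distance (AVD) and
# 95th-percentile Hausdorff distance (95HD). Distances are computed over
# all foreground voxels (not extracted surfaces), in voxel units by
# default; pass the voxel spacing for physical millimetres.

#' Voxel-wise confusion counts
#'
#' @param pred,gt [binary_label_volume()]s of equal shape.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_counts <- function(pred, gt) {
  stopifnot(inherits(pred, "binary_label_volume"),
            inherits(gt, "binary_label_volume"))
  if (!identical(dim(pred$data), dim(gt$data)))
    stop("pred and gt must share shape", call. = FALSE)
  p <- pred$data == 1; g <- gt$data == 1
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' `dsc = 2TP / (2TP + FP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. Empty-denominator convention (vacuous
#' truth): a metric whose denominator is empty is 1 — an empty prediction
#' has perfect precision, an empty ground truth is perfectly recalled;
#' the Dice coefficient is 1 only when both foregrounds are empty.
#'
#' @param counts a `confusion_counts` object.
#' @return Named list with `dsc`, `precision`, `recall`.
#' @export
overlap_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    dsc <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
    precision <- if (TP + FP == 0) 1 else TP / (TP + FP)
    recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
    list(dsc = dsc, precision = precision, recall = recall)
  })
}

foreground_coords <- function(x) {
  arr <- if (is.list(x)) x$data else x
  which(arr == 1, arr.ind = TRUE)
}

#' Directed average nearest-neighbour distance
#'
#' `(1/|A|) * sum_{a in A} min_{b in B} ||a - b||`, Euclidean, with axes
#' scaled by `spacing` (default voxel units).
#'
#' @param A,B voxel coordinate matrices (rows are `x, y, z`) or
#'   [binary_label_volume()]s whose foregrounds define the sets.
#' @param spacing length-3 axis scaling.
#' @return Scalar; `Inf` if `B` is empty (flagged upstream), 0 if `A` is
#'   empty.
#' @export
directed_avg_distance <- function(A, B, spacing = c(1, 1, 1)) {
  A <- if (is.matrix(A)) A else foreground_coords(A)
  B <- if (is.matrix(B)) B else foreground_coords(B)
  if (nrow(A) == 0L) return(0)
  if (nrow(B) == 0L) return(Inf)
  mean(cpp_nnmin(A, B, spacing))
}

directed_nn_distances <- function(A, B, spacing) {
  as.numeric(cpp_nnmin(A, B, spacing))
}

#' Average Hausdorff distance
#'
#' The maximum of the two directed mean nearest-neighbour distances
#' between the foreground voxel sets of prediction and ground truth.
#' If both foregrounds are empty the distance is 0 (with a warning); if
#' exactly one is empty it is `Inf` (with a warning).
#'
#' @param pred,gt [binary_label_volume()]s of equal shape.
#' @param spacing length-3 axis scaling (default voxel units).
#' @return Scalar distance.
#' @export
avd <- function(pred, gt, spacing = c(1, 1, 1)) {
  hausdorff_directed(pred, gt, spacing, mean)
}

#' 95th-percentile Hausdorff distance
#'
#' The maximum over both directions of the 95th percentile (linear
#' interpolation between order statistics) of the nearest-neighbour
#' distance distribution. Degenerate foregrounds follow the [avd()]
#' conventions.
#'
#' @inheritParams avd
#' @return Scalar distance.
#' @export
hd95 <- function(pred, gt, spacing = c(1, 1, 1)) {
  hausdorff_directed(pred, gt, spacing,
                     function(d) quantile(d, 0.95, names = FALSE, type = 7))
}

hausdorff_directed <- function(pred, gt, spacing, reducer) {
  if (!identical(dim(pred$data), dim(gt$data)))
    stop("pred and gt must share shape", call. = FALSE)
  P <- foreground_coords(pred); G <- foreground_coords(gt)
  if (nrow(P) == 0L && nrow(G) == 0L) {
    warning("both foregrounds empty; distance defined as 0")
    return(0)
  }
  if (nrow(P) == 0L || nrow(G) == 0L) {
    warning("one foreground empty; distance is Inf")
    return(Inf)
  }
  max(reducer(directed_nn_distances(P, G, spacing)),
      reducer(directed_nn_distances(G, P, spacing)))
}

#' Full five-metric evaluation report
#'
#' @inheritParams avd
#' @return An object of class `evaluation_report`: `dsc`, `precision`,
#'   `recall` (ratios), `avd`, `hd95` (distances) and `counts`.
#' @export
evaluate_segmentation <- function(pred, gt, spacing = c(1, 1, 1)) {
  counts <- confusion_counts(pred, gt)
  om <- overlap_metrics(counts)
  P <- foreground_coords(pred); G <- foreground_coords(gt)
  if (nrow(P) == 0L && nrow(G) == 0L) {
    a <- 0; h <- 0
  } else if (nrow(P) == 0L || nrow(G) == 0L) {
    a <- Inf; h <- Inf
  } else {
    dPG <- directed_nn_distances(P, G, spacing)
    dGP <- directed_nn_distances(G, P, spacing)
    a <- max(mean(dPG), mean(dGP))
    h <- max(quantile(dPG, 0.95, names = FALSE),
             quantile(dGP, 0.95, names = FALSE))
  }
  structure(list(dsc = om$dsc, precision = om$precision,
                 recall = om$recall, avd = a, hd95 = h, counts = counts),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> DSC %.4f | precision %.4f | recall %.4f | AVD %.4f | 95HD %.4f\n",
    x$dsc, x$precision, x$recall, x$avd, x$hd95))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(dsc = x$dsc, precision = x$precision, recall = x$recall,
             avd = x$avd, hd95 = x$hd95, TP = x$counts$TP,
             FP = x$counts$FP, FN = x$counts$FN, TN = x$counts$TN)
}
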