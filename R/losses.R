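# Soft-Dice loss, its analytic gradient, and deep-supervision weighting.

#' Soft Dice similarity coefficient
#'
#' For a probability patch `p` and binary ground truth `g`, returns
#' `(2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)`. The training
#' loss is `1 -` this value. On a binary `p` the unstabilised form reduces
#' to the counting definition `2TP / (2TP + FP + FN)`.
#'
#' The stabiliser `eps` (default 1) makes the empty-prediction /
#' empty-truth case a perfect score of 1; patches with no vessel voxel are
#' common because half of all training patches are not vessel-centric.
#' Set `eps = 0` for the raw ratio.
#'
#' @param p numeric array/vector of probabilities in `[0, 1]`.
#' @param g numeric array/vector over \{0, 1\}, same shape as `p`.
#' @param eps non-negative stabiliser added to numerator and denominator.
#' @return A scalar in `[0, 1]`.
#' @export
soft_dsc <- function(p, g, eps = 1) {
  check_pair(p, g)
  (2 * sum(p * g) + eps) / (sum(p * p) + sum(g * g) + eps)
}

#' Analytic gradient of the soft Dice coefficient
#'
#' The derivative of [soft_dsc()] with respect to `p` at voxel `j`:
#' `2 * (g_j * (D + eps) - 2 * p_j * (S + eps/2) ... ` — concretely
#' `(2 * g_j * (D + eps) - 2 * p_j * (2 * S + eps)) / (D + eps)^2` with
#' `S = sum(p * g)` and `D = sum(p^2) + sum(g^2)`. At `eps = 0` this is
#' exactly `2 * (g_j * D - 2 * p_j * S) / D^2`. Training itself
#' backpropagates through the same expression; this closed form doubles as
#' an independent oracle for gradient checking.
#'
#' @inheritParams soft_dsc
#' @param j optional voxel index (linear, 1-based); if `NULL` the full
#'   gradient array is returned.
#' @return A scalar (for `j`) or an array shaped like `p`.
#' @export
soft_dsc_gradient <- function(p, g, j = NULL, eps = 1) {
  check_pair(p, g)
  S <- sum(p * g)
  D <- sum(p * p) + sum(g * g) + eps
  grad <- (2 * g * D - 2 * p * (2 * S + eps)) / D^2
  if (is.null(j)) grad else grad[j]
}

check_pair <- function(p, g) {
  if (!identical(dim(p) %||% length(p), dim(g) %||% length(g)))
    stop("p and g must share shape", call. = FALSE)
  invisible(NULL)
}

#' Deep-supervision loss weights
#'
#' The final head carries weight 0.5; the remaining 0.5 is split equally
#' across the intermediate heads. For a single head the weight is 1. The
#' returned vector lists intermediate heads first, final head last, and
#' always sums to 1.
#'
#' @param n_heads number of output heads (>= 1).
#' @return Numeric weight vector of length `n_heads`.
#' @export
ds_weights <- function(n_heads) {
  if (n_heads < 1) stop("n_heads must be >= 1", call. = FALSE)
  if (n_heads == 1) return(1)
  c(rep(0.5 / (n_heads - 1), n_heads - 1), 0.5)
}

#' Weighted multi-head Dice loss
#'
#' `sum_i w_i * (1 - soft_dsc(head_i, g))`: the Dice loss of every output
#' head, weighted by [ds_weights()] (or any weights summing to 1) and
#' summed into the scalar training loss.
#'
#' @param head_outputs list of probability patches, final head last.
#' @param g binary ground-truth patch.
#' @param w weight vector, same length as `head_outputs`.
#' @param eps stabiliser passed to [soft_dsc()].
#' @return Scalar loss in `[0, 1]`.
#' @export
composite_loss <- function(head_outputs, g, w = ds_weights(length(head_outputs)),
                           eps = 1) {
  if (length(head_outputs) != length(w))
    stop("head_outputs and w must have equal length", call. = FALSE)
  sum(vapply(seq_along(w), function(i)
    w[i] * (1 - soft_dsc(head_outputs[[i]], g, eps = eps)), 0))
}
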