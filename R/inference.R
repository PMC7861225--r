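# Whole-volume reconstruction from patch-wise predictions, thresholding,
# and fold ensembling. Inference consumes raw volumes: no mask, no
# normalisation step.

#' Tile a volume with patch centres
#'
#' Generates centres so that every voxel is covered by at least one patch
#' (patch placement follows the [extract_patch()] convention). The last
#' tile per axis is clamped to the boundary; an axis shorter than the
#' patch gets a single tile, covered through padding.
#'
#' @param shape length-3 volume shape.
#' @param patch length-3 patch shape.
#' @param stride length-3 step between tile origins (default `patch`:
#'   non-overlapping tiling). Components larger than the patch would break
#'   coverage and are capped at the patch size.
#' @return A data.frame of 1-based centre coordinates `x, y, z`.
#' @export
tile_centers <- function(shape, patch, stride = patch) {
  shape <- as.integer(shape); patch <- as.integer(patch)
  stride <- as.integer(stride)
  if (any(stride < 1L)) stop("stride components must be >= 1", call. = FALSE)
  stride <- pmin(stride, patch)
  axis_centers <- function(D, s, t) {
    if (D >= s) {
      starts <- unique(c(seq(1L, D - s + 1L, by = t), D - s + 1L))
      starts + s %/% 2L
    } else {
      min(s %/% 2L + 1L, D)  # single clamped tile; padding covers the rest
    }
  }
  g <- expand.grid(x = axis_centers(shape[1], patch[1], stride[1]),
                   y = axis_centers(shape[2], patch[2], stride[2]),
                   z = axis_centers(shape[3], patch[3], stride[3]))
  g[order(g$z, g$y, g$x), , drop = FALSE]
}

#' Reconstruct a whole-volume probability map
#'
#' Extracts primary (and, for context variants, context) patches at every
#' tile centre with zero padding, runs the network, and writes the final
#' head's probabilities back into the volume; voxels covered by several
#' overlapping tiles receive the mean of the contributing predictions.
#' Raw volumes are accepted as-is — no mask and no normalisation.
#'
#' @param net an `angioseg_network`, or (for testing) a function
#'   `f(primary, context)` returning a probability array of primary shape.
#' @param v a [volume()].
#' @param stride tiling stride, default the patch size (non-overlapping).
#' @param primary_patch,context_patch patch shapes; taken from the network
#'   configuration when `net` is an `angioseg_network`.
#' @param batch_size tiles evaluated per forward pass.
#' @return A [probability_volume()] of the input shape.
#' @export
predict_volume <- function(net, v, stride = NULL, primary_patch = NULL,
                           context_patch = NULL, batch_size = 4L) {
  stopifnot(inherits(v, "volume"))
  is_net <- inherits(net, "angioseg_network")
  if (is_net) {
    primary_patch <- net$config$primary_patch
    context_patch <- if (has_context(net$config)) net$config$context_patch
  }
  if (is.null(primary_patch))
    stop("primary_patch required for a function predictor", call. = FALSE)
  primary_patch <- as.integer(primary_patch)
  if (is.null(stride)) stride <- primary_patch
  d <- dim(v$data)
  centers <- tile_centers(d, primary_patch, stride)
  acc <- array(0, d); cnt <- array(0, d)
  use_ctx <- !is.null(context_patch)

  run_tiles <- function(rows) {
    prim <- lapply(rows, function(i)
      extract_patch(v, as.integer(centers[i, ]), primary_patch, 0))
    ctx <- if (use_ctx) lapply(rows, function(i)
      extract_patch(v, as.integer(centers[i, ]), context_patch, 0))
    if (is_net) {
      bp <- patches_to_batch(prim)
      bc <- if (use_ctx) patches_to_batch(ctx)
      fw <- net_forward(net, bp$X, bp$dims, bp$B,
                        if (use_ctx) bc$X, if (use_ctx) bc$dims,
                        train = FALSE, final_only = TRUE)
      final <- fw$heads[[length(fw$heads)]]
      nvox <- prod(primary_patch)
      lapply(seq_along(rows), function(b)
        array(final[((b - 1L) * nvox + 1L):(b * nvox), 1L],
              dim = primary_patch))
    } else {
      lapply(seq_along(rows), function(b)
        net(prim[[b]], if (use_ctx) ctx[[b]]))
    }
  }

  idx_chunks <- split(seq_len(nrow(centers)),
                      ceiling(seq_len(nrow(centers)) / batch_size))
  for (rows in idx_chunks) {
    preds <- run_tiles(rows)
    for (b in seq_along(rows)) {
      ctr <- as.integer(centers[rows[b], ])
      start <- ctr - primary_patch %/% 2L
      lo_src <- pmax(start, 1L)
      hi_src <- pmin(start + primary_patch - 1L, d)
      lo_dst <- lo_src - start + 1L; hi_dst <- hi_src - start + 1L
      sx <- lo_src[1]:hi_src[1]; sy <- lo_src[2]:hi_src[2]
      sz <- lo_src[3]:hi_src[3]
      acc[sx, sy, sz] <- acc[sx, sy, sz] +
        preds[[b]][lo_dst[1]:hi_dst[1], lo_dst[2]:hi_dst[2],
                   lo_dst[3]:hi_dst[3]]
      cnt[sx, sy, sz] <- cnt[sx, sy, sz] + 1
    }
  }
  probability_volume(acc / cnt, v$voxel_size)
}

#' Threshold a probability volume
#'
#' A voxel becomes foreground iff its probability strictly exceeds the
#' threshold; ties at exactly the threshold map to background.
#'
#' @param p a [probability_volume()].
#' @param threshold scalar in `[0, 1]` (default 0.5).
#' @return A [binary_label_volume()].
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(inherits(p, "probability_volume"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  binary_label_volume(array(as.numeric(p$data > threshold), dim(p$data)),
                      p$voxel_size)
}

#' Ensemble prediction across fold models
#'
#' Averages the per-network probability volumes voxel-wise, then
#' thresholds at 0.5. All networks must share variant and configuration.
#'
#' @param nets non-empty list of `angioseg_network` objects.
#' @param v a [volume()].
#' @param threshold binarisation threshold.
#' @param ... passed on to [predict_volume()].
#' @return A [binary_label_volume()].
#' @export
ensemble_predict <- function(nets, v, threshold = 0.5, ...) {
  if (length(nets) == 0L) stop("need at least one network", call. = FALSE)
  if (all(vapply(nets, inherits, TRUE, "angioseg_network"))) {
    variants <- vapply(nets, function(n) n$config$variant, "")
    if (length(unique(variants)) != 1L)
      stop("all networks must share the same variant", call. = FALSE)
  }
  probs <- lapply(nets, function(n) predict_volume(n, v, ...)$data)
  mean_p <- Reduce(`+`, probs) / length(probs)
  binarize(probability_volume(mean_p, v$voxel_size), threshold)
}
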