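# Heuristic masking, vessel-centric patch sampling, patch extraction and
# stratified cross-validation splits.

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Heuristic air-exclusion mask
#'
#' Smooths the volume with a sliding box-mean filter (stride 1, replicate
#' padding at the edges) and thresholds the result: a voxel belongs to the
#' mask iff its windowed mean intensity strictly exceeds `threshold`. With
#' the defaults (16-voxel window, threshold 10) this separates the bright
#' head region from surrounding near-zero air, keeping a thick border shell
#' around the skull. The mask is a training-time patch pre-selection device
#' only; inference never uses it.
#'
#' @param v a [volume()].
#' @param window box edge length in voxels; an even window covers offsets
#'   `-window/2 .. window/2 - 1`, matching the patch-centre convention.
#' @param threshold intensity threshold; comparison is strict (`> threshold`).
#' @return A [binary_label_volume()] of the same shape.
#' @export
compute_heuristic_mask <- function(v, window = 16, threshold = 10) {
  stopifnot(inherits(v, "volume"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (window > min(dim(v$data)))
    stop("window (", window, ") larger than a volume dimension",
         call. = FALSE)
  sm <- cpp_boxmean(as.numeric(v$data), dim(v$data), window)
  binary_label_volume(array(as.numeric(sm > threshold), dim(v$data)),
                      v$voxel_size)
}

#' Sample vessel-centric patch centres
#'
#' Draws `n` voxel locations inside the mask, guaranteeing that exactly
#' `ceiling(n * vessel_fraction)` of them sit on vessel-labelled voxels
#' ("vessel-centric": the centre voxel itself carries label 1). The
#' remaining centres are drawn from non-vessel mask voxels (or from the
#' whole mask if it contains no background). Sampling is without
#' replacement while the admissible pool is large enough, with replacement
#' otherwise.
#'
#' @param labels a [binary_label_volume()] of vessel ground truth.
#' @param mask a [binary_label_volume()] from [compute_heuristic_mask()].
#' @param n number of centres (default 2000 per volume).
#' @param vessel_fraction fraction of vessel-centric centres in `[0, 1]`
#'   (default 0.5).
#' @param seed integer seed; the draw is reproducible under it.
#' @return A data.frame with columns `x, y, z` (1-based voxel indices) and
#'   `is_vessel_centric`.
#' @export
sample_patch_centers <- function(labels, mask, n = 2000,
                                 vessel_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(labels, "binary_label_volume"),
            inherits(mask, "binary_label_volume"))
  if (!identical(dim(labels$data), dim(mask$data)))
    stop("labels and mask must share shape", call. = FALSE)
  if (vessel_fraction < 0 || vessel_fraction > 1)
    stop("vessel_fraction must lie in [0, 1]", call. = FALSE)
  in_mask <- mask$data == 1
  if (!any(in_mask)) stop("empty mask: no voxel to sample", call. = FALSE)
  vessel_pool <- which(in_mask & labels$data == 1)
  bg_pool <- which(in_mask & labels$data == 0)
  if (length(bg_pool) == 0L) bg_pool <- which(in_mask)
  n_vessel <- ceiling(n * vessel_fraction)
  if (n_vessel > 0L && length(vessel_pool) == 0L)
    stop("no vessel voxel inside mask but vessel_fraction > 0",
         call. = FALSE)
  draw <- function(pool, k) {
    if (k == 0L) return(integer(0))
    sample(pool, k, replace = length(pool) < k)
  }
  idx <- with_seed(seed, {
    c(draw(vessel_pool, n_vessel), draw(bg_pool, n - n_vessel))
  })
  co <- arrayInd(idx, dim(labels$data))
  data.frame(x = co[, 1], y = co[, 2], z = co[, 3],
             is_vessel_centric = labels$data[idx] == 1)
}

#' Extract a patch around a centre voxel
#'
#' Returns a patch of exactly the requested size. For even sizes the centre
#' voxel occupies offset `size/2` (0-based; the upper-middle position), i.e.
#' the patch spans indices `center - floor(size/2)` to
#' `center + size - 1 - floor(size/2)`. Positions outside the volume are
#' filled with `pad_value`.
#'
#' @param v a [volume()], [binary_label_volume()] or plain 3-D array.
#' @param center length-3 integer, 1-based voxel index; must lie inside.
#' @param size length-3 integer patch shape.
#' @param pad_value fill value for out-of-bounds positions.
#' @return A 3-D array of shape `size`.
#' @export
extract_patch <- function(v, center, size, pad_value = 0) {
  arr <- if (is.list(v)) v$data else v
  d <- dim(arr)
  center <- as.integer(center); size <- as.integer(size)
  if (any(center < 1L) || any(center > d))
    stop("center outside volume", call. = FALSE)
  start <- center - size %/% 2L            # 1-based start index
  out <- array(pad_value, dim = size)
  lo_src <- pmax(start, 1L); hi_src <- pmin(start + size - 1L, d)
  if (all(lo_src <= hi_src)) {
    lo_dst <- lo_src - start + 1L; hi_dst <- hi_src - start + 1L
    out[lo_dst[1]:hi_dst[1], lo_dst[2]:hi_dst[2], lo_dst[3]:hi_dst[3]] <-
      arr[lo_src[1]:hi_src[1], lo_src[2]:hi_src[2], lo_src[3]:hi_src[3]]
  }
  out
}

#' Build two-scale patch samples
#'
#' For each centre, extracts the primary intensity patch, the co-centred
#' context patch at twice the edge length (when `context` is non-NULL), and
#' the label patch of primary size.
#'
#' @param v a [volume()].
#' @param labels the paired [binary_label_volume()].
#' @param centers data.frame from [sample_patch_centers()].
#' @param primary primary (and label) patch shape.
#' @param context context patch shape (`2 *` primary), or `NULL` for
#'   single-scale variants.
#' @return A list of patch samples, each with elements `center`, `primary`,
#'   `context` (possibly `NULL`) and `label`.
#' @export
sample_patches <- function(v, labels, centers, primary = c(64, 64, 8),
                           context = NULL) {
  if (!is.null(context) && !identical(as.integer(context),
                                      as.integer(2L * primary)))
    stop("context patch must be exactly 2x the primary patch per axis",
         call. = FALSE)
  lapply(seq_len(nrow(centers)), function(i) {
    ctr <- as.integer(centers[i, c("x", "y", "z")])
    list(center = ctr,
         primary = extract_patch(v, ctr, primary, 0),
         context = if (!is.null(context))
           extract_patch(v, ctr, context, 0),
         label = extract_patch(labels, ctr, primary, 0))
  })
}

#' Stratified k-fold cross-validation splits
#'
#' Builds `folds` train/validation/test partitions stratified by source
#' cohort. Per source, each fold's test set receives `floor(count/folds)`
#' ids (the remainder under the floor stays in training across all folds).
#' From each fold's non-test pool, `floor(val_fraction * pool)` ids are
#' moved to validation, stratified per source by the same floor rule, any
#' shortfall filled from the largest source. With cohort sizes
#' `c(74, 9, 181)` and the defaults this yields 170/29/65
#' train/validation/test ids in every fold.
#'
#' @param cohort_sizes named integer vector, ids per source cohort.
#' @param folds number of folds (default 4).
#' @param val_fraction validation fraction of the non-test pool, in
#'   `[0, 1)` (default 0.15).
#' @param seed integer seed.
#' @return A list of length `folds`; each element has `fold`, `train`,
#'   `val`, `test` (disjoint character id vectors) and `source_of` (named
#'   character vector mapping id to source).
#' @export
make_cv_splits <- function(cohort_sizes, folds = 4, val_fraction = 0.15,
                           seed = 1L) {
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1)
    stop("val_fraction must lie in [0, 1)", call. = FALSE)
  cohort_sizes <- unlist(cohort_sizes)
  sources <- names(cohort_sizes)
  if (is.null(sources)) sources <- names(cohort_sizes) <-
      paste0("S", seq_along(cohort_sizes))
  ids <- lapply(sources, function(s)
    sprintf("%s-%03d", s, seq_len(cohort_sizes[[s]])))
  names(ids) <- sources
  source_of <- unlist(lapply(sources, function(s)
    stats::setNames(rep(s, length(ids[[s]])), ids[[s]])))

  with_seed(seed, {
    perm <- lapply(ids, sample)          # per-source random order
    test_of_fold <- lapply(seq_len(folds), function(f) {
      unlist(lapply(sources, function(s) {
        k <- length(perm[[s]]) %/% folds
        if (k == 0L) return(character(0))
        perm[[s]][((f - 1L) * k + 1L):(f * k)]
      }))
    })
    lapply(seq_len(folds), function(f) {
      test <- test_of_fold[[f]]
      pool <- lapply(sources, function(s) setdiff(ids[[s]], test))
      names(pool) <- sources
      pool_n <- vapply(pool, length, 0L)
      target <- floor(val_fraction * sum(pool_n))
      quota <- floor(val_fraction * pool_n)
      short <- target - sum(quota)
      if (short > 0L) {
        big <- sources[which.max(pool_n)]
        quota[big] <- quota[big] + short
      }
      val <- unlist(lapply(sources, function(s) {
        if (quota[s] == 0L) return(character(0))
        sample(pool[[s]], min(quota[s], length(pool[[s]])))
      }))
      train <- setdiff(unlist(pool), val)
      list(fold = f, train = train, val = val %||% character(0),
           test = test, source_of = source_of)
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cross-validation splits as JSON
#'
#' @param splits result of [make_cv_splits()].
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_cv_splits <- function(splits, path) {
  out <- lapply(splits, function(s)
    list(fold = s$fold, train = s$train, val = s$val, test = s$test))
  names(out) <- paste0("fold", vapply(splits, `[[`, 0L, "fold"))
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Write sampled patch centres as CSV
#'
#' @param centers data.frame from [sample_patch_centers()].
#' @param path destination CSV file.
#' @param id volume identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(centers, path, id = "volume") {
  write.csv(cbind(id = id, centers), path, row.names = FALSE)
  invisible(path)
}
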