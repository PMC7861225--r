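#' @useDynLib angioseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile sd
#' @importFrom utils write.csv read.csv
NULL

#' 3-D intensity volume
#'
#' A `volume` is a 3-D scalar grid with a physical voxel spacing. Axis order
#' is `(x, y, z)` with `z` the slice direction; indices are 1-based and
#' voxel-centred. Intensities are kept exactly as supplied: the framework
#' operates on raw angiography images and performs no rescaling or
#' normalisation at I/O time (input normalisation is learned by the
#' networks' initial batch-normalisation layer).
#'
#' @param data 3-D numeric array, all values finite.
#' @param voxel_size positive length-3 numeric, voxel edge lengths in mm.
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- check_grid(data, voxel_size)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "volume")
}

#' Binary label volume
#'
#' Ground-truth vessel labels, masks and thresholded predictions: a 3-D grid
#' over exactly \{0, 1\}, aligned voxel-for-voxel with its paired [volume()].
#'
#' @inheritParams volume
#' @return An object of class `binary_label_volume`.
#' @export
binary_label_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- check_grid(data, voxel_size)
  if (!all(data == 0 | data == 1))
    stop("binary label volume must contain only 0 and 1", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "binary_label_volume")
}

#' Probability volume
#'
#' Voxel-wise vessel probabilities in `[0, 1]`, as produced by whole-volume
#' reconstruction from patch-wise network predictions.
#'
#' @inheritParams volume
#' @return An object of class `probability_volume`.
#' @export
probability_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- check_grid(data, voxel_size)
  if (min(data) < 0 || max(data) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "probability_volume")
}

check_grid <- function(data, voxel_size) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("grid must be a 3-D array, got dimensionality ",
         length(dim(data)), call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths", call. = FALSE)
  if (!all(is.finite(data)))
    stop("intensities must be finite (no NaN/Inf)", call. = FALSE)
  storage.mode(data) <- "double"
  data
}

#' Read a volume from a NIfTI-1 file
#'
#' Grid and voxel spacing are returned exactly as stored; no intensity
#' rescaling is applied. 4-D or multi-channel images are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param type one of `"volume"`, `"label"`, `"probability"`; selects the
#'   returned class (labels are validated to be binary).
#' @return A [volume()], [binary_label_volume()] or [probability_volume()].
#' @export
read_volume <- function(path, type = c("volume", "label", "probability")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L)
    stop("expected a single-channel 3-D image, got ", length(d),
         " dimensions", call. = FALSE)
  d <- c(d, rep(1L, 3L - length(d)))    # NIfTI drops trailing singletons
  vs <- c(RNifti::pixdim(img), rep(1, 3))[1:3]
  arr <- array(as.numeric(img), dim = d)
  switch(type,
         volume = volume(arr, vs),
         label = binary_label_volume(arr, vs),
         probability = probability_volume(arr, vs))
}

#' Write a volume to a NIfTI-1 file
#'
#' Labels are stored as unsigned 8-bit integers (bit-exact round trip),
#' probabilities as 32-bit floats, intensity volumes as 64-bit floats.
#'
#' @param v a [volume()], [binary_label_volume()] or [probability_volume()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    stop("directory not writable: ", dirname(path), call. = FALSE)
  dt <- if (inherits(v, "binary_label_volume")) "uint8"
        else if (inherits(v, "probability_volume")) "float"
        else "double"
  img <- RNifti::asNifti(v$data, internal = FALSE)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm, intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_label_volume <- function(x, ...) {
  cat("<binary_label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground (",
      signif(100 * mean(x$data), 3), "%)\n", sep = "")
  invisible(x)
}

#' @export
print.probability_volume <- function(x, ...) {
  cat("<probability_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, mean p = ", signif(mean(x$data), 4), "\n", sep = "")
  invisible(x)
}
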