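#' Construct a 3-D image volume
#'
#' The universal image container of the pipeline: a 3-D scalar grid with a
#' voxel size and a voxel-to-world affine. Voxel indices are 0-based with the
#' voxel center at the integer index; world coordinates are RAS+ millimetres.
#'
#' @param data 3-D numeric array.
#' @param voxel_size Length-3 positive numeric, voxel edge lengths in mm.
#'   Ignored (derived from `affine`) when `affine` is supplied.
#' @param affine 4x4 voxel-to-world matrix. Default: axis-aligned scaling by
#'   `voxel_size` with the grid's world center at the origin.
#' @return An object of class `volume` with fields `data`, `voxel_size`,
#'   `affine`.
#' @export
volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1 per axis")
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0))
      stop("'voxel_size' must be 3 positive numbers")
    affine <- diag(c(voxel_size, 1))
    # center the grid on the world origin
    affine[1:3, 4] <- -voxel_size * (dim(data) - 1) / 2
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4x4")
    if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(voxel_size <= 0)) stop("degenerate affine: zero voxel dimension")
  }
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Test whether an object is a volume
#' @param x Object.
#' @return Logical.
#' @export
is_volume <- function(x) inherits(x, "volume")

#' World coordinate of the grid center of a volume
#' @param vol A [volume].
#' @return Length-3 numeric, mm.
#' @export
center_world <- function(vol) {
  stopifnot(is_volume(vol))
  c(vol$affine %*% c((dim(vol$data) - 1) / 2, 1))[1:3]
}

#' Check that two volumes share a grid
#'
#' Same dimensions and affines equal within `tol` per element.
#' @param a,b Volumes.
#' @param tol Per-element affine tolerance.
#' @return Logical.
#' @export
same_grid <- function(a, b, tol = 1e-5) {
  is_volume(a) && is_volume(b) &&
    identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Replace the data array of a volume, keeping its grid
#' @param vol A [volume].
#' @param data Array with the same dimensions.
#' @return A [volume].
#' @export
with_data <- function(vol, data) {
  stopifnot(is_volume(vol), identical(dim(data), dim(vol$data)))
  vol$data <- data
  vol
}

#' World coordinate arrays for every voxel of a volume
#'
#' @param vol A [volume].
#' @return List of three arrays `x`, `y`, `z` (mm), each shaped like the grid.
#' @export
world_grid <- function(vol) {
  d <- dim(vol$data)
  i <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d)
  j <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), dim = d)
  k <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d)
  A <- vol$affine
  list(x = A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
       y = A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
       z = A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume]; data in float64, affine from the sform/qform.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop("not a 3-D image: ", path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  arr <- array(as.numeric(img), dim = d)
  vol <- volume(arr, affine = matrix(as.numeric(aff), 4, 4))
  vol
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as float32; the affine is written to both sform and qform.
#' @param vol A [volume].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  if (!dir.exists(dirname(path))) stop("directory not found: ", dirname(path))
  d <- dim(vol$data)
  aff <- vol$affine
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, d, 1L, 1L, 1L, 1L),
    pixdim = c(1, vol$voxel_size, 0, 0, 0, 0),
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
    sform_code = 2L, qform_code = 0L,
    datatype = 16L, bitpix = 32L))
  img <- RNifti::asNifti(vol$data, reference = hdr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}
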