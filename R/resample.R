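#' @useDynLib lfdwi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_grid <- function(x) {
  if (is_volume(x)) return(list(dim = dim(x$data), affine = x$affine))
  stopifnot(is.list(x), !is.null(x$dim), !is.null(x$affine))
  list(dim = as.integer(x$dim), affine = as.matrix(x$affine))
}

#' Resample a volume through a 12-parameter transform
#'
#' Pull-back resampling: for each voxel of the target grid its world
#' coordinate is mapped through the transform and the input volume is
#' interpolated there. Voxels falling outside the input field of view are 0.
#'
#' @param vol Input [volume].
#' @param params `affine12` transform (world-to-world), or `NULL` for
#'   identity (pure grid change).
#' @param target A [volume] or `list(dim, affine)` grid specification to
#'   resample onto. Default: the input grid.
#' @param method `"trilinear"` (images) or `"nearest"` (masks/labels).
#' @param center Rotation/scale center (world mm). Default: the world center
#'   of the target grid.
#' @return A [volume] on the target grid.
#' @export
apply_transform <- function(vol, params = NULL, target = vol,
                            method = c("trilinear", "nearest"),
                            center = NULL) {
  stopifnot(is_volume(vol))
  method <- match.arg(method)
  g <- as_grid(target)
  if (is.null(center)) {
    center <- c(g$affine %*% c((g$dim - 1) / 2, 1))[1:3]
  }
  Tm <- if (is.null(params)) diag(4) else affine_matrix(params, center)
  if (abs(det(Tm)) < 1e-12) stop("singular transform")
  if (any(!is.finite(vol$data))) stop("non-finite values in input volume")
  M <- solve(vol$affine) %*% Tm %*% g$affine
  out <- resample_affine_cpp(as.numeric(vol$data), as.integer(dim(vol$data)),
                             M, as.integer(g$dim),
                             if (method == "nearest") 1L else 0L)
  volume(array(out, dim = g$dim), affine = g$affine)
}

#' Resample a volume to isotropic resolution
#'
#' Produces a grid of cubic voxels covering the same world-space extent
#' (half-open voxel-edge extents preserved within one voxel).
#'
#' @param vol Input [volume].
#' @param resolution Target voxel edge, mm (default 1).
#' @param method `"trilinear"` for images, `"nearest"` for masks.
#' @return A [volume] with `voxel_size = rep(resolution, 3)`.
#' @export
to_isotropic <- function(vol, resolution = 1,
                         method = c("trilinear", "nearest")) {
  stopifnot(is_volume(vol), resolution > 0)
  method <- match.arg(method)
  d <- dim(vol$data)
  s <- resolution / vol$voxel_size
  new_dim <- as.integer(ceiling(d * vol$voxel_size / resolution - 1e-9))
  dir_old <- vol$affine[1:3, 1:3]
  dir_new <- dir_old %*% diag(s)
  # first new voxel center = old grid edge corner + half a new voxel
  corner <- vol$affine %*% c(-0.5, -0.5, -0.5, 1)
  origin <- corner[1:3] + dir_new %*% c(0.5, 0.5, 0.5)
  aff <- diag(4)
  aff[1:3, 1:3] <- dir_new
  aff[1:3, 4] <- origin
  apply_transform(vol, NULL, target = list(dim = new_dim, affine = aff),
                  method = method)
}

#' Downsample a volume by integer block averaging
#'
#' Used by the multi-resolution registration pyramid. Trailing voxels that do
#' not fill a complete block are cropped.
#'
#' @param vol Input [volume].
#' @param factor Positive integer block edge.
#' @return A [volume] with `voxel_size * factor`.
#' @export
block_mean <- function(vol, factor) {
  stopifnot(is_volume(vol), factor >= 1, factor == round(factor))
  f <- as.integer(factor)
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% f
  stopifnot(all(nd >= 1L))
  x <- vol$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
                drop = FALSE]
  dim(x) <- c(f, nd[1], f, nd[2], f, nd[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(f^3, prod(nd))
  m <- colMeans(x)
  dir_new <- vol$affine[1:3, 1:3] * f
  corner <- vol$affine %*% c(-0.5, -0.5, -0.5, 1)
  aff <- diag(4)
  aff[1:3, 1:3] <- dir_new
  aff[1:3, 4] <- corner[1:3] + dir_new %*% c(0.5, 0.5, 0.5)
  volume(array(m, dim = nd), affine = aff)
}
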