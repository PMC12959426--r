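#' 12-parameter affine transform
#'
#' Parameterisation used for series-to-series coregistration: 3 translations
#' (mm), 3 rotations (degrees, about x, y, z), 3 scales and 3 shears,
#' composed as T·R·S·Sh about a center point in world space. The identity is
#' `(0,0,0, 0,0,0, 1,1,1, 0,0,0)`.
#'
#' @param translation,rotation Length-3 numerics (mm, degrees).
#' @param scale Length-3 positive numerics.
#' @param shear Length-3 numerics (xy, xz, yz).
#' @return Named numeric vector of class `affine12`.
#' @export
affine_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                          scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  stopifnot(length(translation) == 3L, length(rotation) == 3L,
            length(scale) == 3L, length(shear) == 3L)
  if (any(scale <= 0)) stop("scales must be > 0")
  p <- c(translation, rotation, scale, shear)
  names(p) <- c("tx", "ty", "tz", "rx", "ry", "rz",
                "sx", "sy", "sz", "kxy", "kxz", "kyz")
  class(p) <- "affine12"
  p
}

#' Identity affine parameters
#' @return An `affine12` identity transform.
#' @export
affine_identity <- function() affine_params()

rot3 <- function(deg, axis) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' World-space matrix of a 12-parameter transform
#'
#' Builds the 4x4 world-to-world mapping `T·Rz·Ry·Rx·S·Sh` applied about
#' `center` (points are shifted so `center` is the rotation/scaling origin).
#'
#' @param params `affine12` vector (or plain length-12 numeric in the same
#'   order).
#' @param center Length-3 world point (mm) the rotation/scale act about.
#' @return 4x4 matrix.
#' @export
affine_matrix <- function(params, center = c(0, 0, 0)) {
  p <- as.numeric(params)
  stopifnot(length(p) == 12L)
  if (any(p[7:9] <= 0)) stop("scales must be > 0")
  R <- rot3(p[6], "z") %*% rot3(p[5], "y") %*% rot3(p[4], "x")
  S <- diag(p[7:9])
  Sh <- diag(3)
  Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  L <- R %*% S %*% Sh
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- p[1:3] + center - L %*% center
  M
}

#' Draw a random small rigid transform
#'
#' Translations uniform in `[-max_translation, max_translation]` mm per axis,
#' rotations uniform in `[-max_rotation, max_rotation]` degrees per axis;
#' unit scales, zero shears. Uses the current RNG state.
#'
#' @param max_translation,max_rotation Magnitude bounds (mm, degrees).
#' @return An `affine12` transform.
#' @export
random_rigid <- function(max_translation = 3, max_rotation = 3) {
  affine_params(translation = stats::runif(3, -max_translation, max_translation),
                rotation = stats::runif(3, -max_rotation, max_rotation))
}
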