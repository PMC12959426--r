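#' Phantom specification
#'
#' Describes the synthetic diffusion-tensor head used throughout: an
#' ellipsoidal brain with a cortical shell, deep gray nuclei, ventricular
#' CSF, a white-matter interior carrying two anisotropic tract systems (a
#' pair of corticospinal-like vertical tubes and a corona-radiata-like fan
#' whose fiber orientation varies smoothly), plus zero or more isotropic
#' restricted-diffusion lesions.
#'
#' Tissue defaults are literature-typical adult-brain values: white-matter
#' tract eigenvalues (1.4, 0.4, 0.4)e-3 mm^2/s; non-tract white matter
#' isotropic at the same mean diffusivity 0.7333e-3; cortical and deep gray
#' isotropic 0.8e-3; CSF 3.0e-3; lesions isotropic 0.4e-3 (restricted).
#' S0 values give T2-like contrast (CSF bright, gray > white).
#'
#' @param grid_dim Grid dimensions (default `c(96, 96, 48)`).
#' @param voxel_size Voxel size in mm (default anisotropic `c(1.5, 1.5, 3)`).
#' @param tissues Named list of per-class parameters, each
#'   `list(s0 = , lambda = )` with eigenvalues in mm^2/s. Classes:
#'   `wm`, `tract`, `cortical_gm`, `deep_gm`, `csf`, `lesion`.
#' @param lesions List of lesions, each `list(center = c(x, y, z) mm,
#'   radius = mm)` (or `volume_ml` instead of `radius`, converted to the
#'   equivalent-sphere radius).
#' @param fan_azimuth_deg Azimuth (degrees) of the fanning bundle's tilt
#'   plane; varied across subjects to disperse tract orientations.
#' @param qc_scores Synthetic segmentation quality-control scores,
#'   `c(supratentorial, infratentorial)` in \[0, 1\].
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(96L, 96L, 48L),
                         voxel_size = c(1.5, 1.5, 3),
                         tissues = default_tissues(),
                         lesions = list(),
                         fan_azimuth_deg = 0,
                         qc_scores = c(supratentorial = 0.9,
                                       infratentorial = 0.5)) {
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 8),
            length(voxel_size) == 3L, all(voxel_size > 0),
            all(qc_scores >= 0), all(qc_scores <= 1))
  lesions <- lapply(lesions, function(l) {
    if (is.null(l$radius)) {
      stopifnot(!is.null(l$volume_ml), l$volume_ml > 0)
      l$radius <- (3 * l$volume_ml * 1000 / (4 * pi))^(1 / 3)
    }
    stopifnot(length(l$center) == 3L, l$radius > 0)
    l
  })
  wm_md <- mean(tissues$wm$lambda)
  for (l in lesions) {
    lesion_adc <- mean(tissues$lesion$lambda)
    if (lesion_adc >= wm_md)
      stop("lesion ADC must be below surrounding-tissue mean diffusivity")
  }
  structure(list(grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
                 tissues = tissues, lesions = lesions,
                 fan_azimuth_deg = fan_azimuth_deg, qc_scores = qc_scores),
            class = "phantom_spec")
}

#' Default tissue parameter table
#' @return Named list of `list(s0, lambda)` per tissue class.
#' @export
default_tissues <- function() {
  list(
    wm          = list(s0 = 800,  lambda = rep(2.2e-3 / 3, 3)),
    tract       = list(s0 = 800,  lambda = c(1.4e-3, 0.4e-3, 0.4e-3)),
    cortical_gm = list(s0 = 1000, lambda = rep(0.8e-3, 3)),
    deep_gm     = list(s0 = 950,  lambda = rep(0.8e-3, 3)),
    csf         = list(s0 = 1600, lambda = rep(3.0e-3, 3)),
    lesion      = list(s0 = 1000, lambda = rep(0.4e-3, 3))
  )
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' @param lambda Numeric length-3 vector, or an n x 3 matrix of eigenvalue
#'   triples (mm^2/s).
#' @return Fractional anisotropy in \[0, 1\] (0 for a zero tensor).
#' @export
fractional_anisotropy <- function(lambda) {
  l <- if (is.matrix(lambda)) lambda else matrix(lambda, nrow = 1)
  stopifnot(ncol(l) == 3L)
  m <- rowMeans(l)
  num <- rowSums((l - m)^2)
  den <- rowSums(l^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  if (!is.matrix(lambda)) fa[[1]] else fa
}

# fiber orientation -> tensor components for axially symmetric tensor
# D = l_perp I + (l_par - l_perp) u u^T, vectorised over voxel subsets
axisym_tensor <- function(ux, uy, uz, l_par, l_perp) {
  d <- l_par - l_perp
  list(xx = l_perp + d * ux * ux, yy = l_perp + d * uy * uy,
       zz = l_perp + d * uz * uz, xy = d * ux * uy,
       xz = d * ux * uz, yz = d * uy * uz)
}

#' Build the phantom ground truth
#'
#' Rasterises the geometry of a [phantom_spec] into tissue masks, a
#' per-voxel diffusion tensor field, an S0 (proton-density-weighted) map, a
#' lesion mask and the true mean-diffusivity map.
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom_truth` with elements `tensor` (list of
#'   arrays `xx, yy, zz, xy, xz, yz`, mm^2/s), `s0` ([volume]), `masks`
#'   (volumes `whole_brain`, `white_matter`, `cortical_gm`, `deep_gm`,
#'   `csf`), `lesion` ([volume]), `md` (true mean diffusivity, [volume]),
#'   `qc_scores`, and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim
  template <- volume(array(0, dim = d), voxel_size = spec$voxel_size)
  w <- world_grid(template)
  X <- w$x; Y <- w$y; Z <- w$z

  semi <- c(62, 70, 58)
  r <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
  brain <- r <= 1

  ellipsoid <- function(c0, rad) {
    ((X - c0[1]) / rad[1])^2 + ((Y - c0[2]) / rad[2])^2 +
      ((Z - c0[3]) / rad[3])^2 <= 1
  }
  csf <- brain & (ellipsoid(c(14, -8, 8), c(6, 16, 8)) |
                  ellipsoid(c(-14, -8, 8), c(6, 16, 8)))
  cortical <- brain & !csf & (r > 0.88)
  deep <- brain & !csf & !cortical &
    (ellipsoid(c(10, 8, -2), c(7, 9, 7)) |
     ellipsoid(c(-10, 8, -2), c(7, 9, 7)) |
     ellipsoid(c(24, 2, 0), c(5, 10, 7)) |
     ellipsoid(c(-24, 2, 0), c(5, 10, 7)))
  wm <- brain & !csf & !cortical & !deep

  # corticospinal-like vertical tubes (fibers along z)
  tube <- wm & (((X - 26)^2 + (Y + 18)^2 <= 8^2) |
                ((X + 26)^2 + (Y + 18)^2 <= 8^2)) & abs(Z) <= 48
  # fanning bundle: fibers tilt away from z with |X|, in the plane set by
  # the azimuth -- orientation varies smoothly across the bundle
  fan <- wm & !tube & Z >= 8 & Z <= 34 & abs(Y) <= 32 & abs(X) <= 48
  tract <- tube | fan

  ts <- spec$tissues
  cls_iso <- array(0, dim = d)   # isotropic diffusivity per voxel
  s0 <- array(0, dim = d)
  cls_iso[wm] <- mean(ts$wm$lambda)
  cls_iso[cortical] <- mean(ts$cortical_gm$lambda)
  cls_iso[deep] <- mean(ts$deep_gm$lambda)
  cls_iso[csf] <- mean(ts$csf$lambda)
  s0[wm] <- ts$wm$s0
  s0[cortical] <- ts$cortical_gm$s0
  s0[deep] <- ts$deep_gm$s0
  s0[csf] <- ts$csf$s0

  tensor <- list(xx = cls_iso, yy = cls_iso, zz = array(0, dim = d),
                 xy = array(0, dim = d), xz = array(0, dim = d),
                 yz = array(0, dim = d))
  tensor$zz <- cls_iso  # copy, not alias

  # stamp anisotropic tract tensors
  l_par <- ts$tract$lambda[1]; l_perp <- ts$tract$lambda[2]
  phi <- spec$fan_azimuth_deg * pi / 180
  ux <- array(0, dim = d); uy <- array(0, dim = d); uz <- array(0, dim = d)
  uz[tube] <- 1
  theta <- (X[fan] / 48) * (60 * pi / 180)
  ux[fan] <- sin(theta) * cos(phi)
  uy[fan] <- sin(theta) * sin(phi)
  uz[fan] <- cos(theta)
  tt <- axisym_tensor(ux[tract], uy[tract], uz[tract], l_par, l_perp)
  for (nm in names(tensor)) tensor[[nm]][tract] <- tt[[nm]]
  s0[tract] <- ts$tract$s0

  # stamp lesions (isotropic restricted diffusion)
  lesion_mask <- array(FALSE, dim = d)
  vox2world_inv <- solve(template$affine)
  for (l in spec$lesions) {
    ctr_vox <- (vox2world_inv %*% c(l$center, 1))[1:3]
    idx <- round(ctr_vox) + 1
    if (any(idx < 1) || any(idx > d) || !brain[idx[1], idx[2], idx[3]])
      stop("lesion center outside brain")
    inside <- brain & ((X - l$center[1])^2 + (Y - l$center[2])^2 +
                       (Z - l$center[3])^2 <= l$radius^2)
    if (any(inside & lesion_mask)) stop("overlapping lesions")
    lesion_mask <- lesion_mask | inside
  }
  if (any(lesion_mask)) {
    lv <- mean(ts$lesion$lambda)
    for (nm in c("xx", "yy", "zz")) tensor[[nm]][lesion_mask] <- lv
    for (nm in c("xy", "xz", "yz")) tensor[[nm]][lesion_mask] <- 0
    s0[lesion_mask] <- ts$lesion$s0
  }

  md <- (tensor$xx + tensor$yy + tensor$zz) / 3
  as_mask <- function(m) with_data(template, array(as.numeric(m), dim = d))
  structure(list(
    tensor = tensor,
    s0 = with_data(template, s0),
    masks = list(whole_brain = as_mask(brain),
                 white_matter = as_mask(wm),
                 cortical_gm = as_mask(cortical),
                 deep_gm = as_mask(deep),
                 csf = as_mask(csf)),
    tract = as_mask(tract),
    lesion = as_mask(lesion_mask),
    md = with_data(template, md),
    qc_scores = spec$qc_scores,
    spec = spec), class = "phantom_truth")
}

#' Directional diffusivity g' D g of a phantom's tensor field
#'
#' @param truth A `phantom_truth`.
#' @param g Unit gradient direction (length 3).
#' @return A [volume] of g' D g values (mm^2/s).
#' @export
tensor_adc <- function(truth, g) {
  stopifnot(inherits(truth, "phantom_truth"), length(g) == 3L)
  if (abs(sqrt(sum(g^2)) - 1) > 1e-8) stop("gradient direction must be unit")
  tn <- truth$tensor
  q <- tn$xx * g[1]^2 + tn$yy * g[2]^2 + tn$zz * g[3]^2 +
    2 * (tn$xy * g[1] * g[2] + tn$xz * g[1] * g[3] + tn$yz * g[2] * g[3])
  with_data(truth$s0, q)
}
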