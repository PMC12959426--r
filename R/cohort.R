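#' Simulate one study subject
#'
#' Builds a subject-specific phantom (fan-bundle orientation and lesion
#' drawn from the subject seed, derived as base seed + index), then
#' simulates both protocols over the same phantom: one single-direction
#' (SD, z) and one multi-direction (MD, x/y/z) series, with per-series
#' rigid motion and Rician noise at the configured SNR. Mimic subjects
#' carry no lesion.
#'
#' @param cfg A `run_config` (see [default_config()]).
#' @param index Positive subject index.
#' @param mimic Simulate a stroke mimic (no lesion)?
#' @return List: `id`, `seed`, `truth` (`phantom_truth`), `sd`/`md`
#'   (`dwi_series`), `true_volume_ml`, `lesion_center`, `mimic`.
#' @export
simulate_subject <- function(cfg, index, mimic = FALSE) {
  stopifnot(inherits(cfg, "run_config"), index >= 1)
  subject_seed <- (cfg$seed + index) %% 2147483647L
  with_seed(subject_seed, {
    fan_az <- stats::runif(1, -90, 90)
    lesions <- list()
    center <- NULL
    vol_ml <- 0
    if (!mimic) {
      rng <- cfg$cohort$lesion_volume_range_ml
      vol_ml <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
      radius <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
      if (stats::runif(1) < cfg$cohort$near_tract_fraction) {
        # adjacent to a corticospinal-like tube, medial side
        side <- sample(c(-1, 1), 1)
        gap <- stats::runif(1, 1, 2.5)
        center <- c(side * (26 - 8 - gap - radius),
                    -18 + stats::runif(1, -3, 3),
                    stats::runif(1, -15, 10))
      } else {
        sites <- rbind(c(35, -30, -5), c(-35, -30, -5), c(30, 28, 0),
                       c(-30, 28, 0), c(0, -42, 5), c(18, -38, -12),
                       c(-18, -38, -12))
        center <- sites[sample.int(nrow(sites), 1), ] +
          stats::runif(3, -3, 3)
      }
      lesions <- list(list(center = center, volume_ml = vol_ml))
    }
    spec <- phantom_spec(grid_dim = cfg$phantom$grid_dim,
                         voxel_size = cfg$phantom$voxel_size,
                         lesions = lesions, fan_azimuth_deg = fan_az)
    truth <- build_phantom(spec)
    snr <- if (is.null(cfg$acquisition$snr))
      preset_snr(cfg$acquisition$preset) else cfg$acquisition$snr
    mk_acq <- function(dirs) acquisition_spec(
      directions = dirs, b = cfg$acquisition$b, snr = snr,
      motion = cfg$acquisition$motion)
    sd_series <- simulate_series(truth, mk_acq("sd"))
    md_series <- simulate_series(truth, mk_acq("md"))
    sigma <- 800 / snr
    noise_seeds <- sample.int(2147483646L, 2)
    sd_series <- add_rician_noise(sd_series, sigma, noise_seeds[1])
    md_series <- add_rician_noise(md_series, sigma, noise_seeds[2])
    list(id = sprintf("sub-%03d", index), seed = subject_seed,
         truth = truth, sd = sd_series, md = md_series,
         true_volume_ml = if (mimic) 0 else mask_volume_ml(truth$lesion),
         lesion_center = center, mimic = mimic)
  })
}

#' Run the image-processing chain for one subject
#'
#' Mirrors the acquisition-to-interpretation order: each direction volume is
#' coregistered to its b=0 (12-parameter affine), maps are computed on the
#' native grid (per-direction ADC for SD; trace DWI and trace ADC for MD),
#' and maps plus masks are interpolated to isotropic resolution (trilinear
#' for images, nearest for masks).
#'
#' @param sub A subject from [simulate_subject()].
#' @param cfg A `run_config`.
#' @param register Run registration (default: only when the configuration
#'   simulates inter-series motion).
#' @return List with `native` (maps on the acquisition grid) and `iso`
#'   (1 mm maps, region masks, parenchyma and lesion masks).
#' @export
process_subject <- function(sub, cfg = as_run_config(),
                            register = !is.null(cfg$acquisition$motion)) {
  adc_max <- cfg$analysis$adc_max
  res <- cfg$analysis$isotropic_mm
  # small expected motions: a reduced iteration budget suffices
  sd_series <- if (register) align_series(sub$sd, max_iter = 60) else sub$sd
  md_series <- if (register) align_series(sub$md, max_iter = 60) else sub$md
  dwi_sd <- sd_series$dwi[[1]]$vol
  adc_sd <- compute_adc(sd_series$b0, dwi_sd, sd_series$b,
                        adc_max = adc_max)
  tr <- compute_trace_maps(md_series, adc_max = adc_max)
  iso_img <- function(v) to_isotropic(v, res, "trilinear")
  iso_msk <- function(v) to_isotropic(v, res, "nearest")
  masks_iso <- lapply(sub$truth$masks, iso_msk)
  parenchyma <- with_data(masks_iso$whole_brain,
                          pmax(masks_iso$whole_brain$data -
                               masks_iso$csf$data, 0))
  list(
    native = list(dwi_sd = dwi_sd, adc_sd = adc_sd,
                  trace_dwi = tr$trace_dwi, trace_adc = tr$trace_adc),
    iso = list(dwi_sd = iso_img(dwi_sd), adc_sd = iso_img(adc_sd),
               trace_dwi = iso_img(tr$trace_dwi),
               trace_adc = iso_img(tr$trace_adc),
               masks = masks_iso, parenchyma = parenchyma,
               lesion = iso_msk(sub$truth$lesion)))
}

#' Separable box smoothing of a volume
#'
#' Running-mean filter with an odd window per axis sized to the requested
#' physical radius; used to pick a reading seed point on noisy maps.
#'
#' @param vol A [volume].
#' @param radius_mm Physical half-width, mm.
#' @return A smoothed [volume].
#' @export
box_smooth <- function(vol, radius_mm = 3) {
  stopifnot(is_volume(vol))
  x <- vol$data
  d <- dim(x)
  for (ax in 1:3) {
    w <- max(0L, as.integer(round(radius_mm / vol$voxel_size[ax])))
    if (w == 0L) next
    k <- 2L * w + 1L
    perm <- c(ax, setdiff(1:3, ax))
    y <- aperm(x, perm)
    dy <- dim(y)
    m <- matrix(y, nrow = dy[1])
    cs <- apply(rbind(0, m), 2, cumsum)
    n <- dy[1]
    lo <- pmax(seq_len(n) - w - 1L, 0L)
    hi <- pmin(seq_len(n) + w, n)
    sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) /
      (hi - lo)
    y <- array(sm, dim = dy)
    x <- aperm(y, order(perm))
  }
  with_data(vol, x)
}

#' Mask-normalised box smoothing
#'
#' Smooths `map * mask` and `mask` separately and returns their ratio
#' inside the mask (original values outside), so values beyond the mask
#' (background, CSF) cannot bleed into the smoothed estimate.
#'
#' @param map A [volume].
#' @param mask Binary [volume] on the same grid.
#' @param radius_mm Box half-width, mm.
#' @return A [volume].
#' @export
masked_smooth <- function(map, mask, radius_mm = 3) {
  stopifnot(same_grid(map, mask))
  m <- mask$data > 0.5
  num <- box_smooth(with_data(map, map$data * m), radius_mm)
  den <- box_smooth(with_data(map, m + 0), radius_mm)
  out <- map$data
  out[m] <- num$data[m] / pmax(den$data[m], 1e-12)
  with_data(map, out)
}

sphere_mask <- function(template, center, radius) {
  A <- template$affine
  d <- dim(template$data)
  if (max(abs(A[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))])) < 1e-9) {
    # axis-aligned grid: separable squared distances
    dx2 <- (A[1, 1] * (seq_len(d[1]) - 1) + A[1, 4] - center[1])^2
    dy2 <- (A[2, 2] * (seq_len(d[2]) - 1) + A[2, 4] - center[2])^2
    dz2 <- (A[3, 3] * (seq_len(d[3]) - 1) + A[3, 4] - center[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  } else {
    w <- world_grid(template)
    inside <- (w$x - center[1])^2 + (w$y - center[2])^2 +
      (w$z - center[3])^2 <= radius^2
  }
  with_data(template, array(as.numeric(inside), dim = d))
}

# any 6-connected component of `mask` with >= min_voxels voxels?
has_component <- function(mask, min_voxels = 3L) {
  remaining <- which(mask)
  while (length(remaining) >= min_voxels) {
    comp <- flood_fill6(mask, remaining[1])
    if (sum(comp) >= min_voxels) return(TRUE)
    mask[comp] <- FALSE
    remaining <- which(mask)
  }
  FALSE
}

#' Read a lesion presence/location call for one subject and sequence
#'
#' Emulates the reading procedure on the interpolated maps: the reading map
#' is the DWI image (bright-lesion polarity; `reading = "adc"` reads the
#' ADC map dark). For lesion subjects the reader is pointed at the true
#' lesion neighbourhood (ground-truth-guided seed sphere) and the seeded
#' threshold segmentation must overlap the truth; for mimics any
#' suprathreshold component of at least 3 voxels anywhere in the
#' parenchyma counts as a (false) detection.
#'
#' @param proc Output of [process_subject()].
#' @param sub The subject from [simulate_subject()].
#' @param sequence `"sd"` or `"md"`.
#' @param k Threshold multiplier (default 3).
#' @param reading `"adc"` (default: ADC map, dark-lesion polarity) or
#'   `"dwi"` (DWI image, bright polarity).
#' @param smooth_mm Box-smoothing half-width applied to the reading map
#'   before thresholding, emulating the reader's visual integration scale
#'   (default 3 mm; 0 disables).
#' @return List: `detected`, `segmented_ml`, `threshold`, `seg`.
#' @export
read_subject <- function(proc, sub, sequence = c("md", "sd"), k = 3,
                         reading = c("adc", "dwi"), smooth_mm = 3) {
  sequence <- match.arg(sequence)
  reading <- match.arg(reading)
  map <- switch(paste(reading, sequence),
                "dwi sd" = proc$iso$dwi_sd, "dwi md" = proc$iso$trace_dwi,
                "adc sd" = proc$iso$adc_sd, "adc md" = proc$iso$trace_adc)
  dark <- reading == "adc"
  brain <- proc$iso$parenchyma
  if (smooth_mm > 0) map <- masked_smooth(map, brain, smooth_mm)
  if (!sub$mimic) {
    radius <- (3 * sub$true_volume_ml * 1000 / (4 * pi))^(1 / 3)
    seed_region <- sphere_mask(map, sub$lesion_center, radius + 4)
    seg <- segment_lesion(map, brain, seed_region, k = k, dark = dark,
                          robust = TRUE)
    det <- is_detected(seg, proc$iso$lesion)
  } else {
    x <- if (dark) -map$data else map$data
    sel <- brain$data > 0.5
    peak <- which(sel)[which.max(x[sel])]
    ctr <- c(map$affine %*% c(arrayInd(peak, dim(map$data))[1, ] - 1, 1))[1:3]
    seed_region <- sphere_mask(map, ctr, 8)
    seg <- segment_lesion(map, brain, seed_region, k = k, dark = dark,
                          robust = TRUE)
    det <- seg$n_voxels > 0
  }
  list(detected = det, segmented_ml = seg$volume_ml,
       threshold = seg$threshold, seg = seg)
}
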