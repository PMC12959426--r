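#' Semiautomated threshold segmentation of a lesion
#'
#' Deterministic stand-in for interactive threshold segmentation: the
#' threshold is `mean + k * SD` of the normal-appearing brain (brain mask
#' minus the seed region); the segmentation is the 6-connected
#' suprathreshold component containing the hottest voxel of the seed
#' region. Components smaller than `min_voxels` are discarded (empty
#' result). With `dark = TRUE` the map is negated first, so "hottest"
#' means darkest and the threshold is `mean - k * SD` on the original
#' scale (ADC-dark lesion reading).
#'
#' @param map A [volume] to segment.
#' @param brain Binary brain (or parenchyma) [volume] on the same grid.
#' @param seed_region Binary [volume]: where the reader points; must
#'   intersect `brain`.
#' @param k Threshold multiplier (default 3).
#' @param dark Segment dark instead of bright voxels.
#' @param min_voxels Minimum component size (default 3).
#' @param robust Use median and 1.4826*MAD in place of mean and SD for the
#'   threshold (default `FALSE`). The robust variant is what the cohort
#'   reading uses: heavy anisotropy tails on single-direction maps make the
#'   plain SD estimate of normal-brain spread collapse the threshold.
#' @return List of class `lesion_segmentation`: `mask` (binary [volume]),
#'   `volume_ml`, `threshold` (original map scale), `seed_voxel`
#'   (1-based index triple or `NULL`), `n_voxels`.
#' @export
segment_lesion <- function(map, brain, seed_region, k = 3, dark = FALSE,
                           min_voxels = 3, robust = FALSE) {
  stopifnot(is_volume(map), k > 0)
  if (!same_grid(map, brain) || !same_grid(map, seed_region))
    stop("map, brain and seed_region must share a grid")
  bmask <- brain$data > 0.5
  if (!any(bmask)) stop("empty brain mask")
  smask <- seed_region$data > 0.5 & bmask
  x <- if (dark) -map$data else map$data
  normal <- bmask & !smask
  thr <- if (robust) {
    stats::median(x[normal]) + k * stats::mad(x[normal])
  } else {
    mean(x[normal]) + k * stats::sd(x[normal])
  }
  empty <- function() {
    m <- with_data(map, array(0, dim = dim(map$data)))
    structure(list(mask = m, volume_ml = 0,
                   threshold = if (dark) -thr else thr,
                   seed_voxel = NULL, n_voxels = 0L),
              class = "lesion_segmentation")
  }
  if (!any(smask)) return(empty())
  supra <- bmask & (x > thr)
  seed_idx <- which(smask)
  hot <- seed_idx[which.max(x[seed_idx])]
  if (!supra[hot]) return(empty())
  comp <- flood_fill6(supra, hot)
  if (sum(comp) < min_voxels) return(empty())
  m <- with_data(map, array(as.numeric(comp), dim = dim(map$data)))
  structure(list(mask = m, volume_ml = mask_volume_ml(m),
                 threshold = if (dark) -thr else thr,
                 seed_voxel = arrayInd(hot, dim(map$data))[1, ],
                 n_voxels = sum(comp)),
            class = "lesion_segmentation")
}

# 6-connected component of `start` (linear index) within logical array
flood_fill6 <- function(mask, start) {
  d <- dim(mask)
  nx <- d[1]; nxy <- d[1] * d[2]; n <- length(mask)
  comp <- logical(n)
  comp[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    i0 <- (frontier - 1L) %% nx                    # x index, 0-based
    j0 <- ((frontier - 1L) %/% nx) %% d[2]         # y index
    k0 <- (frontier - 1L) %/% nxy                  # z index
    nb <- c(frontier[i0 > 0L] - 1L,
            frontier[i0 < nx - 1L] + 1L,
            frontier[j0 > 0L] - nx,
            frontier[j0 < d[2] - 1L] + nx,
            frontier[k0 > 0L] - nxy,
            frontier[k0 < d[3] - 1L] + nxy)
    nb <- unique(nb[mask[nb] & !comp[nb]])
    comp[nb] <- TRUE
    frontier <- nb
  }
  dim(comp) <- d
  comp
}

#' Volume of a binary mask in millilitres
#'
#' @param mask Binary [volume] (values 0/1).
#' @return Voxel count times voxel volume (mm^3) / 1000.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(is_volume(mask))
  v <- mask$data
  if (!all(v %in% c(0, 1))) stop("mask is not binary")
  sum(v) * prod(mask$voxel_size) / 1000
}

#' Detection rule: does a segmentation hit the true lesion?
#'
#' Detected iff the segmentation is nonempty and overlaps the truth mask by
#' at least one voxel.
#'
#' @param seg A `lesion_segmentation`.
#' @param truth_lesion Binary truth [volume] on the same grid.
#' @return Logical.
#' @export
is_detected <- function(seg, truth_lesion) {
  stopifnot(inherits(seg, "lesion_segmentation"), is_volume(truth_lesion))
  if (!same_grid(seg$mask, truth_lesion)) stop("grids differ")
  seg$n_voxels > 0 && sum(seg$mask$data > 0.5 & truth_lesion$data > 0.5) >= 1
}

#' ROC analysis of lesion detection against lesion volume
#'
#' Predictor: true lesion volume; outcome: detection. Thresholds are placed
#' at the observed volumes (predict "detected" when volume >= t), plus an
#' all-negative endpoint. The AUC is the trapezoid area, which equals the
#' pairwise concordance statistic with ties counted 0.5.
#'
#' @param volumes Numeric lesion volumes (mL).
#' @param detected Logical detection outcomes.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_detection <- function(volumes, detected) {
  stopifnot(length(volumes) == length(detected), length(volumes) >= 2L)
  detected <- as.logical(detected)
  if (all(detected) || !any(detected))
    stop("ROC requires both detected and missed records")
  thr <- sort(unique(volumes))
  sens <- vapply(thr, function(t) mean(volumes[detected] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(volumes[!detected] < t), numeric(1))
  # curve endpoints: everything positive ... everything negative
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
             (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc), class = "roc_result")
}

# brute-force concordance AUC (independent formulation kept for validation)
auc_concordance <- function(volumes, detected) {
  pos <- volumes[as.logical(detected)]
  neg <- volumes[!as.logical(detected)]
  g <- expand.grid(pos = pos, neg = neg)
  mean((g$pos > g$neg) + 0.5 * (g$pos == g$neg))
}

#' Optimal lesion-volume cut point by the Youden index
#'
#' Maximises `J = sensitivity + specificity - 1` over the ROC thresholds;
#' ties are broken toward the smallest threshold.
#'
#' @param roc A `roc_result`.
#' @return List: `cutpoint` (mL), `j`, `sensitivity`, `specificity` at the
#'   cut point.
#' @export
youden_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- which(j >= max(j) - 1e-12)[1]  # thresholds sorted: first = smallest
  list(cutpoint = roc$thresholds[i], j = j[i],
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i])
}

#' Diagnostic accuracy metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 table, each in percent with a 95% Clopper-Pearson interval. A metric
#' whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with columns `metric`, `numerator`, `denominator`,
#'   `percent`, `lower`, `upper`.
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  one <- function(metric, x, n) {
    if (n == 0)
      return(data.frame(metric = metric, numerator = x, denominator = n,
                        percent = NA_real_, lower = NA_real_,
                        upper = NA_real_))
    ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
    data.frame(metric = metric, numerator = x, denominator = n,
               percent = 100 * x / n, lower = 100 * ci[1],
               upper = 100 * ci[2])
  }
  rbind(one("sensitivity", tp, tp + fn),
        one("specificity", tn, tn + fp),
        one("ppv", tp, tp + fp),
        one("npv", tn, tn + fn))
}

#' Fleiss kappa for multi-rater categorical agreement
#'
#' `kappa = (Pbar - Pe) / (1 - Pe)` with the standard Fleiss definitions
#' over category proportions. Requires at least 2 raters and 2 subjects;
#' when every rating falls in one category the chance agreement Pe is 1 and
#' kappa is undefined (error).
#'
#' @param ratings Subjects x raters matrix (factor levels, characters or
#'   integers); complete (no `NA`).
#' @return Kappa (numeric scalar).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L || ncol(ratings) < 2L)
    stop("need >= 2 subjects and >= 2 raters")
  if (any(is.na(ratings))) stop("ratings table must be complete")
  cats <- sort(unique(as.vector(ratings)))
  if (length(cats) < 2L)
    stop("all ratings fall in one category: kappa undefined")
  n <- ncol(ratings)
  counts <- vapply(cats, function(cc) rowSums(ratings == cc),
                   numeric(nrow(ratings)))
  counts <- matrix(counts, nrow = nrow(ratings))
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_j <- colSums(counts) / (nrow(ratings) * n)
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e < 1e-12)
    stop("chance agreement is 1: kappa undefined")
  (p_bar - p_e) / (1 - p_e)
}

#' Bootstrap confidence interval for Fleiss kappa
#'
#' Resamples subjects (rows) with replacement `B` times, recomputes kappa on
#' each resample, and returns the percentile interval. Degenerate resamples
#' (all ratings one category) are dropped and counted.
#'
#' @param ratings Subjects x raters matrix.
#' @param B Number of bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `kappa_result`: `kappa`, `ci` (length 2), `B`,
#'   `n_degenerate`, `band`.
#' @export
bootstrap_kappa <- function(ratings, B = 500, seed = 1, conf_level = 0.95) {
  stopifnot(B >= 1)
  ratings <- as.matrix(ratings)
  k_hat <- fleiss_kappa(ratings)
  ks <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(nrow(ratings), replace = TRUE)
      tryCatch(fleiss_kappa(ratings[idx, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_deg <- sum(is.na(ks))
  ks <- ks[!is.na(ks)]
  if (!length(ks)) stop("all bootstrap resamples degenerate")
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(ks, c(alpha / 2, 1 - alpha / 2)))
  structure(list(kappa = k_hat, ci = ci, B = B, n_degenerate = n_deg,
                 band = kappa_band(k_hat)),
            class = "kappa_result")
}

#' Landis-Koch interpretation band for a kappa value
#'
#' `<0` poor; `0-0.20` slight; `0.21-0.40` fair; `0.41-0.60` moderate;
#' `0.61-0.80` substantial; `0.81-1.0` almost perfect (upper boundaries
#' inclusive).
#'
#' @param kappa Numeric kappa, at most 1.
#' @return Character band label.
#' @export
kappa_band <- function(kappa) {
  if (kappa > 1) stop("kappa cannot exceed 1")
  if (kappa < 0) return("poor")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}
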