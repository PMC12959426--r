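#' Segmentation quality-control gate
#'
#' A subject's segmentation passes when its supratentorial QC score is
#' strictly above 0.7 and its infratentorial score strictly above 0.1.
#'
#' @param qc_scores Numeric `c(supratentorial, infratentorial)`, each in
#'   \[0, 1\].
#' @param supratentorial_min,infratentorial_min Gate thresholds.
#' @return Logical: include the subject.
#' @export
qc_gate <- function(qc_scores, supratentorial_min = 0.7,
                    infratentorial_min = 0.1) {
  stopifnot(length(qc_scores) == 2L)
  if (any(qc_scores < 0) || any(qc_scores > 1))
    stop("QC scores must lie in [0, 1]")
  qc_scores[[1]] > supratentorial_min && qc_scores[[2]] > infratentorial_min
}

#' Per-region signal standard deviation with lesion subtraction
#'
#' For each region of interest the lesion mask is subtracted from the region
#' and the sample standard deviation (n - 1 denominator) of the map values
#' over the remaining voxels is returned. Regions left with fewer than 2
#' voxels are reported as `NA`.
#'
#' @param map A [volume] (signal image or ADC map).
#' @param masks Named list of binary region [volume]s (e.g. `whole_brain`,
#'   `white_matter`, `cortical_gm`, `deep_gm`).
#' @param lesion Optional binary lesion [volume]; `NULL` for none.
#' @return Named numeric vector of standard deviations (map units).
#' @export
region_sd <- function(map, masks, lesion = NULL) {
  stopifnot(is_volume(map), is.list(masks))
  les <- if (is.null(lesion)) FALSE else {
    if (!same_grid(map, lesion)) stop("lesion mask not on the map grid")
    lesion$data > 0.5
  }
  vapply(masks, function(m) {
    if (!same_grid(map, m)) stop("region mask not on the map grid")
    sel <- (m$data > 0.5) & !les
    if (sum(sel) < 2L) return(NA_real_)
    stats::sd(map$data[sel])
  }, numeric(1))
}

# Exact null distribution of the signed-rank sum W+ with midranks, via the
# shift algorithm on doubled (integer) ranks. Returns P(W+ <= w) and
# P(W+ >= w).
signed_rank_tails <- function(w, r) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1)  # counts over support 0..tot of 2*W+
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
    f <- g
  }
  p <- f / 2^length(r)
  w2 <- 2 * w
  lower <- sum(p[seq_len(floor(w2 + 1e-9) + 1)])
  upper <- sum(p[(ceiling(w2 - 1e-9) + 1):(tot + 1)])
  c(lower = lower, upper = upper)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided test on per-subject (SD, MD) value pairs. Differences
#' `d = md - sd` of zero are dropped (Wilcoxon's original rule; `pratt`
#' keeps them in the ranking). The statistic `W` is the rank sum of positive
#' differences. The exact tie-aware null distribution (midranks, shift
#' algorithm) is used when the informative n is at most `exact_max`;
#' otherwise the normal approximation with continuity and tie correction.
#'
#' @param sd_values,md_values Paired numeric vectors (one entry per subject).
#' @param exact_max Largest informative n for the exact branch (default 25).
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return List: `statistic` (W), `p_value`, `n_informative`, `method`,
#'   `no_informative_pairs` flag.
#' @export
paired_wilcoxon <- function(sd_values, md_values, exact_max = 25,
                            zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  stopifnot(length(sd_values) == length(md_values), length(sd_values) >= 1L)
  d <- md_values - sd_values
  if (zeros == "drop") d_ranked <- d[d != 0] else d_ranked <- d
  n <- sum(d_ranked != 0)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_informative = 0L,
                method = "none", no_informative_pairs = TRUE))
  }
  r_all <- rank(abs(d_ranked))
  if (zeros == "pratt") {
    keep <- d_ranked != 0
    r <- r_all[keep]
    dd <- d_ranked[keep]
  } else {
    r <- r_all
    dd <- d_ranked
  }
  w <- sum(r[dd > 0])
  if (n <= exact_max) {
    tails <- signed_rank_tails(w, r)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4  # = tie-corrected n(n+1)(2n+1)/24 with midranks
    z_num <- w - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_informative = as.integer(n),
       method = method, no_informative_pairs = FALSE)
}
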