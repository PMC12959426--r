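#' Acquisition specification
#'
#' Defines a diffusion acquisition: b-values, gradient direction set,
#' noise level and optional inter-series motion. `"sd"` is the
#' single-direction protocol (one b=900 s/mm^2 volume along z), `"md"` the
#' multi-direction protocol (three orthogonal directions x, y, z).
#'
#' @param directions `"sd"`, `"md"`, or an n x 3 matrix of unit row vectors
#'   (1 <= n <= 3).
#' @param b Diffusion weighting, s/mm^2 (default 900).
#' @param sigma Gaussian channel noise standard deviation (image units). If
#'   `NULL` and `snr` is given, derived as `s0_wm / snr`.
#' @param snr Target b=0 white-matter signal-to-noise ratio (used only when
#'   `sigma` is `NULL`). Presets: 15 ("v1-like"), 20 ("v2-like").
#' @param s0_wm White-matter S0 used for the SNR-to-sigma conversion.
#' @param motion `NULL` (no motion), or `list(max_translation = mm,
#'   max_rotation = degrees)` from which one small rigid transform per
#'   diffusion series is drawn at simulation time.
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(directions = "md", b = 900, sigma = NULL,
                             snr = 15, s0_wm = 800, motion = NULL) {
  if (is.character(directions)) {
    directions <- switch(match.arg(directions, c("sd", "md")),
                         sd = matrix(c(0, 0, 1), 1, 3, byrow = TRUE),
                         md = diag(3))
  }
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L, nrow(directions) >= 1L,
            nrow(directions) <= 3L)
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-8)) stop("gradient directions must be unit")
  if (nrow(directions) == 3L) {
    gram <- directions %*% t(directions)
    if (max(abs(gram[upper.tri(gram)])) > 1e-8)
      stop("three directions must be pairwise orthogonal")
  }
  if (b < 0) stop("b must be >= 0")
  if (is.null(sigma)) sigma <- if (is.null(snr) || snr <= 0) 0 else s0_wm / snr
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(directions = directions, b = b, sigma = sigma,
                 motion = motion), class = "acquisition_spec")
}

#' Simulate a noiseless diffusion series from phantom truth
#'
#' Monoexponential tensor signal model: `S(g) = S0 * exp(-b * g' D g)` per
#' voxel and direction; the b=0 volume equals S0. If the acquisition
#' specifies motion, one small rigid transform per diffusion series is drawn
#' from the current RNG state and applied (trilinear resampling), emulating
#' inter-series patient motion; the b=0 volume stays fixed.
#'
#' @param truth A `phantom_truth` from [build_phantom()].
#' @param acq An [acquisition_spec()].
#' @return A list of class `dwi_series`: `b0` ([volume]), `dwi` (list of
#'   `list(g, vol)`), `b`, and `provenance` (noise state, applied motion).
#' @export
simulate_series <- function(truth, acq) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(acq, "acquisition_spec"))
  s0 <- truth$s0
  dwi <- vector("list", nrow(acq$directions))
  motions <- NULL
  if (!is.null(acq$motion)) {
    motions <- replicate(nrow(acq$directions),
                         random_rigid(acq$motion$max_translation,
                                      acq$motion$max_rotation),
                         simplify = FALSE)
  }
  for (i in seq_len(nrow(acq$directions))) {
    g <- acq$directions[i, ]
    q <- tensor_adc(truth, g)
    vol <- with_data(s0, s0$data * exp(-acq$b * q$data))
    if (!is.null(motions)) vol <- apply_transform(vol, motions[[i]])
    dwi[[i]] <- list(g = g, vol = vol)
  }
  structure(list(b0 = s0, dwi = dwi, b = acq$b,
                 provenance = list(noise = "noiseless", seed = NULL,
                                   motion = motions)),
            class = "dwi_series")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rician <- function(x, sigma) {
  sqrt((x + stats::rnorm(length(x), 0, sigma))^2 +
       stats::rnorm(length(x), 0, sigma)^2)
}

#' Add Rician noise to a diffusion series
#'
#' Magnitude-MRI noise: each voxel value S is replaced by
#' `sqrt((S + n1)^2 + n2^2)` with independent zero-mean Gaussian channels
#' n1, n2 of standard deviation `sigma`. Applied to the b=0 and every
#' diffusion volume. Reproducible under `seed`.
#'
#' @param series A `dwi_series`.
#' @param sigma Channel noise standard deviation (image units), >= 0.
#' @param seed Integer seed.
#' @return A `dwi_series` with noisy volumes and updated provenance.
#' @export
add_rician_noise <- function(series, sigma, seed) {
  stopifnot(inherits(series, "dwi_series"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(series)
  with_seed(seed, {
    series$b0$data <- array(rician(series$b0$data, sigma),
                            dim = dim(series$b0$data))
    for (i in seq_along(series$dwi)) {
      v <- series$dwi[[i]]$vol
      series$dwi[[i]]$vol$data <- array(rician(v$data, sigma),
                                        dim = dim(v$data))
    }
  })
  series$provenance$noise <- "noisy"
  series$provenance$seed <- seed
  series$provenance$sigma <- sigma
  series
}
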