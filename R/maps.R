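#' Compute an apparent diffusion coefficient map
#'
#' Voxelwise `ADC = -(1/b) * log(S_b / S_0)`. Signals below
#' `epsilon = 1e-6 * max(b0)` are clamped to epsilon before the log, and the
#' output is clamped to `[0, adc_max]`; both clamp counts are reported in the
#' `qa` attribute rather than propagated as log blow-ups.
#'
#' @param b0 The b=0 [volume].
#' @param dwi A diffusion-weighted [volume] on the same grid.
#' @param b Diffusion weighting, s/mm^2 (> 0).
#' @param adc_max Upper physical clamp, mm^2/s (default 4e-3).
#' @param source Provenance tag stored on the result
#'   (`"single-direction"` or `"trace"`).
#' @return A [volume] of ADC values (mm^2/s) with attributes `qa`
#'   (`n_signal_clamped`, `n_range_clamped`), `b`, and `source`.
#' @export
compute_adc <- function(b0, dwi, b, adc_max = 4e-3,
                        source = "single-direction") {
  stopifnot(is_volume(b0), is_volume(dwi))
  if (!same_grid(b0, dwi)) stop("b0 and dwi are not on the same grid")
  if (b <= 0) stop("b must be > 0")
  eps <- 1e-6 * max(b0$data)
  if (eps <= 0) stop("b0 volume has no signal")
  n_signal <- sum(b0$data < eps | dwi$data < eps)
  s0 <- pmax(b0$data, eps)
  sb <- pmax(dwi$data, eps)
  adc <- -log(sb / s0) / b
  n_range <- sum(adc < 0 | adc > adc_max)
  adc <- pmin(pmax(adc, 0), adc_max)
  out <- with_data(b0, array(adc, dim = dim(b0$data)))
  attr(out, "qa") <- list(n_signal_clamped = n_signal,
                          n_range_clamped = n_range)
  attr(out, "b") <- b
  attr(out, "source") <- source
  out
}

#' Synthesise trace DWI and trace ADC maps from three aligned directions
#'
#' Trace DWI is the voxelwise geometric mean of the three coregistered
#' direction volumes, `(S_x S_y S_z)^(1/3)`; its contrast depends only on
#' the mean diffusivity, suppressing tract anisotropy. The trace ADC is, by
#' default, the arithmetic mean of the three per-direction ADC maps; where
#' all signals exceed the log-safety epsilon this is identical to
#' `-(1/b) log(trace / S0)` (the `"geometric"` route, also exposed).
#'
#' @param series A `dwi_series` with exactly 3 direction volumes already on
#'   the b=0 grid (see [align_series()]).
#' @param adc_max Upper ADC clamp, mm^2/s.
#' @param method `"mean_adc"` (default) or `"geometric"`.
#' @return List with elements `trace_dwi` ([volume]) and `trace_adc`
#'   (ADC [volume], as from [compute_adc()]).
#' @export
compute_trace_maps <- function(series, adc_max = 4e-3,
                               method = c("mean_adc", "geometric")) {
  stopifnot(inherits(series, "dwi_series"))
  method <- match.arg(method)
  if (length(series$dwi) != 3L)
    stop("trace maps require exactly 3 direction volumes")
  b0 <- series$b0
  vols <- lapply(series$dwi, `[[`, "vol")
  for (v in vols) if (!same_grid(b0, v))
    stop("direction volumes are not aligned to the b0 grid")
  prod_dat <- vols[[1]]$data * vols[[2]]$data * vols[[3]]$data
  trace_dwi <- with_data(b0, array(pmax(prod_dat, 0)^(1 / 3),
                                   dim = dim(b0$data)))
  if (method == "mean_adc") {
    adcs <- lapply(vols, function(v)
      compute_adc(b0, v, series$b, adc_max = adc_max))
    mean_dat <- (adcs[[1]]$data + adcs[[2]]$data + adcs[[3]]$data) / 3
    trace_adc <- with_data(b0, mean_dat)
    attr(trace_adc, "qa") <- list(
      n_signal_clamped = sum(vapply(adcs, function(a)
        attr(a, "qa")$n_signal_clamped, numeric(1))),
      n_range_clamped = sum(vapply(adcs, function(a)
        attr(a, "qa")$n_range_clamped, numeric(1))))
    attr(trace_adc, "b") <- series$b
    attr(trace_adc, "source") <- "trace"
  } else {
    trace_adc <- compute_adc(b0, trace_dwi, series$b, adc_max = adc_max,
                             source = "trace")
  }
  list(trace_dwi = trace_dwi, trace_adc = trace_adc)
}

#' Coregister every direction volume of a series to its b=0
#'
#' The processing chain starts by registering each
#' diffusion-weighted volume to the b=0 reference with a 12-parameter
#' affine ([register_affine()]), then resampling it onto the b=0 grid.
#'
#' @param series A `dwi_series`.
#' @param ... Passed to [register_affine()].
#' @return The series with aligned direction volumes; the estimated
#'   transforms are stored in `provenance$registration`.
#' @export
align_series <- function(series, ...) {
  stopifnot(inherits(series, "dwi_series"))
  transforms <- vector("list", length(series$dwi))
  for (i in seq_along(series$dwi)) {
    tr <- register_affine(series$dwi[[i]]$vol, series$b0, ...)
    series$dwi[[i]]$vol <- apply_transform(series$dwi[[i]]$vol, tr,
                                           target = series$b0,
                                           center = attr(tr, "center"))
    transforms[[i]] <- tr
  }
  series$provenance$registration <- transforms
  series
}
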