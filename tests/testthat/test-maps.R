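test_that("ADC computation inverts the signal model", {
  b0 <- const_volume(1000, dim = c(4L, 4L, 4L))
  dwi <- const_volume(406.5697, dim = c(4L, 4L, 4L))
  adc <- compute_adc(b0, dwi, 900)
  expect_equal(adc$data[1], 1.000e-3, tolerance = 1e-6)
  # S_b = S0 -> ADC 0
  expect_true(all(compute_adc(b0, b0, 900)$data == 0))
  expect_error(compute_adc(b0, dwi, 0), "b must be > 0")
  small <- const_volume(1000, dim = c(5L, 5L, 5L))
  expect_error(compute_adc(b0, small, 900), "same grid")
})

test_that("degenerate signals are clamped and counted, not propagated", {
  b0 <- const_volume(1000, dim = c(4L, 4L, 4L))
  dwi <- const_volume(500, dim = c(4L, 4L, 4L))
  dwi$data[1, 1, 1] <- 0          # dead voxel
  dwi$data[2, 1, 1] <- 2000       # noise pushed S_b above S0
  adc <- compute_adc(b0, dwi, 900)
  qa <- attr(adc, "qa")
  expect_equal(qa$n_signal_clamped, 1)
  expect_gte(qa$n_range_clamped, 2)
  expect_equal(adc$data[1, 1, 1], 4e-3)   # capped at ADC_max
  expect_equal(adc$data[2, 1, 1], 0)      # negative ADC clamped to 0
  expect_true(all(is.finite(adc$data)))
})

test_that("trace maps: geometric mean and mean-ADC forms agree", {
  b0 <- const_volume(1000, dim = c(4L, 4L, 4L))
  mk <- function(vals) {
    structure(list(
      b0 = b0,
      dwi = lapply(seq_along(vals), function(i)
        list(g = diag(3)[i, ], vol = const_volume(vals[i],
                                                  dim = c(4L, 4L, 4L)))),
      b = 900, provenance = list(noise = "noiseless")),
      class = "dwi_series")
  }
  tr1 <- compute_trace_maps(mk(c(500, 500, 500)))
  expect_equal(tr1$trace_dwi$data[1], 500, tolerance = 1e-12)

  tr2 <- compute_trace_maps(mk(c(800, 100, 100)))
  expect_equal(tr2$trace_dwi$data[1], 200, tolerance = 1e-9)
  expect_equal(tr2$trace_adc$data[1], log(5) / 900, tolerance = 1e-9)
  expect_equal(tr2$trace_adc$data[1], 1.7883e-3, tolerance = 1e-4)

  tr2g <- compute_trace_maps(mk(c(800, 100, 100)), method = "geometric")
  expect_equal(tr2g$trace_adc$data, tr2$trace_adc$data, tolerance = 1e-9)

  expect_error(compute_trace_maps(mk(c(500, 500))), "3 direction")
})

test_that("trace ADC is rotation invariant while per-direction ADC is not", {
  spec <- tiny_spec()
  set.seed(12)
  per_dir <- c(); trace_vals <- c()
  for (rep in 1:25) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    # single anisotropic tensor with principal axis u
    l_par <- 1.4e-3; l_perp <- 0.4e-3
    D <- l_perp * diag(3) + (l_par - l_perp) * (u %*% t(u))
    for (g in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      per_dir <- c(per_dir, c(t(g) %*% D %*% g))
    }
    trace_vals <- c(trace_vals, sum(diag(D)) / 3)
  }
  expect_lt(max(abs(trace_vals - 2.2e-3 / 3)), 1e-9)
  expect_true(all(per_dir >= 0.4e-3 - 1e-12 & per_dir <= 1.4e-3 + 1e-12))
  expect_gt(max(per_dir) - min(per_dir), 0.8e-3)

  # end-to-end: simulated series of a rotated-fan phantom, trace ADC equals
  # the true mean diffusivity everywhere in brain
  truth <- build_phantom(spec)
  ser <- simulate_series(truth, acquisition_spec("md", sigma = 0))
  tr <- compute_trace_maps(ser)
  br <- truth$masks$whole_brain$data > 0.5
  expect_lt(max(abs(tr$trace_adc$data[br] - truth$md$data[br])), 1e-9)
})

test_that("series alignment undoes simulated inter-series motion", {
  truth <- build_phantom(phantom_spec())   # full-resolution phantom
  set.seed(21)
  acq <- acquisition_spec("sd", sigma = 0,
                          motion = list(max_translation = 2,
                                        max_rotation = 2))
  ser <- simulate_series(truth, acq)
  moved_err <- max(abs(ser$dwi[[1]]$vol$data -
                       simulate_series(truth,
                         acquisition_spec("sd", sigma = 0))$dwi[[1]]$vol$data))
  expect_gt(moved_err, 1)   # motion visibly changed the volume
  al <- align_series(ser)
  est <- al$provenance$registration[[1]]
  tr0 <- ser$provenance$motion[[1]]
  M <- affine_matrix(tr0, center_world(truth$s0)) %*%
    affine_matrix(est, attr(est, "center"))
  expect_lt(max(abs(M[1:3, 4])), 0.3)            # residual translation, mm
  expect_lt(max(abs(M[1:3, 1:3] - diag(3))), 5e-3)
})
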