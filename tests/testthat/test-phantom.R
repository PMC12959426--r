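test_that("phantom masks partition the brain and lesions stamp correctly", {
  truth0 <- build_phantom(tiny_spec())
  m <- truth0$masks
  union <- m$white_matter$data + m$cortical_gm$data + m$deep_gm$data +
    m$csf$data
  expect_true(all(union == m$whole_brain$data))   # disjoint + covering
  expect_true(all(union <= 1))
  expect_equal(sum(truth0$lesion$data), 0)

  truth1 <- build_phantom(tiny_spec(
    lesions = list(list(center = c(20, -20, 0), volume_ml = 2))))
  expect_gt(sum(truth1$lesion$data), 0)
  expect_true(all(truth1$lesion$data <= truth1$masks$whole_brain$data))
  # lesion voxels are isotropic at the lesion ADC
  les <- truth1$lesion$data > 0.5
  expect_true(all(truth1$tensor$xx[les] == 0.4e-3))
  expect_true(all(truth1$tensor$xy[les] == 0))
  expect_equal(max(abs(truth1$md$data[les] - 0.4e-3)), 0)

  expect_error(build_phantom(tiny_spec(
    lesions = list(list(center = c(200, 0, 0), volume_ml = 1)))),
    "outside brain")
  expect_error(build_phantom(tiny_spec(
    lesions = list(list(center = c(20, -20, 0), volume_ml = 2),
                   list(center = c(21, -21, 0), volume_ml = 2)))),
    "overlapping")
})

test_that("tensor field is physical: symmetric PSD, bounded eigenvalues", {
  truth <- build_phantom(tiny_spec())
  tn <- truth$tensor
  br <- truth$masks$whole_brain$data > 0.5
  idx <- which(br)[seq(1, sum(br), by = 7)]
  for (i in idx) {
    D <- matrix(c(tn$xx[i], tn$xy[i], tn$xz[i],
                  tn$xy[i], tn$yy[i], tn$yz[i],
                  tn$xz[i], tn$yz[i], tn$zz[i]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-18))
    expect_true(all(ev <= 4e-3))
  }
})

test_that("fractional anisotropy: closed form and isotropic limit", {
  expect_equal(fractional_anisotropy(c(1.4, 0.4, 0.4) * 1e-3), 0.6623,
               tolerance = 1e-4)
  expect_equal(fractional_anisotropy(c(0.8, 0.8, 0.8) * 1e-3), 0)
  expect_equal(fractional_anisotropy(c(0, 0, 0)), 0)
  m <- fractional_anisotropy(rbind(c(1.4, 0.4, 0.4), c(1, 1, 1)))
  expect_equal(m[2], 0)
})

test_that("signal model follows S0 exp(-b gDg)", {
  truth <- build_phantom(tiny_spec())
  # isotropic gray matter voxel: D = 0.8e-3, S0 = 1000
  acq <- acquisition_spec("md", sigma = 0)
  ser <- simulate_series(truth, acq)
  cgm <- truth$masks$cortical_gm$data > 0.5
  for (d in 1:3)
    expect_equal(max(abs(ser$dwi[[d]]$vol$data[cgm] -
                         1000 * exp(-900 * 0.8e-3))), 0)
  # b = 0 returns S0 exactly
  ser0 <- simulate_series(truth, acquisition_spec("md", b = 0, sigma = 0))
  for (d in 1:3)
    expect_identical(ser0$dwi[[d]]$vol$data, truth$s0$data)

  # closed-form worked examples on a hand-built tensor
  expect_equal(1000 * exp(-900 * 1.0e-3), 406.5697, tolerance = 1e-4)
  g <- c(1, 0, 0)
  # fiber along x with eigenvalues (1.4, .4, .4)e-3 at S0=1000
  sx <- 1000 * exp(-900 * 1.4e-3)
  sy <- 1000 * exp(-900 * 0.4e-3)
  expect_equal(sx, 283.654, tolerance = 1e-3)
  expect_equal(sy, 697.676, tolerance = 1e-3)

  expect_error(acquisition_spec(matrix(c(1, 1, 0), 1)), "unit")
  expect_error(acquisition_spec("md", b = -1), ">= 0")
})

test_that("orthogonal-direction diffusivities sum to the tensor trace", {
  truth <- build_phantom(tiny_spec())
  qx <- tensor_adc(truth, c(1, 0, 0))$data
  qy <- tensor_adc(truth, c(0, 1, 0))$data
  qz <- tensor_adc(truth, c(0, 0, 1))$data
  tr <- truth$tensor$xx + truth$tensor$yy + truth$tensor$zz
  expect_lt(max(abs(qx + qy + qz - tr)), 1e-18)
})

test_that("Rician noise: identity at zero, Rayleigh background, moments", {
  truth <- build_phantom(tiny_spec())
  ser <- simulate_series(truth, acquisition_spec("sd", sigma = 0))
  expect_identical(add_rician_noise(ser, 0, 1)$b0$data, ser$b0$data)

  n1 <- add_rician_noise(ser, 10, 99)
  n2 <- add_rician_noise(ser, 10, 99)
  expect_identical(n1$b0$data, n2$b0$data)        # seeded determinism
  n3 <- add_rician_noise(ser, 10, 100)
  expect_false(identical(n1$b0$data, n3$b0$data))

  # background (S = 0) is Rayleigh with mean sigma * sqrt(pi/2)
  bg <- truth$s0$data == 0
  expect_gt(sum(bg), 5000)
  big <- volume(array(0, dim = c(50, 50, 50)))
  ser_bg <- structure(list(b0 = big, dwi = list(), b = 900,
                           provenance = list(noise = "noiseless")),
                      class = "dwi_series")
  noisy <- add_rician_noise(ser_bg, 10, 7)
  expect_equal(mean(noisy$b0$data), 10 * sqrt(pi / 2), tolerance = 0.1 / 12.5)
  # second moment: E[M^2] = S^2 + 2 sigma^2 within 3 standard errors
  s_const <- volume(array(50, dim = c(40, 40, 40)))
  ser_c <- structure(list(b0 = s_const, dwi = list(), b = 900,
                          provenance = list(noise = "noiseless")),
                     class = "dwi_series")
  nc <- add_rician_noise(ser_c, 10, 8)$b0$data
  m2 <- mean(nc^2)
  se <- sd(nc^2) / sqrt(length(nc))
  expect_lt(abs(m2 - (50^2 + 2 * 100)), 3 * se)
  expect_error(add_rician_noise(ser, -1, 1), ">= 0")
})

test_that("subjects derive distinct, reproducible realizations", {
  cfg <- as_run_config(list(
    phantom = list(grid_dim = c(32L, 32L, 16L), voxel_size = c(4.5, 4.5, 9)),
    acquisition = list(motion = NULL)))
  s1a <- simulate_subject(cfg, 1)
  s1b <- simulate_subject(cfg, 1)
  s2 <- simulate_subject(cfg, 2)
  expect_identical(s1a$sd$dwi[[1]]$vol$data, s1b$sd$dwi[[1]]$vol$data)
  expect_false(identical(s1a$sd$dwi[[1]]$vol$data, s2$sd$dwi[[1]]$vol$data))
  expect_true(s1a$true_volume_ml >= 0)
  mim <- simulate_subject(cfg, 3, mimic = TRUE)
  expect_equal(mim$true_volume_ml, 0)
  expect_equal(sum(mim$truth$lesion$data), 0)
})
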