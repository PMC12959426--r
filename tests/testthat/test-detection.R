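test_that("threshold segmentation recovers a hot sphere exactly", {
  tmpl <- const_volume(100, dim = c(24L, 24L, 24L))
  brain <- const_volume(1, dim = c(24L, 24L, 24L))
  sphere <- centered_sphere(tmpl, 4)
  map <- with_data(tmpl, tmpl$data + 200 * sphere$data)
  seed_region <- centered_sphere(tmpl, 6)
  seg <- segment_lesion(map, brain, seed_region, k = 3)
  expect_identical(seg$mask$data, sphere$data)
  expect_equal(seg$n_voxels, sum(sphere$data))
  # threshold is mean + 3 SD of normal-appearing brain (flat background)
  norm <- brain$data > 0.5 & !(seed_region$data > 0.5)
  expect_equal(seg$threshold, mean(map$data[norm]) + 3 * sd(map$data[norm]))
})

test_that("segmentation is seeded: only the pointed-at component returns", {
  tmpl <- const_volume(100, dim = c(30L, 12L, 12L))
  brain <- const_volume(1, dim = c(30L, 12L, 12L))
  map <- tmpl
  map$data[4:6, 5:7, 5:7] <- 300     # component A
  map$data[22:25, 5:7, 5:7] <- 300   # component B
  seed_region <- const_volume(0, dim = c(30L, 12L, 12L))
  seed_region$data[3:8, 4:8, 4:8] <- 1
  seg <- segment_lesion(map, brain, seed_region, k = 3)
  expect_equal(seg$n_voxels, 27)
  expect_true(all(which(seg$mask$data > 0) %in%
                  which(slice.index(map$data, 1) <= 6)))
})

test_that("segmentation degenerate cases", {
  tmpl <- const_volume(100, dim = c(10L, 10L, 10L))
  brain <- const_volume(1, dim = c(10L, 10L, 10L))
  seed_region <- centered_sphere(tmpl, 3)
  # flat image: nothing exceeds mean + 3 SD (SD = 0)
  set.seed(5)
  noisy <- with_data(tmpl, tmpl$data + rnorm(1000))
  seg <- segment_lesion(noisy, brain, seed_region, k = 5)
  expect_equal(seg$n_voxels, 0L)
  expect_equal(seg$volume_ml, 0)
  # sub-minimum component discarded
  map <- tmpl; map$data[5, 5, 5] <- 1000
  seg2 <- segment_lesion(map, brain, seed_region, k = 3, min_voxels = 3)
  expect_equal(seg2$n_voxels, 0L)
  expect_error(segment_lesion(map, const_volume(0, dim = c(10L, 10L, 10L)),
                              seed_region), "empty brain")
})

test_that("mask volumes are voxel count times voxel volume", {
  empty <- const_volume(0, dim = c(10L, 10L, 10L))
  expect_equal(mask_volume_ml(empty), 0)
  m <- const_volume(0, dim = c(20L, 20L, 20L))
  m$data[seq_len(150)] <- 1
  expect_equal(mask_volume_ml(m), 0.15)   # 150 voxels at 1 mm^3
  m2 <- const_volume(0, dim = c(10L, 10L, 10L), voxel_size = c(1.5, 1.5, 5))
  m2$data[seq_len(100)] <- 1
  expect_equal(mask_volume_ml(m2), 1.125)
  bad <- const_volume(0.5, dim = c(4L, 4L, 4L))
  expect_error(mask_volume_ml(bad), "binary")
})

test_that("detection rule: nonempty segmentation with >= 1 voxel overlap", {
  tmpl <- const_volume(100, dim = c(16L, 16L, 16L))
  brain <- const_volume(1, dim = c(16L, 16L, 16L))
  map <- tmpl; map$data[6:8, 8, 8] <- 300
  seed_region <- const_volume(1, dim = c(16L, 16L, 16L))
  seed_region$data[12:16, , ] <- 0
  seg <- segment_lesion(map, brain, seed_region, k = 3)
  truth1 <- const_volume(0, dim = c(16L, 16L, 16L)); truth1$data[8, 8, 8] <- 1
  truth0 <- const_volume(0, dim = c(16L, 16L, 16L)); truth0$data[14, 2, 2] <- 1
  expect_true(is_detected(seg, truth1))
  expect_false(is_detected(seg, truth0))
  flat <- segment_lesion(tmpl, brain, seed_region, k = 3)
  expect_false(is_detected(flat, truth1))
})

test_that("ROC trapezoid area equals pairwise concordance", {
  roc1 <- roc_detection(c(0.8, 1.0, 2.0, 0.2, 0.5),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc1$auc, 1.0)
  roc2 <- roc_detection(c(0.5, 1.0, 0.5, 0.2),
                        c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc2$auc, 0.875)
  expect_error(roc_detection(c(1, 2), c(TRUE, TRUE)), "both")

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    vols <- round(runif(n, 0, 3), sample(0:2, 1))  # induce ties
    det <- runif(n) < plogis(vols - 1)
    if (all(det) || !any(det)) next
    roc <- roc_detection(vols, det)
    expect_equal(roc$auc, lfdwi:::auc_concordance(vols, det),
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with pROC on untied data", {
  skip_if_not_installed("pROC")
  set.seed(7)
  vols <- runif(30); det <- runif(30) < plogis(4 * vols - 2)
  if (any(det) && !all(det)) {
    ref <- suppressMessages(pROC::auc(pROC::roc(det, vols, direction = "<")))
    expect_equal(roc_detection(vols, det)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("Youden cut point maximises J with smallest-threshold ties", {
  roc <- roc_detection(c(0.8, 1.0, 2.0, 0.2, 0.5),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cp <- youden_cutpoint(roc)
  expect_equal(cp$cutpoint, 0.8)
  expect_equal(cp$j, 1)
  # tie: two thresholds with equal J -> smaller wins
  roc2 <- roc_detection(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  cp2 <- youden_cutpoint(roc2)
  j_brute <- vapply(roc2$thresholds, function(t) {
    vols <- c(1, 2, 3, 4); det <- c(FALSE, TRUE, FALSE, TRUE)
    mean(vols[det] >= t) + mean(vols[!det] < t) - 1
  }, numeric(1))
  expect_equal(cp2$j, max(j_brute))
  expect_equal(cp2$cutpoint, roc2$thresholds[which.max(j_brute)])

  set.seed(31)
  for (rep in 1:10) {
    vols <- round(runif(12, 0, 2), 1)
    det <- runif(12) < plogis(3 * vols - 2)
    if (all(det) || !any(det)) next
    roc3 <- roc_detection(vols, det)
    cp3 <- youden_cutpoint(roc3)
    jb <- vapply(roc3$thresholds, function(t)
      mean(vols[det] >= t) + mean(vols[!det] < t) - 1, numeric(1))
    expect_equal(cp3$j, max(jb), tolerance = 1e-12)
  }
})

test_that("diagnostic metrics with exact binomial CIs", {
  dm <- diagnostic_metrics(tp = 19, fp = 3, tn = 30, fn = 1)
  expect_equal(dm$percent[dm$metric == "sensitivity"], 95.0)
  expect_equal(dm$percent[dm$metric == "specificity"], 100 * 30 / 33,
               tolerance = 1e-9)
  expect_equal(dm$percent[dm$metric == "ppv"], 100 * 19 / 22,
               tolerance = 1e-9)
  expect_equal(dm$percent[dm$metric == "npv"], 100 * 30 / 31,
               tolerance = 1e-9)
  perfect <- diagnostic_metrics(10, 0, 12, 0)
  expect_true(all(perfect$percent == 100))
  # Clopper-Pearson via beta quantiles, 19/20 successes
  sens <- diagnostic_metrics(19, 0, 0, 1)[1, ]
  expect_equal(sens$lower, 100 * qbeta(0.025, 19, 2), tolerance = 1e-9)
  expect_equal(sens$upper, 100 * qbeta(0.975, 20, 1), tolerance = 1e-9)
  expect_equal(round(sens$lower, 1), 75.1)
  expect_equal(round(sens$upper, 1), 99.9)
  # undefined, not zero
  dm0 <- diagnostic_metrics(0, 0, 5, 5)
  expect_true(is.na(dm0$percent[dm0$metric == "ppv"]))
})

test_that("Fleiss kappa matches the worked example and its invariances", {
  perfect <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(fleiss_kappa(perfect), 1)
  ex <- cbind(c(1, 1, 0, 1), c(1, 1, 0, 0))
  expect_equal(fleiss_kappa(ex), 7 / 15, tolerance = 1e-12)
  expect_equal(round(fleiss_kappa(ex), 4), 0.4667)
  expect_error(fleiss_kappa(cbind(c(1, 1), c(1, 1))), "one category")
  # subject- and rater-order invariance
  set.seed(17)
  r <- matrix(sample(0:2, 30, replace = TRUE), 10, 3)
  expect_equal(fleiss_kappa(r), fleiss_kappa(r[sample(10), ]))
  expect_equal(fleiss_kappa(r), fleiss_kappa(r[, c(3, 1, 2)]))
})

test_that("bootstrap kappa: degenerate, deterministic, and covering", {
  perfect <- cbind(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  bk <- bootstrap_kappa(perfect, B = 100, seed = 4)
  expect_equal(bk$ci, c(1, 1))
  ex <- cbind(c(1, 1, 0, 1, 0, 1, 0, 1), c(1, 1, 0, 0, 0, 1, 1, 1))
  b1 <- bootstrap_kappa(ex, B = 500, seed = 42)
  b2 <- bootstrap_kappa(ex, B = 500, seed = 42)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= b1$kappa && b1$kappa <= b1$ci[2])
})

test_that("bootstrap kappa CI covers the population kappa in simulation", {
  # two raters each flip a fair latent label with 10% error;
  # population kappa = (1 - 2*eps)^2 analytically for this mechanism
  eps <- 0.1
  kappa_true <- (1 - 2 * eps)^2
  hits <- 0; reps <- 40
  set.seed(2024)
  for (i in seq_len(reps)) {
    latent <- rbinom(60, 1, 0.5)
    r1 <- ifelse(runif(60) < eps, 1 - latent, latent)
    r2 <- ifelse(runif(60) < eps, 1 - latent, latent)
    bk <- bootstrap_kappa(cbind(r1, r2), B = 200, seed = i)
    hits <- hits + (bk$ci[1] <= kappa_true && kappa_true <= bk$ci[2])
  }
  expect_gte(hits / reps, 0.9)
})

test_that("kappa interpretation bands follow the published cut-offs", {
  expect_equal(kappa_band(0.72), "substantial")
  expect_equal(kappa_band(0.84), "almost perfect")
  expect_equal(kappa_band(-0.1), "poor")
  expect_equal(kappa_band(0), "slight")
  expect_equal(kappa_band(0.20), "slight")
  expect_equal(kappa_band(0.21), "fair")
  expect_equal(kappa_band(0.60), "moderate")
  expect_equal(kappa_band(0.80), "substantial")
  expect_equal(kappa_band(1), "almost perfect")
  expect_error(kappa_band(1.2), "exceed")
})
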