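test_that("QC gate applies strict supratentorial/infratentorial thresholds", {
  expect_true(qc_gate(c(0.75, 0.2)))
  expect_false(qc_gate(c(0.65, 0.2)))
  expect_false(qc_gate(c(0.7, 0.5)))    # boundary is exclusive
  expect_false(qc_gate(c(0.9, 0.1)))
  expect_error(qc_gate(c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("region SD subtracts the lesion and uses the sample estimator", {
  tmpl <- const_volume(dim = c(4L, 1L, 1L))
  map <- with_data(tmpl, array(c(1, 2, 3, 4), dim = c(4, 1, 1)))
  region <- with_data(tmpl, array(1, dim = c(4, 1, 1)))
  expect_equal(unname(region_sd(map, list(r = region))),
               sd(c(1, 2, 3, 4)), tolerance = 1e-12)
  expect_equal(unname(region_sd(map, list(r = region))), 1.2910,
               tolerance = 1e-4)

  map2 <- with_data(tmpl, array(c(1, 2, 3, 100), dim = c(4, 1, 1)))
  lesion <- with_data(tmpl, array(c(0, 0, 0, 1), dim = c(4, 1, 1)))
  expect_equal(unname(region_sd(map2, list(r = region), lesion)), 1,
               tolerance = 1e-12)

  # constant region -> 0; starved region -> NA
  cmap <- with_data(tmpl, array(7, dim = c(4, 1, 1)))
  expect_equal(unname(region_sd(cmap, list(r = region))), 0)
  tiny <- with_data(tmpl, array(c(1, 0, 0, 0), dim = c(4, 1, 1)))
  expect_true(is.na(region_sd(map, list(r = tiny))))
})

test_that("region SD ignores voxel order and out-of-region lesion voxels", {
  set.seed(11)
  tmpl <- const_volume(dim = c(5L, 4L, 3L))
  vals <- array(rnorm(60), dim = c(5, 4, 3))
  region <- array(0, dim = c(5, 4, 3)); region[2:4, 2:3, 1:2] <- 1
  lesion <- array(0, dim = c(5, 4, 3)); lesion[1, 1, ] <- 1  # outside region
  a <- region_sd(with_data(tmpl, vals), list(r = with_data(tmpl, region)),
                 with_data(tmpl, lesion))
  b <- region_sd(with_data(tmpl, vals), list(r = with_data(tmpl, region)))
  expect_identical(a, b)

  perm <- aperm(vals, c(2, 1, 3))
  aperm_region <- aperm(region, c(2, 1, 3))
  tmpl2 <- const_volume(dim = c(4L, 5L, 3L))
  c_ <- region_sd(with_data(tmpl2, perm),
                  list(r = with_data(tmpl2, aperm_region)))
  expect_equal(unname(a), unname(c_), tolerance = 1e-12)
})

test_that("paired Wilcoxon: degenerate and one-sided extreme cases", {
  res <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_true(res$no_informative_pairs)

  # MD lower in all 10 subjects: W = 0, p = 2/2^10
  sd_vals <- 10 + seq_len(10)
  md_vals <- sd_vals - runif(10, 0.5, 1.5)
  res <- paired_wilcoxon(sd_vals, md_vals)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(res$method, "exact")
})

test_that("exact branch matches brute-force enumeration for n <= 10", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- x + rnorm(n)
    # occasionally force ties in |d| to exercise the midrank path
    if (rep %% 3 == 0) y[2] <- x[2] + (y[1] - x[1])
    res <- paired_wilcoxon(x, y)
    expect_equal(res$p_value, enumerate_signed_rank_p(y - x),
                 tolerance = 1e-12)
  }
})

test_that("exact branch agrees with wilcox.test on tie-free data", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- x + rnorm(n)
    ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
    res <- paired_wilcoxon(x, y)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-n branch uses the continuity-corrected normal approximation", {
  set.seed(404)
  n <- 40
  x <- rnorm(n); y <- x + rnorm(n, 0.3)
  ref <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
  res <- paired_wilcoxon(x, y)
  expect_equal(res$method, "normal")
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})
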