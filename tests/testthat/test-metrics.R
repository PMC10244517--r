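test_that("DSC follows the overlap formula with the documented conventions", {
  a <- array(FALSE, c(4, 4, 2)); b <- a
  expect_identical(dsc(a, b), 100)  # agreement on absence
  a[1:2, 1, 1] <- TRUE
  expect_identical(dsc(a, a), 100)
  b[3:4, 4, 2] <- TRUE
  expect_identical(dsc(a, b), 0)
  b <- array(FALSE, c(4, 4, 2)); b[2:3, 1, 1] <- TRUE
  expect_identical(dsc(a, b), 50)  # |A|=|B|=2, intersection 1
  # symmetry and mirror invariance
  expect_identical(dsc(b, a), dsc(a, b))
  expect_identical(dsc(a[4:1, , ], b[4:1, , ]), dsc(a, b))
  expect_error(dsc(a, array(FALSE, c(4, 4, 3))), "grid")
})

test_that("per-muscle DSC pools both legs and flags absent muscles", {
  pred <- array(0L, c(8, 4, 1)); ref <- pred
  pred[1:2, 1, 1] <- 1L; ref[1:2, 1, 1] <- 1L   # left leg: perfect
  pred[5:6, 1, 1] <- 1L; ref[7:8, 1, 1] <- 1L   # right leg: disjoint, equal size
  p <- label_volume(pred, scheme = muscle_scheme(2))
  r <- label_volume(ref, scheme = muscle_scheme(2))
  expect_identical(per_muscle_dsc(p, r, 1), 50)
  m2 <- per_muscle_dsc(p, r, 2)
  expect_identical(as.numeric(m2), 100)
  expect_true(isTRUE(attr(m2, "absent")))
  expect_error(per_muscle_dsc(p, r, 9), "not in scheme")
})

test_that("generalized DSC pools intersections and sizes over labels", {
  a <- array(0L, c(6, 2, 1)); b <- a
  a[1:2, 1, 1] <- 1L; b[1:2, 1, 1] <- 1L  # muscle 1 perfectly matched (2 voxels)
  a[3:4, 1, 1] <- 2L; b[3:4, 2, 1] <- 2L  # muscle 2 disjoint (2 voxels each)
  expect_identical(generalized_dsc(a, b, ids = 1:2), 50)
  expect_identical(generalized_dsc(a, b, ids = 1), per_muscle_dsc(a, b, 1))
  expect_identical(generalized_dsc(a, a, ids = 1:2), 100)
  expect_error(generalized_dsc(a, b, ids = integer()), "empty")
})

test_that("ASSD is symmetric, zero on identity, and exact on constructed cases", {
  sp <- c(1.2, 1.2, 2.0)
  a <- array(FALSE, c(6, 6, 3)); a[2:4, 2:4, 1:2] <- TRUE
  expect_identical(assd(a, a, sp), 0)
  s1 <- array(FALSE, c(5, 5, 3)); s1[2, 2, 2] <- TRUE
  s2 <- array(FALSE, c(5, 5, 3)); s2[3, 2, 2] <- TRUE
  expect_equal(assd(s1, s2, sp), 1.2, tolerance = 1e-12)
  s3 <- array(FALSE, c(5, 5, 3)); s3[2, 2, 3] <- TRUE
  expect_equal(assd(s1, s3, sp), 2.0, tolerance = 1e-12)
  set.seed(8)
  b <- random_mask(c(6, 6, 3))
  if (sum(b) > 0) expect_identical(assd(a, b, sp), assd(b, a, sp))
  expect_warning(out <- assd(a, array(FALSE, c(6, 6, 3)), sp), "empty")
  expect_true(is.na(out))
})

test_that("metrics reports flag empty muscles and carry the generalized DSC", {
  ph <- tiny_phantom(n_muscles = 3, grid = c(64, 48, 8))
  rep0 <- metrics_report(ph$labels, ph$labels)
  expect_identical(nrow(rep0), 3L)
  expect_true(all(rep0$dsc_pct == 100))
  expect_true(all(rep0$assd_mm == 0))
  expect_identical(attr(rep0, "gdsc_pct"), 100)

  pred <- ph$labels
  pred$values[pred$values == 2L] <- 0L  # drop one muscle entirely
  rep1 <- metrics_report(pred, ph$labels)
  expect_identical(rep1$flag[rep1$muscle_id == 2], "one_empty")
  expect_true(is.na(rep1$assd_mm[rep1$muscle_id == 2]))
  expect_lt(attr(rep1, "gdsc_pct"), 100)
})

test_that("eroding the reference strictly lowers DSC against the uneroded prediction", {
  ph <- tiny_phantom(n_muscles = 3, grid = c(64, 48, 8))
  er <- erode_boundary(ph$labels, 1)
  expect_lt(generalized_dsc(ph$labels, er), 100)
})

test_that("Wilcoxon signed-rank handles the documented cases and matches stats::wilcox.test when tie-free", {
  expect_warning(w0 <- wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_identical(w0$p_value, 1)
  # n = 6, all differences positive and distinct: two-sided p = 2/2^6
  a <- c(10, 20, 30, 40, 50, 60); b <- a - c(1, 2, 3, 4, 5, 6)
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$p_value, 2 / 64, tolerance = 1e-12)
  expect_identical(w$method, "exact")
  # tie-free data: agrees with the standard exact implementation
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large n: normal approximation in (0, 1]
  set.seed(6)
  x <- rnorm(40); y <- x + rnorm(40, 0.2)
  wn <- wilcoxon_signed_rank(x, y)
  expect_identical(wn$method, "normal_tie_corrected")
  expect_true(wn$p_value > 0 && wn$p_value <= 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4)), "at least 5")
})

test_that("Bland-Altman computes bias and 1.96-sd limits in input order", {
  ba <- bland_altman(c(2, 0), c(1, 1))  # differences {1, -1}
  expect_identical(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(unname(ba$loa), c(-1.96 * sqrt(2), 1.96 * sqrt(2)),
               tolerance = 1e-12)
  a <- c(5, 1, 9, 3); b <- c(4, 2, 9, 1)
  bb <- bland_altman(a, b)
  expect_identical(bb$differences, a - b)
  expect_identical(bb$means, (a + b) / 2)
  expect_error(bland_altman(1, 2), "at least 2")
})
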