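test_that("per-muscle FF is the mean over valid voxels, pooled across legs", {
  ph <- tiny_phantom(n_muscles = 3, infiltration = c(0.3, 0.0, 0.9), noise = 0)
  ff <- ff_map_of(ph$dixon)
  expect_equal(muscle_ff(ff, ph$labels, 1), 30, tolerance = 1e-12)
  expect_equal(muscle_ff(ff, ph$labels, 2), 0, tolerance = 1e-12)
  expect_equal(muscle_ff(ff, ph$labels, 3), 90, tolerance = 1e-12)
  # half the voxels at 0%, half at 100% -> 50%
  fat <- array(0, c(4, 4, 2)); fat[1:2, , ] <- 1000
  water <- array(0, c(4, 4, 2)); water[3:4, , ] <- 1000
  lab <- array(1L, c(4, 4, 2))
  ffm <- compute_ff_map(fat, water)
  expect_identical(muscle_ff(ffm, lab, 1), 50)
  # empty muscle: NA with a warning
  expect_warning(na <- muscle_ff(ffm, lab, 2), "no valid voxels")
  expect_true(is.na(na))
})

test_that("overall FF is voxel-weighted, not a mean of per-muscle means", {
  fat <- array(0, c(8, 1, 1)); water <- array(0, c(8, 1, 1))
  lab <- array(0L, c(8, 1, 1))
  # muscle 1: 2 voxels at 10%; muscle 2: 6 voxels at 30%
  fat[1:2, 1, 1] <- 100; water[1:2, 1, 1] <- 900; lab[1:2, 1, 1] <- 1L
  fat[3:8, 1, 1] <- 300; water[3:8, 1, 1] <- 700; lab[3:8, 1, 1] <- 2L
  ff <- compute_ff_map(fat, water)
  expect_equal(overall_ff(ff, lab), 25, tolerance = 1e-12)  # (2*10 + 6*30)/8
  # reduces to muscle_ff with a single muscle
  lab1 <- array(1L, c(8, 1, 1))
  expect_equal(overall_ff(ff, lab1), muscle_ff(ff, lab1, 1))
})

test_that("muscle volume is voxel count times voxel volume", {
  lab <- array(0L, c(20, 10, 5)); lab[seq_len(1000)] <- 1L
  expect_equal(muscle_volume(lab, 1, c(1.2, 1.2, 2.0)), 2.88, tolerance = 1e-12)
  expect_identical(muscle_volume(lab, 2, c(1.2, 1.2, 2.0)), 0)
  expect_identical(muscle_volume(mirror_lr(lab), 1, c(1.2, 1.2, 2.0)),
                   muscle_volume(lab, 1, c(1.2, 1.2, 2.0)))
})

test_that("scan quantification reproduces the phantom design and flags absent muscles", {
  design <- c(0.05, 0.20, 0.40, 0.60)
  ph <- tiny_phantom(n_muscles = 4, infiltration = design, noise = 0)
  rep <- quantify_scan(ph$dixon, ph$labels)
  expect_identical(nrow(rep$per_muscle), 4L)
  expect_equal(rep$per_muscle$ff_pct, 100 * design, tolerance = 1e-12)
  expect_equal(rep$per_muscle$volume_ml,
               ph$truth$per_muscle$volume_ml, tolerance = 1e-12)
  # volume-weighted overall equals the weighted mean of per-muscle values
  wsum <- with(rep$per_muscle, sum(ff_pct * n_voxels) / sum(n_voxels))
  expect_equal(rep$overall_ff_pct, wsum, tolerance = 1e-9)

  labs <- ph$labels
  labs$values[labs$values == 3L] <- 0L
  rep2 <- quantify_scan(ph$dixon, labs)
  expect_identical(rep2$per_muscle$flag[3], "absent")
  expect_identical(rep2$per_muscle$n_voxels[3], 0L)
  expect_true(is.na(rep2$per_muscle$ff_pct[3]))
})

test_that("FF estimates stay unbiased under noise and erosion shrinks volumes", {
  design <- c(0.2, 0.6)
  errs <- replicate(8, {
    ph <- tiny_phantom(n_muscles = 2, infiltration = design, noise = 0.02,
                       seed = sample.int(1e6, 1))
    quantify_scan(ph$dixon, ph$labels)$per_muscle$ff_pct - 100 * design
  })
  expect_lt(max(abs(rowMeans(errs))), 0.5)

  ph <- tiny_phantom(n_muscles = 2, infiltration = design)
  er <- erode_boundary(ph$labels, 1)
  for (m in 1:2)
    expect_lt(muscle_volume(er, m), muscle_volume(ph$labels, m))
})

test_that("FF reports round-trip to CSV with an overall row", {
  dir <- withr::local_tempdir()
  ph <- tiny_phantom(n_muscles = 2, infiltration = c(0.1, 0.5), noise = 0)
  f <- file.path(dir, "ff.csv")
  write_ff_report(quantify_scan(ph$dixon, ph$labels), f)
  df <- read.csv(f)
  expect_identical(nrow(df), 3L)
  expect_identical(df$abbrev[3], "overall")
  expect_equal(df$ff_pct[1:2], c(10, 50), tolerance = 1e-6)
})
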