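test_that("NIfTI round trip preserves values, anisotropic spacing, and label integers", {
  dir <- withr::local_tempdir()
  v <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(1.2, 1.2, 2.0))
  f <- file.path(dir, "v.nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  # channels are stored as 32-bit float
  expect_equal(r$values, v$values, tolerance = 1e-6)
  expect_equal(r$spacing, c(1.2, 1.2, 2.0), tolerance = 1e-6)

  lab <- label_volume(array(sample(0:3, 8 * 8 * 4, TRUE), c(8, 8, 4)),
                      scheme = muscle_scheme(3))
  fl <- file.path(dir, "l.nii.gz")
  write_volume(lab, fl)
  rl <- read_labels(fl, muscle_scheme(3))
  expect_identical(rl$values, lab$values)
})

test_that("reading a 4-D NIfTI fails with a dimensionality error", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "v4.nii")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "4-D")
  expect_error(read_volume(file.path(dir, "missing.nii")), "not found")
})

test_that("FF map implements fat / (fat + water) in percent with a validity mask", {
  mk <- function(x) array(x, c(2, 2, 2))
  expect_equal(compute_ff_map(mk(0), mk(500))$values[1], 0)
  expect_equal(compute_ff_map(mk(500), mk(500))$values[1], 50)
  expect_equal(compute_ff_map(mk(750), mk(250))$values[1], 75)

  fat <- mk(0); fat[1, 1, 1] <- 300
  water <- mk(0); water[1, 1, 1] <- 100
  ff <- compute_ff_map(fat, water)
  expect_identical(sum(ff$valid), 1L)
  expect_equal(ff$values[1, 1, 1], 75)
  expect_true(all(ff$values[!ff$valid] == 0))

  set.seed(1)
  f2 <- mk(runif(8, 0, 10)); w2 <- mk(runif(8, 0, 10))
  v <- compute_ff_map(f2, w2)$values
  expect_true(all(v >= 0 & v <= 100))
  expect_error(compute_ff_map(array(0, c(2, 2, 1)), mk(1)), "mismatch")
})

test_that("in-phase and out-of-phase follow the Dixon identities", {
  w <- array(600, c(2, 2, 1)); f <- array(400, c(2, 2, 1))
  io <- derive_ip_op(w, f)
  expect_equal(io$ip[1], 1000)
  expect_equal(io$op[1], 200)
  io0 <- derive_ip_op(w, array(0, dim(w)))
  expect_identical(io0$ip, w)
  expect_identical(io0$op, w)
  expect_true(all(derive_ip_op(w, w)$op == 0))
})

test_that("stitching blends overlaps with a ramp and is exact for consistent stacks", {
  ph <- tiny_phantom(n_muscles = 2, grid = c(64, 48, 20), noise = 0.05, seed = 3)
  # single stack: identity crop
  cfg1 <- phantom_config(grid_shape = c(64, 48, 20), n_muscles = 2,
                         noise_sigma = 0.05, seed = 3, n_stacks = 1)
  s1 <- acquire_stacks(ph$dixon, cfg1)
  expect_identical(stitch_stacks(s1)$fat, ph$dixon$fat)

  # abutting stacks: pure concatenation
  cfg0 <- phantom_config(grid_shape = c(64, 48, 20), n_muscles = 2,
                         noise_sigma = 0.05, seed = 3, n_stacks = 2,
                         stack_len = 10, stack_overlap = 0)
  expect_identical(stitch_stacks(acquire_stacks(ph$dixon, cfg0))$ip, ph$dixon$ip)

  # overlapping stacks from one volume: bit-equal reconstruction
  cfg2 <- phantom_config(grid_shape = c(64, 48, 20), n_muscles = 2,
                         noise_sigma = 0.05, seed = 3, n_stacks = 2,
                         stack_len = 14, stack_overlap = 8)
  st <- acquire_stacks(ph$dixon, cfg2)
  expect_identical(stitch_stacks(st)$water, ph$dixon$water)
  # overlap values are identical in both stacks (noise applied before split)
  expect_identical(st[[1]]$water[, , 7:14], st[[2]]$water[, , 1:8])

  # gaps are rejected
  gap <- list(st[[1]], dixon_volume(st[[2]]$water, st[[2]]$fat, st[[2]]$ip,
                                    st[[2]]$op, st[[2]]$spacing, z_offset = 15L))
  expect_error(stitch_stacks(gap), "gap")

  # disagreeing overlaps are blended between the two values
  a <- dixon_volume(array(0, c(4, 4, 6)), array(0, c(4, 4, 6)))
  b <- dixon_volume(array(100, c(4, 4, 6)), array(0, c(4, 4, 6)),
                    z_offset = 4L)
  sab <- stitch_stacks(list(a, b))
  ov <- sab$water[1, 1, 5:6]
  expect_true(all(ov > 0 & ov < 100))
  expect_lt(ov[1], ov[2])  # ramp rises toward the later stack's interior
})

test_that("dixon channel files round-trip through the _W/_F/_IP/_OP naming", {
  dir <- withr::local_tempdir()
  ph <- tiny_phantom(n_muscles = 2, grid = c(64, 48, 8), noise = 0.02)
  p <- file.path(dir, "case")
  write_dixon(ph$dixon, p, labels = ph$labels)
  expect_true(all(file.exists(paste0(p, c("_W", "_F", "_IP", "_OP", "_labels"),
                                     ".nii.gz"))))
  r <- read_dixon(p)
  expect_equal(r$op, ph$dixon$op, tolerance = 1e-5)
})
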