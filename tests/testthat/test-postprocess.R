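test_that("component filtering keeps the two largest blobs per muscle", {
  lab <- array(0L, c(20, 10, 4))
  lab[1:5, 1:5, 1:4] <- 1L    # 100 voxels
  lab[8:12, 1:5, 1:2] <- 1L   # 50 voxels (second leg surrogate)
  lab[15:19, 1:2, 1] <- 1L    # 10 voxels: must vanish
  lv <- label_volume(lab, scheme = muscle_scheme(2))
  out <- filter_components(lv)
  expect_identical(sum(out$values == 1L), 150L)
  expect_true(all(out$values[15:19, 1:2, 1] == 0L))
  # a single-component muscle passes through untouched
  lab2 <- array(0L, c(6, 6, 2)); lab2[2:4, 2:4, ] <- 2L
  lv2 <- label_volume(lab2, scheme = muscle_scheme(2))
  expect_identical(filter_components(lv2)$values, lab2)
  # voxel counts never increase
  expect_lte(sum(filter_components(lv)$values > 0), sum(lab > 0))
})

test_that("size ties at rank two resolve to the lower left-right centroid", {
  lab <- array(0L, c(30, 6, 2))
  lab[1:4, 1:4, 1:2] <- 1L     # 32 voxels: largest
  lab[10:12, 1:2, 1] <- 1L     # 6 voxels, centroid x = 11
  lab[20:22, 1:2, 1] <- 1L     # 6 voxels, centroid x = 21
  out <- filter_components(label_volume(lab, scheme = muscle_scheme(1)))
  expect_identical(sum(out$values[10:12, 1:2, 1]), 6L)
  expect_true(all(out$values[20:22, , ] == 0L))
})

test_that("hole filling closes enclosed cavities only", {
  lab <- array(0L, c(9, 9, 9))
  lab[3:7, 3:7, 3:7] <- 3L
  lab[5, 5, 5] <- 0L  # fully enclosed single-voxel cavity
  lv <- label_volume(lab, scheme = muscle_scheme(3))
  out <- fill_holes(lv)
  expect_identical(out$values[5, 5, 5], 3L)
  expect_gte(sum(out$values == 3L), sum(lab == 3L))

  # a cavity opening to the volume border stays background
  lab2 <- array(0L, c(9, 9, 9))
  lab2[3:7, 3:7, 3:9] <- 3L
  lab2[5, 5, 5:9] <- 0L  # channel to the border
  out2 <- fill_holes(label_volume(lab2, scheme = muscle_scheme(3)))
  expect_identical(out2$values[5, 5, 5], 0L)

  # an enclosed cavity bordered by two different muscles is inter-muscle
  # space, not a hole
  lab3 <- array(0L, c(9, 9, 5))
  lab3[3:7, 3:7, 2:4] <- 1L
  lab3[6, 5, 3] <- 2L     # one neighbour of the cavity belongs to muscle 2
  lab3[5, 5, 3] <- 0L     # enclosed cavity
  out3 <- fill_holes(label_volume(lab3, scheme = muscle_scheme(2)))
  expect_identical(out3$values[5, 5, 3], 0L)

  # hole-free maps are untouched; the operation is idempotent
  ph <- tiny_phantom(n_muscles = 3, grid = c(64, 48, 8))
  expect_identical(fill_holes(ph$labels)$values, ph$labels$values)
  once <- fill_holes(lv)
  expect_identical(fill_holes(once)$values, once$values)
})

test_that("boundary erosion is an in-plane cross erosion, shrinking and idempotent in width", {
  lab <- array(0L, c(9, 9, 3))
  lab[3:7, 3:7, ] <- 1L       # 5x5 square on every slice
  lv <- label_volume(lab, scheme = muscle_scheme(1))
  e1 <- erode_boundary(lv, 1)
  expect_identical(sum(e1$values == 1L), 9L * 3L)  # 3x3 per slice
  expect_true(all(e1$values[4:6, 4:6, ] == 1L))
  # thin in-plane structures are erased
  line <- array(0L, c(9, 9, 2)); line[2:8, 5, ] <- 1L
  el <- erode_boundary(label_volume(line, scheme = muscle_scheme(1)), 1)
  expect_identical(sum(el$values), 0L)
  # width 0 is the identity; output is always a subset of the input
  expect_identical(erode_boundary(lv, 0)$values, lab)
  expect_true(all(lab[e1$values == 1L] == 1L))
  # two single-width passes equal one double-width pass
  expect_identical(erode_boundary(e1, 1)$values, erode_boundary(lv, 2)$values)
})

test_that("ground-truth sparsification keeps every k-th slice and copies the nearest one elsewhere", {
  set.seed(12)
  Z <- 12L
  lab <- array(sample(0:2, 8 * 8 * Z, TRUE), c(8, 8, Z))
  lv <- label_volume(lab, scheme = muscle_scheme(2))
  expect_identical(sparsify_gt(lv, 1)$values, lab)

  s5 <- sparsify_gt(lv, 5)$values
  # kept slices (0-based 0, 5, 10) are bit-identical
  for (z in c(1, 6, 11)) expect_identical(s5[, , z], lab[, , z])
  # 0-based slice 7 copies slice 5; slice 8 copies slice 10
  expect_identical(s5[, , 8], lab[, , 6])
  expect_identical(s5[, , 9], lab[, , 11])

  # equidistant ties resolve toward the inferior slice: 0-based slice 5 -> 0
  s10 <- sparsify_gt(lv, 10)$values
  expect_identical(s10[, , 6], lab[, , 1])
  expect_warning(sparsify_gt(lv, 20), "only slice 0")
})

test_that("sparsified phantom ground truth stays close to the dense version", {
  ph <- tiny_phantom(n_muscles = 4, grid = c(64, 64, 20))
  s5 <- sparsify_gt(ph$labels, 5)
  disagree <- mean(s5$values[ph$labels$values > 0] !=
                     ph$labels$values[ph$labels$values > 0])
  expect_lt(disagree, 0.10)
  expect_gt(generalized_dsc(s5, ph$labels), 90)
})
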