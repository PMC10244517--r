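test_that("noise-free phantom realizes the designed signal model exactly", {
  # zero infiltration: no fat signal anywhere inside muscle
  ph0 <- tiny_phantom(n_muscles = 3, infiltration = 0, noise = 0)
  muscle <- ph0$labels$values > 0
  expect_true(all(ph0$dixon$fat[muscle] == 0))
  expect_true(all(ph0$dixon$water[muscle] == 1000))

  # per-voxel FF equals the designed value exactly
  ph <- tiny_phantom(n_muscles = 3, infiltration = c(0.4, 0.1, 0.7), noise = 0)
  ff <- ff_map_of(ph$dixon)
  for (m in 1:3) {
    sel <- ph$labels$values == m
    expect_equal(unique(ff$values[sel]), ph$truth$per_muscle$designed_ff_pct[m],
                 tolerance = 1e-12)
  }
  expect_equal(ph$truth$per_muscle$designed_ff_pct, c(40, 10, 70))
})

test_that("phantom generation is deterministic and mirror-symmetric", {
  a <- tiny_phantom(n_muscles = 4, infiltration = 0.2, noise = 0.03, seed = 11)
  b <- tiny_phantom(n_muscles = 4, infiltration = 0.2, noise = 0.03, seed = 11)
  expect_identical(a$dixon$water, b$dixon$water)
  expect_identical(a$labels$values, b$labels$values)

  # labels are mirror-symmetric about the mid-sagittal plane
  lab <- a$labels$values
  expect_identical(lab, lab[dim(lab)[1]:1, , ])

  # noise-free geometry: exactly two 26-connected components per muscle
  nf <- tiny_phantom(n_muscles = 4, infiltration = 0, noise = 0)
  for (m in 1:4) {
    comp <- cpp_label_components(as.integer(nf$labels$values == m),
                                 dim(nf$labels$values), 26L)
    expect_identical(max(comp), 2L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(grid_shape = c(40, 64, 8)), "32 in-plane")
  expect_error(phantom_config(grid_shape = c(63, 64, 8)), "even")
  expect_error(phantom_config(infiltration = 1.2), "\\[0, 1\\]")
  expect_error(phantom_config(n_muscles = 19), "1..18")
  expect_error(phantom_config(n_stacks = 2, stack_len = 10, stack_overlap = 12),
               "overlap")
  expect_error(phantom_config(grid_shape = c(64, 64, 48), n_stacks = 2,
                              stack_len = 20, stack_overlap = 5),
               "cover")
})

test_that("stack acquisition covers the volume with the documented offsets", {
  cfg <- phantom_config(grid_shape = c(64, 64, 140), n_muscles = 2,
                        noise_sigma = 0, n_stacks = 2, stack_len = 80,
                        stack_overlap = 20)
  ph <- generate_phantom(cfg)
  st <- acquire_stacks(ph$dixon, cfg)
  expect_identical(vapply(st, function(s) s$z_offset, 0L), c(0L, 60L))
  covered <- sort(unique(unlist(lapply(st, function(s)
    s$z_offset + seq_len(dim(s$water)[3])))))
  expect_identical(covered, 1:140)
})

test_that("cohorts draw per-muscle infiltration in range with distinct anatomy", {
  base <- phantom_config(grid_shape = c(64, 64, 12), n_muscles = 3,
                         noise_sigma = 0)
  expect_identical(make_cohort(0, c(0, 0.2), base), list())
  co <- make_cohort(3, c(0, 0.17), base, seed = 5)
  for (su in co)
    expect_true(all(su$truth$per_muscle$designed_ff_pct <= 17))
  # subject-level shape jitter: distinct label maps
  expect_false(identical(co[[1]]$labels$values, co[[2]]$labels$values))
  # reproducible
  co2 <- make_cohort(3, c(0, 0.17), base, seed = 5)
  expect_identical(co[[2]]$dixon$water, co2[[2]]$dixon$water)
})

test_that("phantom subjects write channels, labels and a truth table", {
  dir <- withr::local_tempdir()
  ph <- tiny_phantom(n_muscles = 2, grid = c(64, 48, 8))
  write_phantom(ph, dir, "s01")
  truth <- read.csv(file.path(dir, "s01_truth.csv"))
  expect_identical(nrow(truth), 2L)
  expect_true(all(c("muscle_id", "abbrev", "designed_ff_pct", "volume_ml")
                  %in% names(truth)))
})
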