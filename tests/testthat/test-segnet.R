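# expected parameter count from the architecture definition: two convs per
# encoder/decoder level, a stride-2 down conv per level, four deepest convs,
# an up conv per level, and the final classifier; each normalized conv has
# 27*cin*cout weights + 2*cout norm parameters, the final conv adds a bias
expected_n_params <- function(depth, base, growth, in_ch, K) {
  ch <- base * growth^(0:(depth - 1))
  n <- 0
  conv <- function(ci, co, norm = TRUE) 27 * ci * co + if (norm) 2 * co else co
  for (l in seq_len(depth - 1)) {
    cin <- if (l == 1) in_ch else ch[l - 1]
    n <- n + conv(cin, ch[l]) + conv(ch[l], ch[l]) +  # encoder level
      conv(ch[l], ch[l]) +                            # down-sampling conv
      conv(ch[l + 1], ch[l]) +                        # up conv
      conv(2 * ch[l], ch[l]) + conv(ch[l], ch[l])     # decoder level
  }
  n <- n + conv(ch[depth - 1], ch[depth]) + 3 * conv(ch[depth], ch[depth])
  n + conv(ch[1], K, norm = FALSE)
}

test_that("the network matches its architectural parameter-count formula and quadruples when filters double", {
  for (cfg in list(c(2, 4, 2, 2, 3), c(3, 8, 2, 2, 7), c(3, 8, 1, 2, 7))) {
    m <- dixon_unet(seg_model_spec(depth = cfg[1], base_filters = cfg[2],
                                   growth = cfg[3], in_channels = cfg[4],
                                   n_classes = cfg[5]))
    expect_identical(n_params(m),
                     expected_n_params(cfg[1], cfg[2], cfg[3], cfg[4], cfg[5]))
  }
  n1 <- n_params(dixon_unet(seg_model_spec(2, 8, n_classes = 3)))
  n2 <- n_params(dixon_unet(seg_model_spec(2, 16, n_classes = 3)))
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.1)
})

test_that("forward pass yields voxel-wise probability simplexes, reproducibly under seed", {
  spec <- seg_model_spec(depth = 2, base_filters = 4, n_classes = 3)
  m1 <- dixon_unet(spec, seed = 7)
  m2 <- dixon_unet(spec, seed = 7)
  expect_identical(model_weights(m1), model_weights(m2))
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  pv <- predict_volume(m1, x, patch_slices = 4)
  sums <- rowSums(matrix(pv$probs, ncol = 3))
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_identical(pv$probs, predict_volume(m2, x, patch_slices = 4)$probs)
  # shape not divisible by 2^(depth-1) along pooled axes
  expect_error(predict_volume(m1, array(0, c(7, 8, 4, 2)), patch_slices = 4),
               "divisible")
})

test_that("the direct convolution kernel agrees with im2col+GEMM and with a triple-loop reference", {
  set.seed(31)
  dims <- c(7L, 6L, 5L)
  for (cc in list(c(2, 8), c(3, 5), c(4, 16))) {
    cin <- cc[1]; cout <- cc[2]
    x <- array(rnorm(prod(dims) * cin), c(dims, cin))
    w <- array(rnorm(27 * cin * cout), c(3, 3, 3, cin, cout))
    ref <- conv3d_ref(x, w, stride = 1)
    fast <- cpp_conv3d(as.numeric(x), dims, as.numeric(w), cin, cout, 1L, TRUE)
    gemm <- cpp_conv3d(as.numeric(x), dims, as.numeric(w), cin, cout, 1L, FALSE)
    expect_equal(array(fast, dim(ref)), ref, tolerance = 1e-5)
    expect_equal(as.numeric(fast), as.numeric(gemm), tolerance = 1e-5)
    # stride-2 path (im2col) against the reference
    ref2 <- conv3d_ref(x, w, stride = 2)
    gemm2 <- cpp_conv3d(as.numeric(x), dims, as.numeric(w), cin, cout, 2L, FALSE)
    expect_equal(array(gemm2, dim(ref2)), ref2, tolerance = 1e-5)
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  m <- dixon_unet(seg_model_spec(depth = 2, base_filters = 4, n_classes = 3),
                  seed = 42)
  p <- model_weights(m)
  dims <- c(8L, 8L, 8L)
  n <- prod(dims)
  x <- rnorm(n * 2)
  lab <- sample(0:2, n, TRUE)
  gr <- unet_gradients(m$ptr, x, dims, lab)
  set.seed(7)
  errs <- c()
  for (nm in sample(names(p), 8)) {
    ii <- sample(length(p[[nm]]), 1)
    eps <- 2e-3
    p2 <- p; p2[[nm]][ii] <- p[[nm]][ii] + eps
    set_model_weights(m, p2)
    lp <- unet_eval_loss(m$ptr, x, dims, lab)
    p2[[nm]][ii] <- p[[nm]][ii] - eps
    set_model_weights(m, p2)
    lm <- unet_eval_loss(m$ptr, x, dims, lab)
    fd <- (lp - lm) / (2 * eps)
    g <- gr[[nm]][ii]
    errs <- c(errs, abs(fd - g) / max(abs(fd), abs(g), 1e-3))
  }
  # float32 loss limits finite-difference precision; gradients must agree to
  # within a few percent for most probes and never be wildly off
  expect_lt(median(errs), 0.05)
  expect_lt(max(errs), 0.5)
})

test_that("subject-grouped folds partition subjects and keep scans together", {
  f <- make_folds(1:10, k = 5, seed = 3)
  expect_identical(sort(unlist(f$folds)), 1:10)
  expect_true(all(lengths(f$folds) == 2))
  tab <- data.frame(subject_id = rep(1:4, times = c(3, 2, 1, 2)),
                    scan_id = paste0("s", 1:8))
  f2 <- make_folds(tab, k = 2, seed = 1)
  for (i in 1:2) {
    subj_of_scans <- tab$subject_id[tab$scan_id %in% f2$scans[[i]]]
    expect_true(all(subj_of_scans %in% f2$folds[[i]]))
  }
  expect_identical(sort(unlist(f2$scans)), sort(tab$scan_id))
  expect_error(make_folds(1:4, k = 1), "2 folds")
  expect_error(make_folds(1:4, k = 5), "more folds")
})

test_that("learning-rate plateau policy is a pure function of the loss sequence", {
  # strictly improving: rate untouched
  s <- lr_schedule(exp(-seq_len(30)), lr0 = 1e-4, patience = 25)
  expect_true(all(s$lr == 1e-4))
  # two plateaus: two halvings
  s2 <- lr_schedule(c(1, rep(1, 25), 0.5, rep(0.5, 25)), patience = 25)
  expect_identical(s2$lr[length(s2$lr)], 2.5e-5)
  # identical input, identical output
  expect_identical(lr_schedule(rep(1, 30)), lr_schedule(rep(1, 30)))
  # improvements below tolerance do not reset the plateau counter
  s3 <- lr_schedule(1 - seq_len(26) * 1e-9, patience = 25, tol = 1e-6)
  expect_identical(s3$lr[26], 5e-5)
})

test_that("training descends on an easy phantom and tracks history, fine-tuning with 0 epochs is the identity", {
  ph1 <- tiny_phantom(n_muscles = 2, infiltration = c(0.1, 0.6),
                      grid = c(64, 48, 12), noise = 0.02, seed = 1)
  ph2 <- tiny_phantom(n_muscles = 2, infiltration = c(0.2, 0.5),
                      grid = c(64, 48, 12), noise = 0.02, seed = 2)
  m <- dixon_unet(seg_model_spec(depth = 2, base_filters = 4, n_classes = 3),
                  seed = 1)
  cfg <- train_config(max_epochs = 20, lr0 = 1e-3, patch_slices = 8, seed = 1)
  m <- train_unet(m, leg_scans(ph1$dixon, ph1$labels),
                  leg_scans(ph2$dixon, ph2$labels), cfg)
  h <- m$history
  expect_identical(nrow(h), 20L)
  expect_lt(h$train_loss[20], h$train_loss[1])
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in% names(h)))

  ft0 <- finetune_unet(m, leg_scans(ph1$dixon, ph1$labels),
                       leg_scans(ph2$dixon, ph2$labels),
                       train_config(max_epochs = 0, patch_slices = 8))
  expect_identical(model_weights(ft0), model_weights(m))
  expect_identical(ft0$provenance$parent, m$label)

  expect_error(train_unet(m, list(), leg_scans(ph2$dixon, ph2$labels), cfg),
               "empty training")
})

test_that("patch-wise prediction covers every slice and averages overlapping patch probabilities", {
  m <- dixon_unet(seg_model_spec(depth = 2, base_filters = 4, n_classes = 3),
                  seed = 5)
  x <- array(rnorm(8 * 8 * 12 * 2), c(8, 8, 12, 2))
  # single patch spanning the volume: output is the plain forward pass
  pv <- predict_volume(m, x, patch_slices = 12)
  direct <- unet_predict(m$ptr, as.numeric(x), c(8L, 8L, 12L))
  expect_equal(as.numeric(pv$probs), as.numeric(direct), tolerance = 1e-6)
  expect_true(all(pv$coverage == 1))

  # two half-overlapping patches: coverage-weighted mean, renormalized
  pv2 <- predict_volume(m, x, patch_slices = 8, overlap = 0.5)
  expect_true(all(pv2$coverage >= 1))
  p1 <- array(unet_predict(m$ptr, as.numeric(x[, , 1:8, ]), c(8L, 8L, 8L)),
              c(8, 8, 8, 3))
  p2 <- array(unet_predict(m$ptr, as.numeric(x[, , 5:12, ]), c(8L, 8L, 8L)),
              c(8, 8, 8, 3))
  mixed <- (p1[, , 5:8, ] + p2[, , 1:4, ]) / 2
  mixed <- mixed / array(rep(apply(mixed, 1:3, sum), 3), dim(mixed))
  expect_equal(pv2$probs[, , 5:8, ], mixed, tolerance = 1e-6)

  # random policy reaches full coverage
  set.seed(2)
  pvr <- predict_volume(m, x, patch_slices = 8, policy = "random")
  expect_true(all(pvr$coverage >= 1))
})

test_that("majority voting follows counts, then mean probability, then lowest id", {
  base <- array(0L, c(2, 2, 1))
  mk <- function(v) { a <- base; a[1, 1, 1] <- as.integer(v); a }
  # unanimity
  expect_identical(ensemble_vote(list(mk(2), mk(2), mk(2))), mk(2))
  # clear majority 3 vs 2
  fused <- ensemble_vote(list(mk(3), mk(3), mk(3), mk(7), mk(7)))
  expect_identical(fused[1, 1, 1], 3L)
  # 2-2-1 tie broken by the higher mean probability
  labs <- list(mk(1), mk(1), mk(2), mk(2), mk(3))
  pr <- function(p1, p2, p3) {
    a <- array(0, c(2, 2, 1, 4))
    a[, , , 1] <- 1  # background elsewhere
    a[1, 1, 1, ] <- c(0, p1, p2, p3)
    a
  }
  probs <- list(pr(.40, .45, .15), pr(.40, .45, .15), pr(.40, .45, .15),
                pr(.40, .45, .15), pr(.40, .45, .15))
  fused2 <- ensemble_vote(labs, probs)
  expect_identical(fused2[1, 1, 1], 2L)
  # without probabilities the tie resolves to the lowest id
  expect_identical(ensemble_vote(labs[1:4])[1, 1, 1], 1L)
})

test_that("whole-subject segmentation is mirror-equivariant on symmetric input and preserves the grid", {
  ph <- tiny_phantom(n_muscles = 3, infiltration = c(0.1, 0.4, 0.7),
                     grid = c(64, 48, 8), noise = 0)
  m <- dixon_unet(seg_model_spec(depth = 2, base_filters = 4, n_classes = 4),
                  seed = 9)
  pred <- segment_subject(m, ph$dixon, patch_slices = 8)
  expect_identical(dim(pred$values), dim(ph$dixon$water))
  # symmetric input -> left prediction is the mirror of the right prediction
  expect_identical(pred$values, pred$values[dim(pred$values)[1]:1, , ])
  # argmax ties resolve to the lowest class id
  tied <- array(1 / 3, c(2, 2, 1, 3))
  expect_true(all(argmax_labels(tied) == 0L))
})

test_that("model checkpoints round-trip through save/load", {
  dir <- withr::local_tempdir()
  m <- dixon_unet(seg_model_spec(depth = 2, base_filters = 4, n_classes = 3),
                  seed = 3, label = "demo")
  f <- file.path(dir, "m.rds")
  save_model(m, f)
  r <- load_model(f)
  expect_identical(model_weights(r), model_weights(m))
  expect_identical(r$spec, m$spec)
  expect_identical(r$label, "demo")
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  expect_identical(predict_volume(r, x, 4)$probs, predict_volume(m, x, 4)$probs)
})
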