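#' Synthetic Dixon leg phantoms
#'
#' The phantom emulates an axial Dixon acquisition of both proximal legs: two
#' mirror-symmetric legs, each built from an elliptical subcutaneous fat rind,
#' a central femur with fatty marrow, and a ring of muscle compartments laid
#' out as angular wedges around the femur. Every muscle carries a designed
#' fat-infiltration fraction in [0, 1]: inside muscle m the water channel is
#' (1 - infiltration) * S and the fat channel infiltration * S, so the
#' designed per-muscle FF\% is known exactly and the whole downstream pipeline
#' can be scored against ground truth without clinical data. Geometry tapers
#' linearly along the slice direction so muscles have genuine 3-D shape.
#'
#' The phantom does not model MR physics (relaxation, field inhomogeneity,
#' multi-echo reconstruction) or partial-volume effects; its purpose is a
#' controlled test bed, not image realism.
#'
#' @name phantom
NULL

PHANTOM_SIGNAL <- 1000  # arbitrary units; scans carry no absolute scale

#' Phantom configuration
#'
#' @param grid_shape voxels (X, Y, Z); X even. Desk scale is 96 x 96 x 48;
#'   the clinical grid 384 x 384 x 140 works behind the same interface.
#' @param spacing voxel size in mm
#' @param n_muscles muscle compartments per leg (1-18)
#' @param infiltration per-muscle fat infiltration fraction in [0, 1];
#'   recycled to length \code{n_muscles}
#' @param noise_sigma additive Gaussian noise, as a fraction of the full
#'   signal amplitude S = 1000
#' @param n_stacks number of partially overlapping axial stacks (1-3)
#' @param stack_len slices per stack (default: full Z for one stack, else a
#'   length giving roughly even coverage)
#' @param stack_overlap overlapping slices between consecutive stacks
#' @param seed RNG seed for noise
#' @param shape_jitter optional list perturbing leg geometry (used by
#'   \code{\link{make_cohort}}): \code{axes} scale factors, \code{center}
#'   voxel shifts, \code{taper}, \code{rot} wedge rotation in radians
#' @return object of class \code{phantom_config}
#' @export
phantom_config <- function(grid_shape = c(96, 96, 48),
                           spacing = c(1.2, 1.2, 2.0),
                           n_muscles = 6,
                           infiltration = 0,
                           noise_sigma = 0.02,
                           n_stacks = 1,
                           stack_len = NULL,
                           stack_overlap = 0,
                           seed = 1,
                           shape_jitter = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0))
  if (grid_shape[1] %% 2 != 0) stop("X extent must be even (mid-sagittal split)")
  if (grid_shape[1] / 2 < 32 || grid_shape[2] < 32)
    stop("grid too small to host the leg geometry: need >= 32 in-plane voxels per leg")
  if (n_muscles < 1 || n_muscles > 18) stop("n_muscles must be in 1..18")
  infiltration <- rep_len(as.numeric(infiltration), n_muscles)
  if (any(infiltration < 0 | infiltration > 1))
    stop("infiltration fractions must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!n_stacks %in% 1:3) stop("n_stacks must be 1, 2, or 3")
  Z <- grid_shape[3]
  if (is.null(stack_len))
    stack_len <- if (n_stacks == 1) Z
    else ceiling((Z + (n_stacks - 1) * stack_overlap) / n_stacks)
  if (stack_overlap >= stack_len) stop("stack_overlap must be < stack_len")
  if (n_stacks * stack_len - (n_stacks - 1) * stack_overlap < Z)
    stop("stack layout does not cover the volume: ",
         n_stacks, " x ", stack_len, " slices with overlap ", stack_overlap)
  jit <- list(axes = c(1, 1), center = c(0, 0), taper = 0.25, rot = 0)
  if (!is.null(shape_jitter)) jit[names(shape_jitter)] <- shape_jitter
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 n_muscles = as.integer(n_muscles), infiltration = infiltration,
                 noise_sigma = noise_sigma, n_stacks = as.integer(n_stacks),
                 stack_len = as.integer(stack_len),
                 stack_overlap = as.integer(stack_overlap),
                 seed = as.integer(seed), shape_jitter = jit),
            class = "phantom_config")
}

# label map of one half (columns 1..X/2), built analytically; returns an
# integer array (X/2, Y, Z) with 0 background, ids 1..M muscles, -1 fat rind
# or inter-muscular fat, -2 femur marrow
phantom_half_geometry <- function(config) {
  X2 <- config$grid_shape[1] / 2
  Y <- config$grid_shape[2]
  Z <- config$grid_shape[3]
  M <- config$n_muscles
  jit <- config$shape_jitter
  cx <- X2 / 2 + 0.5 + jit$center[1]
  cy <- Y / 2 + 0.5 + jit$center[2]
  a0 <- 0.42 * X2 * jit$axes[1]   # leg ellipse semi-axes, voxels
  b0 <- 0.44 * Y * jit$axes[2]
  rind <- 0.82                    # muscle region scale relative to the leg
  rf <- 0.18 * min(a0, b0)        # femur radius
  # mild deterministic per-muscle radial modulation (elliptical deformation)
  rmod <- 0.90 + 0.10 * (seq_len(M) %% 3) / 2
  xs <- (seq_len(X2) - cx)
  ys <- (seq_len(Y) - cy)
  ex <- matrix(rep(xs, Y), X2)               # x offsets per in-plane voxel
  ey <- matrix(rep(ys, each = X2), X2)
  theta <- (atan2(ey, ex) - jit$rot) %% (2 * pi)
  wedge <- pmin(M, floor(theta / (2 * pi / M)) + 1L)  # 1..M
  lab <- array(0L, c(X2, Y, Z))
  for (z in seq_len(Z)) {
    sc <- 1 - jit$taper * (z - 1) / max(1, Z - 1)
    az <- a0 * sc
    bz <- b0 * sc
    rleg2 <- (ex / az)^2 + (ey / bz)^2
    rfem2 <- (ex^2 + ey^2) / (rf * sc)^2
    rr <- sqrt(rleg2) / rind                 # 1 at muscle-region boundary
    sl <- matrix(0L, X2, Y)
    sl[rleg2 <= 1] <- -1L                    # leg tissue: default fat
    inner <- rr <= 1 & rfem2 > 1
    keep <- inner & rr <= rmod[wedge]        # inside this muscle's boundary
    sl[keep] <- wedge[keep]
    sl[rfem2 <= 1] <- -2L                    # femur marrow
    lab[, , z] <- sl
  }
  lab
}

#' Generate a synthetic two-leg Dixon phantom
#'
#' @param config \code{phantom_config}
#' @return list with elements \code{dixon} (a \code{\link{dixon_volume}}),
#'   \code{labels} (a \code{\link{label_volume}}, 0 = background), and
#'   \code{truth} (designed per-muscle FF\% and true volumes in ml)
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(grid_shape = c(64, 64, 16),
#'                                       n_muscles = 4, noise_sigma = 0))
#' ph$truth$per_muscle
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  X <- config$grid_shape[1]; Y <- config$grid_shape[2]; Z <- config$grid_shape[3]
  M <- config$n_muscles
  S <- PHANTOM_SIGNAL
  half <- phantom_half_geometry(config)
  X2 <- X / 2
  geo <- array(0L, c(X, Y, Z))
  geo[1:X2, , ] <- half
  geo[X:(X2 + 1), , ] <- half                 # mirror about the mid-sagittal plane
  water <- array(0, c(X, Y, Z))
  fat <- array(0, c(X, Y, Z))
  fat[geo < 0] <- S                           # rind, inter-muscular fat, marrow
  for (m in seq_len(M)) {
    vox <- geo == m
    water[vox] <- (1 - config$infiltration[m]) * S
    fat[vox] <- config$infiltration[m] * S
  }
  if (config$noise_sigma > 0) {
    n <- length(water)
    with_seed(config$seed, {
      water <- water + rnorm(n, 0, config$noise_sigma * S)
      fat <- fat + rnorm(n, 0, config$noise_sigma * S)
    })
    water[water < 0] <- 0
    fat[fat < 0] <- 0
    dim(water) <- dim(fat) <- c(X, Y, Z)
  }
  io <- derive_ip_op(water, fat)
  dixon <- dixon_volume(water, fat, io$ip, io$op, config$spacing)
  lab <- geo
  lab[lab < 0] <- 0L
  scheme <- muscle_scheme(M)
  labels <- label_volume(lab, config$spacing, scheme)
  vox_ml <- prod(config$spacing) / 1000
  counts <- vapply(seq_len(M), function(m) sum(lab == m), 0)
  truth <- structure(list(
    per_muscle = data.frame(
      muscle_id = seq_len(M), abbrev = scheme$abbrev,
      muscle_name = scheme$name,
      designed_ff_pct = 100 * config$infiltration,
      volume_ml = counts * vox_ml, n_voxels = as.integer(counts),
      stringsAsFactors = FALSE),
    infiltration = config$infiltration,
    config = config), class = "phantom_truth")
  list(dixon = dixon, labels = labels, truth = truth)
}

#' Split a phantom volume into overlapping acquisition stacks
#'
#' Emulates acquiring the leg as 1-3 identical, partially overlapping axial
#' stacks: consecutive stacks start \code{stack_len - stack_overlap} slices
#' apart, and the last stack is shifted so the union of slice ranges covers
#' the full volume. Noise is part of the source volume, so overlapping slices
#' are identical across stacks.
#'
#' @param dixon \code{dixon_volume}
#' @param config \code{phantom_config} (provides the stack layout)
#' @return list of \code{dixon_volume}s, each with its \code{z_offset}
#' @export
acquire_stacks <- function(dixon, config) {
  stopifnot(inherits(dixon, "dixon_volume"), inherits(config, "phantom_config"))
  Z <- dim(dixon$water)[3]
  len <- config$stack_len
  if (config$stack_overlap >= len) stop("stack_overlap must be < stack_len")
  step <- len - config$stack_overlap
  offsets <- (seq_len(config$n_stacks) - 1) * step
  offsets[length(offsets)] <- min(offsets[length(offsets)], Z - len)
  offsets <- pmin(offsets, Z - len)
  if (max(offsets) + len < Z) stop("stack layout does not cover the volume")
  lapply(offsets, function(o) {
    zr <- (o + 1):(o + len)
    dixon_volume(dixon$water[, , zr, drop = FALSE], dixon$fat[, , zr, drop = FALSE],
                 dixon$ip[, , zr, drop = FALSE], dixon$op[, , zr, drop = FALSE],
                 dixon$spacing, z_offset = o)
  })
}

#' Simulate a cohort of phantom subjects
#'
#' Each subject draws its per-muscle infiltration uniformly from
#' \code{infiltration_range} and receives subject-specific shape jitter
#' (ellipse axes, leg position, taper, wedge rotation), so subjects differ
#' both in pathology and anatomy. Fully reproducible under \code{seed}.
#'
#' @param n_subjects number of subjects (0 gives an empty list)
#' @param infiltration_range c(lo, hi), 0 <= lo <= hi <= 1
#' @param base_config \code{phantom_config} template
#' @param seed cohort-level seed; subject i derives seed * 1000 + i
#' @return list of subjects, each as returned by \code{\link{generate_phantom}}
#'   plus a \code{subject_id}
#' @export
make_cohort <- function(n_subjects, infiltration_range, base_config, seed = 1) {
  stopifnot(n_subjects >= 0)
  lo <- infiltration_range[1]; hi <- infiltration_range[2]
  if (!(lo >= 0 && lo <= hi && hi <= 1))
    stop("infiltration_range must satisfy 0 <= lo <= hi <= 1")
  if (n_subjects == 0) return(list())
  lapply(seq_len(n_subjects), function(i) {
    # keep derived seeds within integer range for any caller-supplied seed
    sseed <- as.integer((abs(seed) %% 2000000) * 1000 + i)
    cfg <- with_seed(sseed, {
      infil <- runif(base_config$n_muscles, lo, hi)
      jit <- list(axes = runif(2, 0.92, 1.08),
                  center = runif(2, -2.5, 2.5),
                  taper = runif(1, 0.18, 0.30),
                  rot = runif(1, -0.15, 0.15))
      phantom_config(grid_shape = base_config$grid_shape,
                     spacing = base_config$spacing,
                     n_muscles = base_config$n_muscles,
                     infiltration = infil,
                     noise_sigma = base_config$noise_sigma,
                     n_stacks = base_config$n_stacks,
                     stack_len = base_config$stack_len,
                     stack_overlap = base_config$stack_overlap,
                     seed = sseed, shape_jitter = jit)
    })
    ph <- generate_phantom(cfg)
    ph$subject_id <- i
    ph
  })
}

#' Write a phantom subject to disk
#'
#' Writes the Dixon channels and label map as NIfTI plus the design truth as
#' CSV (\code{muscle_id, abbrev, designed_ff_pct, volume_ml, n_voxels}).
#'
#' @param phantom output of \code{\link{generate_phantom}}
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @return paths written, invisibly
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, prefix)
  paths <- write_dixon(phantom$dixon, base, labels = phantom$labels)
  csv <- paste0(base, "_truth.csv")
  write.csv(phantom$truth$per_muscle, csv, row.names = FALSE)
  invisible(c(paths, truth = csv))
}
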