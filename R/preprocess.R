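#' Mid-sagittal splitting, mirroring, patch sampling, and augmentation
#'
#' The segmentation network sees single-leg images only: full volumes are
#' split into two equal halves along the mid-sagittal plane, and the second
#' (left-leg) half is mirrored so both legs share one appearance. Training
#' samples are slabs of consecutive axial slices cut at a uniformly random
#' inferior-superior position; optional augmentation applies one shared
#' in-plane affine to channels (linear interpolation) and labels (nearest
#' neighbour) plus Gaussian intensity noise on channels only.
#'
#' @name preprocess
NULL

# reverse a 3-D array along the left-right axis
mirror_array <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

#' Split a volume along the mid-sagittal plane
#'
#' @param x a 3-D array, \code{dixon_volume}, or \code{label_volume} with an
#'   even left-right extent
#' @return list with elements \code{right} (columns 1..X/2) and \code{left}
#'   (columns X/2+1..X) of the same type as the input; concatenating
#'   \code{right} then \code{left} along the first axis restores the input
#' @export
split_midsagittal <- function(x) {
  if (inherits(x, "dixon_volume")) {
    X <- dim(x$water)[1]
    if (X %% 2 != 0) stop("left-right extent must be even, got ", X)
    h <- function(idx) dixon_volume(x$water[idx, , , drop = FALSE],
                                    x$fat[idx, , , drop = FALSE],
                                    x$ip[idx, , , drop = FALSE],
                                    x$op[idx, , , drop = FALSE], x$spacing)
    return(list(right = h(1:(X / 2)), left = h((X / 2 + 1):X)))
  }
  if (inherits(x, "label_volume")) {
    X <- dim(x$values)[1]
    if (X %% 2 != 0) stop("left-right extent must be even, got ", X)
    return(list(
      right = label_volume(x$values[1:(X / 2), , , drop = FALSE], x$spacing, x$scheme),
      left = label_volume(x$values[(X / 2 + 1):X, , , drop = FALSE], x$spacing, x$scheme)))
  }
  X <- dim(x)[1]
  if (is.null(X) || length(dim(x)) != 3) stop("expected a 3-D volume")
  if (X %% 2 != 0) stop("left-right extent must be even, got ", X)
  list(right = x[1:(X / 2), , , drop = FALSE],
       left = x[(X / 2 + 1):X, , , drop = FALSE])
}

#' Mirror a volume left-right
#'
#' Reverses the first (left-right) axis. Label ids are unchanged: the scheme
#' has no left/right distinction, so a mirrored left leg is directly
#' comparable to a right leg. Mirroring is an involution.
#'
#' @param x 3-D array, \code{dixon_volume}, or \code{label_volume}
#' @return the mirrored object, same type
#' @export
mirror_lr <- function(x) {
  if (inherits(x, "dixon_volume"))
    return(dixon_volume(mirror_array(x$water), mirror_array(x$fat),
                        mirror_array(x$ip), mirror_array(x$op),
                        x$spacing, x$z_offset))
  if (inherits(x, "label_volume"))
    return(label_volume(mirror_array(x$values), x$spacing, x$scheme))
  if (length(dim(x)) != 3) stop("expected a 3-D volume")
  mirror_array(x)
}

#' Assemble the 2-channel network input of a single-leg volume
#'
#' @param dixon single-leg \code{dixon_volume}
#' @return 4-D array (X, Y, Z, 2) with channel 1 = out-of-phase and
#'   channel 2 = in-phase
#' @export
leg_channels <- function(dixon) {
  stopifnot(inherits(dixon, "dixon_volume"))
  d <- dim(dixon$op)
  out <- array(0, c(d, 2))
  out[, , , 1] <- dixon$op
  out[, , , 2] <- dixon$ip
  out
}

#' Sample a random axial slab patch
#'
#' Cuts \code{patch_slices} consecutive slices at a start position drawn
#' uniformly from all valid positions, from the channels and (identically)
#' from the paired labels. Volumes shorter than the patch are an error; no
#' padding is applied.
#'
#' @param channels 4-D array (X, Y, Z, C) as from \code{\link{leg_channels}}
#' @param labels 3-D integer array (X, Y, Z) or NULL
#' @param patch_slices slab thickness S
#' @return list with \code{x} (X, Y, S, C), \code{labels} (X, Y, S) or NULL,
#'   and the 0-based start slice \code{z0}
#' @export
sample_patch <- function(channels, labels, patch_slices) {
  d <- dim(channels)
  Z <- d[3]
  if (patch_slices > Z)
    stop("volume has ", Z, " slices but the patch needs ", patch_slices,
         "; no padding is applied")
  z0 <- sample.int(Z - patch_slices + 1, 1) - 1L
  zr <- (z0 + 1):(z0 + patch_slices)
  out <- list(x = channels[, , zr, , drop = FALSE], z0 = z0)
  if (!is.null(labels)) out$labels <- labels[, , zr, drop = FALSE]
  out
}

#' Augmentation parameters
#'
#' Ranges are symmetric about the identity; drawing with all-zero ranges (and
#' scale range collapsed at 1) reproduces the input patch exactly.
#'
#' @param rotate_deg maximal in-plane rotation, degrees
#' @param scale_range c(lo, hi) isotropic in-plane scale
#' @param translate_vox maximal in-plane translation, voxels
#' @param noise_sigma additive Gaussian noise on channels, signal units
#' @return object of class \code{augment_params}
#' @export
augment_params <- function(rotate_deg = 10, scale_range = c(0.9, 1.1),
                           translate_vox = 5, noise_sigma = 10) {
  stopifnot(rotate_deg >= 0, length(scale_range) == 2,
            scale_range[1] <= scale_range[2], translate_vox >= 0,
            noise_sigma >= 0)
  structure(list(rotate_deg = rotate_deg, scale_range = scale_range,
                 translate_vox = translate_vox, noise_sigma = noise_sigma),
            class = "augment_params")
}

# bilinear sample of one slice at fractional coordinates; outside -> 0
bilinear_slice <- function(sl, sx, sy) {
  nx <- nrow(sl); ny <- ncol(sl)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inb <- function(x, y) x >= 1 & x <= nx & y >= 1 & y <= ny
  gv <- function(x, y) {
    ok <- inb(x, y)
    v <- numeric(length(x))
    v[ok] <- sl[cbind(x[ok], y[ok])]
    v
  }
  v00 <- gv(x0, y0); v10 <- gv(x0 + 1, y0)
  v01 <- gv(x0, y0 + 1); v11 <- gv(x0 + 1, y0 + 1)
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  matrix(out, nx, ny)
}

# nearest-neighbour sample of one integer slice; outside -> 0
nn_slice <- function(sl, sx, sy) {
  nx <- nrow(sl); ny <- ncol(sl)
  xi <- round(sx); yi <- round(sy)
  ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  v <- integer(length(xi))
  v[ok] <- sl[cbind(xi[ok], yi[ok])]
  matrix(v, nx, ny)
}

#' Augment a patch
#'
#' Draws one in-plane affine (rotation, isotropic scale, translation) from the
#' parameter ranges and applies it to every slice of every channel with
#' linear interpolation and to the labels with nearest-neighbour
#' interpolation, then adds Gaussian noise to the channels only. Labels and
#' intensities therefore stay aligned voxel for voxel. Identity parameters
#' return the patch bit-identically.
#'
#' @param patch list as from \code{\link{sample_patch}}
#' @param params \code{augment_params}
#' @return augmented patch, same structure
#' @export
augment_patch <- function(patch, params) {
  stopifnot(inherits(params, "augment_params"))
  rot <- if (params$rotate_deg > 0)
    runif(1, -params$rotate_deg, params$rotate_deg) * pi / 180 else 0
  sc <- if (diff(params$scale_range) > 0)
    runif(1, params$scale_range[1], params$scale_range[2]) else params$scale_range[1]
  tr <- if (params$translate_vox > 0)
    runif(2, -params$translate_vox, params$translate_vox) else c(0, 0)
  identity_affine <- rot == 0 && sc == 1 && all(tr == 0)
  out <- patch
  d <- dim(patch$x)
  if (!identity_affine) {
    cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
    gx <- matrix(rep(seq_len(d[1]), d[2]), d[1]) - cx
    gy <- matrix(rep(seq_len(d[2]), each = d[1]), d[1]) - cy
    # inverse map: rotate by -rot, scale by 1/sc, then undo translation
    ca <- cos(-rot); sa <- sin(-rot)
    sx <- (ca * (gx - tr[1]) - sa * (gy - tr[2])) / sc + cx
    sy <- (sa * (gx - tr[1]) + ca * (gy - tr[2])) / sc + cy
    for (ch in seq_len(d[4]))
      for (z in seq_len(d[3]))
        out$x[, , z, ch] <- bilinear_slice(patch$x[, , z, ch], sx, sy)
    if (!is.null(patch$labels))
      for (z in seq_len(d[3]))
        out$labels[, , z] <- nn_slice(patch$labels[, , z], sx, sy)
  }
  if (params$noise_sigma > 0)
    out$x <- out$x + array(rnorm(length(out$x), 0, params$noise_sigma), dim(out$x))
  out
}

#' Prepare the single-leg training scans of one subject
#'
#' Splits a two-leg volume and its labels mid-sagittally, mirrors the left
#' half, and returns both legs as network-ready scans.
#'
#' @param dixon two-leg \code{dixon_volume}
#' @param labels matching \code{label_volume} (or NULL for inference)
#' @return list of two scans, each a list with \code{channels} (X/2, Y, Z, 2),
#'   \code{labels}, and \code{side} ("right"/"left")
#' @export
leg_scans <- function(dixon, labels = NULL) {
  hs <- split_midsagittal(dixon)
  ls <- if (!is.null(labels)) split_midsagittal(labels) else NULL
  right <- list(channels = leg_channels(hs$right),
                labels = if (!is.null(ls)) ls$right$values else NULL,
                side = "right")
  left <- list(channels = leg_channels(mirror_lr(hs$left)),
               labels = if (!is.null(ls)) mirror_array(ls$left$values) else NULL,
               side = "left")
  list(right, left)
}
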