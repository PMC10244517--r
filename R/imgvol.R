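#' Image volumes, Dixon channel sets, NIfTI I/O, FF maps, and stack stitching
#'
#' The package's core containers are deliberately light: a scalar volume is a
#' 3-D array plus a physical voxel spacing in mm, a Dixon volume is the four
#' co-registered channels (water, fat, in-phase, out-of-phase) on one grid,
#' and a label volume is an integer array plus its muscle scheme. Axis 0 (the
#' first array index) runs left-right, axis 1 anterior-posterior, axis 2 is
#' the slice (inferior-superior) direction.
#'
#' @name imgvol
NULL

#' Construct a scalar image volume
#'
#' @param values 3-D numeric array (X, Y, Z)
#' @param spacing voxel size in mm, length 3, strictly positive
#' @param z_offset slice index of the first slice in a stitched frame
#'   (0-based; non-zero only for acquisition stacks)
#' @return object of class \code{image_volume}
#' @export
image_volume <- function(values, spacing = c(1.2, 1.2, 2.0), z_offset = 0L) {
  if (length(dim(values)) != 3)
    stop("image volume must be 3-D, got ", length(dim(values)), " dimensions")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (z_offset < 0) stop("z_offset must be >= 0")
  structure(list(values = values, spacing = as.numeric(spacing),
                 z_offset = as.integer(z_offset)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @return \code{image_volume}
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3-D NIfTI volume, got ", length(d), "-D data in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in ", path)
  image_volume(array(as.numeric(img), d), sp)
}

#' Write a volume as NIfTI
#'
#' Channel data are stored as 32-bit float, label maps as unsigned 8-bit
#' integers; the affine is diagonal RAS built from the voxel spacing.
#'
#' @param volume \code{image_volume}, \code{label_volume}, or 3-D array
#' @param path output file (.nii or .nii.gz)
#' @param spacing voxel spacing, used when \code{volume} is a bare array
#' @param datatype "float" or "uint8"; default picks uint8 for label volumes
#' @return \code{path}, invisibly
#' @export
write_volume <- function(volume, path, spacing = c(1.2, 1.2, 2.0),
                         datatype = NULL) {
  if (inherits(volume, "label_volume")) {
    values <- volume$values
    spacing <- volume$spacing
    datatype <- datatype %||% "uint8"
  } else if (inherits(volume, "image_volume")) {
    values <- volume$values
    spacing <- volume$spacing
    datatype <- datatype %||% "float"
  } else {
    values <- volume
    datatype <- datatype %||% "float"
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Construct a Dixon volume from its four channels
#'
#' The in-phase and out-of-phase channels are derived from water and fat via
#' the standard Dixon identities when not supplied (see
#' \code{\link{derive_ip_op}}).
#'
#' @param water,fat 3-D arrays of water-only and fat-only signal (>= 0)
#' @param ip,op optional in-phase / out-of-phase arrays on the same grid
#' @param spacing voxel size in mm
#' @param z_offset slice offset in the stitched frame (stacks only)
#' @return object of class \code{dixon_volume}
#' @export
dixon_volume <- function(water, fat, ip = NULL, op = NULL,
                         spacing = c(1.2, 1.2, 2.0), z_offset = 0L) {
  if (!identical(dim(water), dim(fat)))
    stop("water and fat channels must share one grid")
  if (length(dim(water)) != 3) stop("Dixon channels must be 3-D")
  if (min(water) < 0 || min(fat) < 0)
    stop("Dixon channel values must be non-negative")
  if (is.null(ip) || is.null(op)) {
    io <- derive_ip_op(water, fat)
    ip <- ip %||% io$ip
    op <- op %||% io$op
  }
  if (!identical(dim(ip), dim(water)) || !identical(dim(op), dim(water)))
    stop("all four Dixon channels must share one grid")
  structure(list(water = water, fat = fat, ip = ip, op = op,
                 spacing = as.numeric(spacing), z_offset = as.integer(z_offset)),
            class = "dixon_volume")
}

#' @export
print.dixon_volume <- function(x, ...) {
  d <- dim(x$water)
  cat(sprintf("<dixon_volume> W/F/IP/OP, %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Derive in-phase and out-of-phase channels
#'
#' Dixon reconstruction gives \code{ip = water + fat} and
#' \code{op = |water - fat|}; the same identities serve as the phantom's
#' forward model.
#'
#' @param water,fat 3-D arrays on a shared grid
#' @return list with arrays \code{ip} and \code{op}
#' @export
derive_ip_op <- function(water, fat) {
  if (!identical(dim(water), dim(fat))) stop("water/fat shape mismatch")
  list(ip = water + fat, op = abs(water - fat))
}

#' Construct an integer label volume
#'
#' @param values 3-D integer array; 0 is background
#' @param spacing voxel size in mm
#' @param scheme muscle scheme data frame (see \code{\link{muscle_scheme}})
#' @return object of class \code{label_volume}
#' @export
label_volume <- function(values, spacing = c(1.2, 1.2, 2.0),
                         scheme = muscle_scheme()) {
  if (length(dim(values)) != 3) stop("label volume must be 3-D")
  storage.mode(values) <- "integer"
  ids <- sort(unique(as.vector(values)))
  bad <- setdiff(ids, c(0L, scheme$id))
  if (length(bad))
    stop("label ids outside scheme: ", paste(bad, collapse = ", "))
  structure(list(values = values, spacing = as.numeric(spacing),
                 scheme = scheme),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$values)
  present <- sum(x$scheme$id %in% unique(as.vector(x$values)))
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d/%d scheme muscles present\n",
              d[1], d[2], d[3], present, nrow(x$scheme)))
  invisible(x)
}

#' Read / write label volumes
#' @param path NIfTI file
#' @param scheme muscle scheme attached to the result
#' @return \code{label_volume}
#' @export
read_labels <- function(path, scheme = muscle_scheme()) {
  v <- read_volume(path)
  label_volume(array(as.integer(round(v$values)), dim(v$values)),
               v$spacing, scheme)
}

#' Compute a fat-fraction map
#'
#' The proton-density fat fraction is the fat-only signal divided by the sum
#' of the fat-only and water-only signals, expressed in percent. Voxels where
#' \code{fat + water == 0} carry no signal; they are flagged invalid, set to
#' 0, and excluded from all downstream means.
#'
#' @param fat,water 3-D arrays or \code{image_volume}s on one grid
#' @param spacing voxel spacing (taken from the inputs when they are
#'   \code{image_volume}s)
#' @return object of class \code{ff_map}: percent values in [0, 100] plus a
#'   validity mask
#' @export
#' @examples
#' ff <- compute_ff_map(fat = array(750, c(2, 2, 2)),
#'                      water = array(250, c(2, 2, 2)))
#' ff$values[1, 1, 1]  # 75
compute_ff_map <- function(fat, water, spacing = c(1.2, 1.2, 2.0)) {
  if (inherits(fat, "image_volume")) { spacing <- fat$spacing; fat <- fat$values }
  if (inherits(water, "image_volume")) {
    if (!isTRUE(all.equal(spacing, water$spacing)))
      stop("fat/water spacing mismatch")
    water <- water$values
  }
  if (!identical(dim(fat), dim(water))) stop("fat/water shape mismatch")
  if (min(fat) < 0 || min(water) < 0) stop("channel values must be non-negative")
  s <- fat + water
  valid <- s > 0
  values <- array(0, dim(fat))
  values[valid] <- 100 * fat[valid] / s[valid]
  structure(list(values = values, valid = valid, spacing = as.numeric(spacing)),
            class = "ff_map")
}

#' Fat-fraction map of a Dixon volume
#' @param dixon \code{dixon_volume}
#' @return \code{ff_map}
#' @export
ff_map_of <- function(dixon) {
  stopifnot(inherits(dixon, "dixon_volume"))
  compute_ff_map(dixon$fat, dixon$water, dixon$spacing)
}

#' Stitch overlapping axial stacks into one volume
#'
#' Stacks are combined in order of their slice offset. Where two stacks
#' overlap, each channel is blended with a linear ramp that favours the stack
#' whose interior is nearer, computed as \code{a + w * (b - a)}; when the
#' overlapping values agree the result equals them exactly, so stitching
#' stacks cropped from one volume reproduces that volume bit for bit.
#'
#' @param stacks list of \code{dixon_volume}s carrying \code{z_offset}
#' @return \code{dixon_volume} covering the union of slice ranges
#' @export
stitch_stacks <- function(stacks) {
  stopifnot(length(stacks) >= 1, all(vapply(stacks, inherits, TRUE, "dixon_volume")))
  ord <- order(vapply(stacks, function(s) s$z_offset, 0))
  stacks <- stacks[ord]
  d0 <- dim(stacks[[1]]$water)[1:2]
  for (s in stacks)
    if (!identical(dim(s$water)[1:2], d0))
      stop("stacks differ in in-plane shape")
  z0 <- stacks[[1]]$z_offset
  zmax <- max(vapply(stacks, function(s) s$z_offset + dim(s$water)[3], 0))
  Z <- zmax - z0
  chans <- c("water", "fat", "ip", "op")
  out <- lapply(chans, function(ch) array(0, c(d0, Z)))
  names(out) <- chans
  end <- 0L  # slices filled so far (local frame)
  for (s in stacks) {
    o <- s$z_offset - z0
    len <- dim(s$water)[3]
    if (o > end) stop("gap between consecutive stacks at slice ", end + z0)
    if (o + len <= end) next  # fully contained
    m <- end - o  # overlap slice count
    for (ch in chans) {
      new <- s[[ch]]
      if (m > 0) {
        w <- seq_len(m) / (m + 1)  # ramp toward the new stack's interior
        for (j in seq_len(m)) {
          a <- out[[ch]][, , o + j]
          b <- new[, , j]
          out[[ch]][, , o + j] <- a + w[j] * (b - a)
        }
      }
      if (m < len) out[[ch]][, , (end + 1):(o + len)] <- new[, , (m + 1):len]
    }
    end <- o + len
  }
  dixon_volume(out$water, out$fat, out$ip, out$op, stacks[[1]]$spacing)
}

#' Write the four Dixon channels (and optional labels) as NIfTI files
#'
#' Files are named \code{<prefix>_W/_F/_IP/_OP/_labels.nii.gz}.
#'
#' @param dixon \code{dixon_volume}
#' @param prefix path prefix (directories must exist)
#' @param labels optional \code{label_volume}
#' @return character vector of file paths, invisibly
#' @export
write_dixon <- function(dixon, prefix, labels = NULL) {
  stopifnot(inherits(dixon, "dixon_volume"))
  paths <- c(W = paste0(prefix, "_W.nii.gz"), F = paste0(prefix, "_F.nii.gz"),
             IP = paste0(prefix, "_IP.nii.gz"), OP = paste0(prefix, "_OP.nii.gz"))
  write_volume(dixon$water, paths["W"], dixon$spacing)
  write_volume(dixon$fat, paths["F"], dixon$spacing)
  write_volume(dixon$ip, paths["IP"], dixon$spacing)
  write_volume(dixon$op, paths["OP"], dixon$spacing)
  if (!is.null(labels)) {
    paths <- c(paths, labels = paste0(prefix, "_labels.nii.gz"))
    write_volume(labels, paths["labels"])
  }
  invisible(paths)
}

#' Read a Dixon volume written by \code{\link{write_dixon}}
#' @param prefix path prefix used at write time
#' @return \code{dixon_volume}
#' @export
read_dixon <- function(prefix) {
  w <- read_volume(paste0(prefix, "_W.nii.gz"))
  f <- read_volume(paste0(prefix, "_F.nii.gz"))
  ip <- read_volume(paste0(prefix, "_IP.nii.gz"))
  op <- read_volume(paste0(prefix, "_OP.nii.gz"))
  dixon_volume(w$values, f$values, ip$values, op$values, w$spacing)
}
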