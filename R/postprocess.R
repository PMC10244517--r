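#' Label-map postprocessing and ground-truth preparation
#'
#' Prediction cleanup keeps, per muscle, only the two largest 3-D connected
#' components (one per leg) and then fills enclosed background cavities.
#' Ground-truth preparation utilities erode a one-pixel layer from every
#' muscle boundary (as done when manual delineations are cleaned of fascia
#' and vessels) and emulate sparse slice-wise annotation by keeping every
#' k-th slice and filling the rest by nearest-neighbour interpolation.
#'
#' @name postprocess
NULL

as_label_array <- function(labels) {
  if (inherits(labels, "label_volume")) labels$values else labels
}

relabel <- function(template, values) {
  if (inherits(template, "label_volume"))
    label_volume(values, template$spacing, template$scheme)
  else values
}

#' Keep the two largest components of every muscle
#'
#' Connected components use 26-connectivity. For each label id, all but the
#' two largest components (by voxel count; size ties at rank two resolve to
#' the component with the lower centroid along the left-right axis) are
#' relabelled to background. Idempotent.
#'
#' @param labels \code{label_volume} or 3-D integer array
#' @return same type as the input
#' @export
filter_components <- function(labels) {
  v <- as_label_array(labels)
  out <- cpp_filter_components(as.integer(v), dim(v))
  relabel(labels, array(out, dim(v)))
}

#' Fill holes inside segmented muscles
#'
#' A hole is a 6-connected component of background voxels that does not reach
#' the volume border and whose entire labelled neighbourhood is a single
#' muscle; such cavities are relabelled to that muscle. Cavities bordered by
#' several muscles are inter-muscular space and are left untouched, as are
#' foreground voxels. Idempotent.
#'
#' @inheritParams filter_components
#' @return same type as the input
#' @export
fill_holes <- function(labels) {
  v <- as_label_array(labels)
  out <- cpp_fill_holes(as.integer(v), dim(v))
  relabel(labels, array(out, dim(v)))
}

#' Erode a pixel-wide layer from every muscle boundary
#'
#' Erosion is applied per axial slice with a 3x3 cross (4-connectivity)
#' structuring element, \code{width} times; voxels are strongly anisotropic
#' (in-plane 1.2 mm vs 2 mm slices) and delineations are drawn per slice, so
#' the layer is read as in-plane. Used to prepare ground truth, not to clean
#' predictions.
#'
#' @inheritParams filter_components
#' @param width number of erosion passes (0 = identity)
#' @return same type as the input
#' @export
erode_boundary <- function(labels, width = 1) {
  stopifnot(width >= 0)
  if (width == 0) return(labels)
  v <- as_label_array(labels)
  out <- cpp_erode_inplane(as.integer(v), dim(v), as.integer(width))
  relabel(labels, array(out, dim(v)))
}

#' Sparsify ground truth to every k-th slice
#'
#' Keeps slices 0, k, 2k, ... (0-based) and replaces every other slice by a
#' copy of the nearest kept slice; equidistant ties resolve toward the
#' inferior (lower-index) slice. \code{k = 1} is the identity. This emulates
#' delineating only every k-th slice and interpolating the rest.
#'
#' @inheritParams filter_components
#' @param k slice stride (>= 1)
#' @return same type as the input
#' @export
sparsify_gt <- function(labels, k) {
  stopifnot(k >= 1)
  v <- as_label_array(labels)
  Z <- dim(v)[3]
  if (k >= Z)
    warning("stride ", k, " >= ", Z, " slices: only slice 0 is kept")
  if (k == 1) return(labels)
  kept <- seq(1L, Z, by = as.integer(k))  # 1-based; slice 0 is always kept
  out <- v
  for (z in seq_len(Z)) {
    nearest <- kept[which.min(abs(kept - z))]  # ties -> first (inferior)
    if (nearest != z) out[, , z] <- v[, , nearest]
  }
  relabel(labels, out)
}
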