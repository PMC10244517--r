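#' Segmentation agreement metrics and statistical comparison
#'
#' Overlap is measured by the Dice similarity coefficient (DSC, in percent):
#' twice the intersection volume over the sum of the two volumes, i.e. the
#' intersection over the mean of the individual volumes. The generalized DSC
#' pools intersections and volumes over all muscle labels of an image. Surface
#' agreement is the average symmetric surface distance (ASSD, in mm): for
#' every boundary voxel of either mask the distance to the nearest boundary
#' voxel of the other mask, averaged over the union of both directed boundary
#' sets, with anisotropic voxel spacing honoured. Paired comparisons use the
#' Wilcoxon signed-rank test (exact null for n <= 25, mid-ranks for ties) and
#' agreement of continuous measurements uses Bland-Altman analysis.
#'
#' @name metrics
NULL

as_mask <- function(x) {
  if (inherits(x, "label_volume")) x <- x$values
  if (!is.logical(x)) x <- x != 0
  x
}

#' Dice similarity coefficient of two masks
#'
#' @param mask_a,mask_b logical 3-D arrays on one grid (numeric arrays are
#'   treated as non-zero = foreground)
#' @return DSC in percent; two empty masks agree perfectly (100)
#' @export
#' @examples
#' a <- array(FALSE, c(4, 4, 1)); a[1:2, 1, 1] <- TRUE
#' b <- array(FALSE, c(4, 4, 1)); b[2:3, 1, 1] <- TRUE
#' dsc(a, b)  # 50
dsc <- function(mask_a, mask_b) {
  a <- as_mask(mask_a); b <- as_mask(mask_b)
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(100)
  100 * 2 * sum(a & b) / (na + nb)
}

#' Per-muscle DSC (both legs pooled)
#'
#' @param pred,ref \code{label_volume}s (or integer arrays) on one grid
#' @param id muscle label id
#' @return DSC in percent, with attribute \code{absent = TRUE} when the
#'   muscle is missing from both volumes
#' @export
per_muscle_dsc <- function(pred, ref, id) {
  p <- as_label_array(pred); r <- as_label_array(ref)
  if (!identical(dim(p), dim(r))) stop("volumes must share one grid")
  if (inherits(pred, "label_volume") && !id %in% pred$scheme$id)
    stop("muscle id ", id, " not in scheme")
  a <- p == id; b <- r == id
  out <- dsc(a, b)
  if (sum(a) + sum(b) == 0) attr(out, "absent") <- TRUE
  out
}

#' Generalized DSC over all muscles of an image
#'
#' Pools per-label intersections and volumes (background excluded,
#' unweighted over labels): \code{100 * 2 * sum_i |A_i n B_i| / sum_i (|A_i| + |B_i|)}.
#'
#' @param pred,ref \code{label_volume}s or integer arrays on one grid
#' @param ids label ids to pool (default: all scheme / foreground ids)
#' @return generalized DSC in percent
#' @export
generalized_dsc <- function(pred, ref, ids = NULL) {
  p <- as_label_array(pred); r <- as_label_array(ref)
  if (!identical(dim(p), dim(r))) stop("volumes must share one grid")
  if (is.null(ids)) {
    ids <- if (inherits(ref, "label_volume")) ref$scheme$id
    else setdiff(sort(unique(c(as.vector(p), as.vector(r)))), 0L)
  }
  if (length(ids) == 0) stop("empty label id set")
  inter <- 0; tot <- 0
  for (id in ids) {
    a <- p == id; b <- r == id
    inter <- inter + sum(a & b)
    tot <- tot + sum(a) + sum(b)
  }
  if (tot == 0) return(100)
  100 * 2 * inter / tot
}

#' Average symmetric surface distance
#'
#' Boundary voxels are foreground voxels with at least one 6-neighbour
#' outside the mask (the volume border counts as outside). Distances are
#' Euclidean between voxel centres in mm; the nearest-boundary distances are
#' obtained from an exact anisotropic distance transform and averaged over
#' both directed boundary sets.
#'
#' @param mask_a,mask_b non-empty masks on one grid
#' @param spacing voxel size in mm
#' @return ASSD in mm; \code{NA} (with a warning) when either mask is empty
#' @export
assd <- function(mask_a, mask_b, spacing = c(1.2, 1.2, 2.0)) {
  a <- as_mask(mask_a); b <- as_mask(mask_b)
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  if (sum(a) == 0 || sum(b) == 0) {
    warning("ASSD undefined: empty mask")
    return(NA_real_)
  }
  d <- dim(a)
  ba <- cpp_boundary_mask(a, d)
  bb <- cpp_boundary_mask(b, d)
  d2b <- cpp_edt_sq(bb, d, spacing)  # squared distance to B's boundary
  d2a <- cpp_edt_sq(ba, d, spacing)
  mean(c(sqrt(d2b[ba]), sqrt(d2a[bb])))
}

#' Per-muscle metrics report
#'
#' DSC and ASSD per muscle (legs pooled) plus the image-level generalized
#' DSC. Muscles absent from both volumes are flagged \code{absent} (DSC 100
#' by convention, ASSD NA); muscles absent from exactly one are flagged
#' \code{one_empty} (ASSD NA).
#'
#' @param pred,ref \code{label_volume}s on one grid
#' @param spacing voxel size in mm (default: from \code{ref})
#' @return data frame (one row per scheme muscle) with attribute
#'   \code{gdsc_pct}
#' @export
metrics_report <- function(pred, ref, spacing = NULL) {
  stopifnot(inherits(ref, "label_volume"))
  spacing <- spacing %||% ref$spacing
  p <- as_label_array(pred); r <- as_label_array(ref)
  scheme <- ref$scheme
  rows <- lapply(scheme$id, function(id) {
    a <- p == id; b <- r == id
    na <- sum(a); nb <- sum(b)
    flag <- if (na + nb == 0) "absent" else if (na == 0 || nb == 0) "one_empty" else ""
    as_mm <- if (flag == "") assd(a, b, spacing) else NA_real_
    data.frame(muscle_id = id, abbrev = scheme$abbrev[scheme$id == id],
               name = scheme$name[scheme$id == id],
               dsc_pct = dsc(a, b), assd_mm = as_mm, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "gdsc_pct") <- generalized_dsc(pred, ref, scheme$id)
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of the hypothesis that paired differences are symmetric
#' about zero. Zero differences are dropped; tied absolute differences get
#' mid-ranks. For n <= 25 (after dropping zeros) the exact null distribution
#' of the positive-rank sum is computed by dynamic programming over all sign
#' assignments; above that, a normal approximation with tie correction is
#' used.
#'
#' @param paired_a,paired_b equal-length numeric vectors
#' @return list with \code{statistic} (positive-rank sum W+), \code{p_value},
#'   \code{n} (pairs used), and \code{method}
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired samples must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  if (n < 5) stop("need at least 5 non-zero paired differences, got ", n)
  r <- rank(abs(d))  # mid-ranks for ties
  w <- sum(r[d > 0])
  if (n <= 25) {
    # exact null via the distribution of the sum of a random subset of the
    # doubled ranks (doubling makes mid-ranks integral)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[1:(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / 48
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_corr)
    z <- (w - mu) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_tie_corrected"
  }
  list(statistic = w, p_value = p, n = as.integer(n), method = method)
}

#' Bland-Altman agreement analysis
#'
#' Differences \code{a - b} against pair means, with bias (mean difference)
#' and 95\% limits of agreement (bias +/- 1.96 sample standard deviations of
#' the differences).
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 2)
#' @return object of class \code{bland_altman}: \code{differences},
#'   \code{means} (input order preserved), \code{bias}, \code{sd},
#'   \code{loa} (lower, upper)
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("inputs must have equal length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs")
  diffs <- values_a - values_b
  s <- sd(diffs)
  bias <- mean(diffs)
  structure(list(differences = diffs, means = (values_a + values_b) / 2,
                 bias = bias, sd = s,
                 loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, limits of agreement [%.4g, %.4g]\n",
              x$n, x$bias, x$loa[1], x$loa[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of pair",
                              ylab = "difference (a - b)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2), col = "grey30")
  invisible(x)
}
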