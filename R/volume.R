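#' @useDynLib nvcfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median optim qt pt pchisq pf rnorm runif sd setNames
#' @importFrom utils write.csv read.csv
NULL

#' Label legend for the four anatomical sub-volumes
#'
#' Fixed integer codes for the explicit-segmentation partition: everything
#' not of interest (`REST`), the cisternal CSF space including the vascular
#' structures it contains (`CSF_VESSEL`), the brainstem (`BRAINSTEM`), the
#' cranial nerves (`NERVE`), and vessels transplanted from the angiographic
#' volume during fusion (`VESSEL`).  `VESSEL` only appears after fusion.
#'
#' @return Named integer vector mapping label name to id.
#' @export
nvc_legend <- function() {
  c(REST = 0L, CSF_VESSEL = 1L, BRAINSTEM = 2L, NERVE = 3L, VESSEL = 4L)
}

#' Construct a 3-D scalar volume
#'
#' A `nvc_volume` bundles a 3-D numeric array with its voxel spacing (mm),
#' a 4x4 affine mapping *0-based* voxel indices `(i,j,k,1)` to world
#' coordinates in mm (NIfTI sform convention, voxel-center sampling), and a
#' modality tag.  All R-level voxel indices passed to package functions
#' (seeds, bounding boxes, centerlines) are 1-based; the affine itself
#' follows the on-disk 0-based convention.
#'
#' @param data 3-D numeric array, at least 2 voxels per axis.
#' @param spacing numeric length-3, mm per axis, all positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling
#'   by `spacing` with origin 0.
#' @param modality one of `"CISS"`, `"TOF"`, `"FUSED"`.
#' @return An object of class `nvc_volume`.
#' @export
nvc_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                       modality = c("CISS", "TOF", "FUSED")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3-D: `data` must be a 3-D array")
  if (any(dim(data) < 2L))
    stop("each axis must have at least 2 voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be 4x4")
  if (!is.finite(det(affine)) || abs(det(affine)) < 1e-12)
    stop("non-invertible affine")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, affine = affine,
                 modality = modality),
            class = "nvc_volume")
}

#' @export
print.nvc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nvc_volume %s  %dx%dx%d  spacing %.3gx%.3gx%.3g mm  range [%.4g, %.4g]>\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a label volume
#'
#' Integer labels on the same grid as a source [nvc_volume()]; every voxel
#' carries exactly one label drawn from `legend`.
#'
#' @param labels 3-D integer array.
#' @param legend named integer vector mapping label name to id; defaults to
#'   [nvc_legend()].
#' @param spacing,affine grid geometry, as for [nvc_volume()].
#' @param template optional `nvc_volume` supplying `spacing`/`affine`.
#' @return An object of class `nvc_label_volume`.
#' @export
nvc_label_volume <- function(labels, legend = nvc_legend(),
                             spacing = c(1, 1, 1), affine = NULL,
                             template = NULL) {
  if (!is.null(template)) {
    stopifnot(inherits(template, "nvc_volume"))
    spacing <- template$spacing
    affine <- template$affine
  }
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("non-3-D: `labels` must be a 3-D array")
  if (is.double(labels) && any(labels != round(labels)))
    stop("labels must be integral")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA")
  if (is.null(names(legend)) || anyDuplicated(legend))
    stop("legend must be a named vector with unique ids")
  if (!all(unique(as.vector(labels)) %in% legend))
    stop("labels contain ids absent from the legend")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(labels = labels, legend = legend,
                 spacing = as.numeric(spacing), affine = as.matrix(affine)),
            class = "nvc_label_volume")
}

#' @export
print.nvc_label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = x$legend,
                      labels = names(x$legend)))
  cat(sprintf("<nvc_label_volume %dx%dx%d>\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

#' Inclusive voxel bounding box
#'
#' @param lo,hi length-3 integer corners, 1-based, `lo <= hi` per axis.
#' @return `nvc_bbox` object.
#' @export
nvc_bbox <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L) stop("bbox corners must be length 3")
  if (any(lo > hi)) stop("bbox requires lo <= hi per axis")
  if (any(lo < 1L)) stop("bbox outside grid bounds")
  structure(list(lo = lo, hi = hi), class = "nvc_bbox")
}

# Clip a bbox to a grid; NULL means the whole grid.
bbox_or_grid <- function(bbox, dims) {
  if (is.null(bbox)) return(nvc_bbox(c(1, 1, 1), dims))
  if (any(bbox$hi > dims)) stop("bbox outside grid bounds")
  bbox
}

#' Map voxel indices to world coordinates
#'
#' @param v an `nvc_volume` or `nvc_label_volume`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  A <- v$affine
  (idx - 1) %*% t(A[1:3, 1:3]) +
    matrix(A[1:3, 4], nrow(idx), 3, byrow = TRUE)
}

#' Map world coordinates to (fractional, 1-based) voxel indices
#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world mm coordinates.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  Ainv <- solve(v$affine)
  (xyz %*% t(Ainv[1:3, 1:3]) +
     matrix(Ainv[1:3, 4], nrow(xyz), 3, byrow = TRUE)) + 1
}

# World coordinate of the volume's geometric center.
world_center <- function(v) {
  d <- if (inherits(v, "nvc_label_volume")) dim(v$labels) else dim(v$data)
  as.numeric(voxel_to_world(v, matrix((d + 1) / 2, 1)))
}

# TRUE if two volumes/label volumes share dims, spacing and affine.
same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "nvc_label_volume")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "nvc_label_volume")) dim(b$labels) else dim(b$data)
  all(da == db) && max(abs(a$affine - b$affine)) < tol
}

# 3-D array of a mask/array shifted by (dx,dy,dz), padding with `fill`.
shift3 <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# Binary dilation by one step of 6- or 26-connectivity.
dilate1 <- function(mask, connectivity = 26) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
    out <- out | shift3(mask, dx, dy, dz, FALSE)
  }
  out
}

# Dice coefficient between two logical masks.
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
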