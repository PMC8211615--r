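# Vessel transfer from the reformatted angiographic volume into the
# anatomical volume.  The hyperintense TOF vessels are extracted by
# volume growing, their intensities are inverted onto the hypointense
# CISS vessel range, and the result replaces the CISS values at exactly
# those voxels.  This is the mechanism that repairs flow-void dropout:
# vessel segments invisible in CISS are fully present in TOF and re-enter
# the CISS display window after the transfer.

# Otsu threshold (maximal between-class variance) on a 256-bin histogram.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  cnt <- as.numeric(tabulate(cut(x, br, include.lowest = TRUE,
                                 labels = FALSE), nb))
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w <- cumsum(cnt); m <- cumsum(cnt * mids)
  wt <- w[nb]; mt <- m[nb]
  between <- (mt * w - m * wt)^2 / (w * (wt - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Extract hyperintense vessels from a reformatted TOF volume
#'
#' Delegates to [volume_grow()] with a high-intensity window.  With
#' `p = NULL` the lower threshold is the Otsu split of the intensity
#' histogram (vessels are the only bright class in TOF) and the growth is
#' seeded at the global intensity maximum; additional seeds cover every
#' bright connected component.
#'
#' @param tof_ref TOF [nvc_volume()] already reformatted onto the CISS grid.
#' @param p optional [grow_params()] overriding the automatic window/seeds.
#' @return Logical vessel mask.
#' @export
extract_tof_vessels <- function(tof_ref, p = NULL) {
  stopifnot(inherits(tof_ref, "nvc_volume"))
  if (is.null(p)) {
    thr <- otsu_threshold(as.vector(tof_ref$data))
    bright <- tof_ref$data >= thr
    if (!any(bright)) stop("no hyperintense voxels above the threshold")
    seeds <- which(bright, arr.ind = TRUE)
    # one seed per bright voxel would be wasteful; the flood fill unions
    # components, so seed every bright voxel directly
    p <- grow_params(seeds, lower = thr, upper = Inf, connectivity = 26)
  }
  volume_grow(tof_ref, p)
}

#' Linear decreasing intensity inversion
#'
#' Maps `[from[1], from[2]]` onto `[to[2], to[1]]`:
#' `invert(v) = to[2] - (v - from[1]) * (to[2] - to[1]) / (from[2] - from[1])`.
#' Strictly decreasing; applying it twice with the ranges swapped is the
#' identity.
#'
#' @param v numeric vector.
#' @param from source range `c(lo, hi)`, `hi > lo`.
#' @param to target range `c(lo, hi)`.
#' @return Mapped values (not clamped).
#' @export
invert_map <- function(v, from, to) {
  if (from[2] <= from[1]) stop("degenerate range: from[2] must exceed from[1]")
  to[2] - (v - from[1]) * (to[2] - to[1]) / (from[2] - from[1])
}

#' Fuse reformatted TOF vessels into the CISS volume
#'
#' For every voxel of `vessel_mask` the fused intensity is the inverted
#' TOF value mapped onto the configured CISS dark-vessel range (then
#' clamped to it); all other voxels keep their CISS value bit-exactly.
#' The mask doubles as the set of voxels to stamp with the VESSEL label.
#'
#' @param ciss CISS [nvc_volume()].
#' @param tof_ref TOF volume on the same grid (see [reformat()]).
#' @param vessel_mask logical mask from [extract_tof_vessels()].
#' @param tof_range source range; default 1st-99th percentile of the TOF
#'   intensities inside the mask.
#' @param ciss_range target dark-vessel range; default `c(150, 250)`,
#'   matching the default CISS vessel display window.
#' @return `list(fused = nvc_volume, labels_delta = logical mask)`.
#' @export
fuse <- function(ciss, tof_ref, vessel_mask, tof_range = NULL,
                 ciss_range = c(150, 250)) {
  stopifnot(inherits(ciss, "nvc_volume"), inherits(tof_ref, "nvc_volume"))
  if (!same_grid(ciss, tof_ref)) stop("volumes must share one grid")
  stopifnot(all(dim(vessel_mask) == dim(ciss$data)))
  fused <- ciss$data
  if (any(vessel_mask)) {
    tv <- tof_ref$data[vessel_mask]
    if (is.null(tof_range))
      tof_range <- as.numeric(stats::quantile(tv, c(0.01, 0.99)))
    if (tof_range[2] <= tof_range[1])
      stop("degenerate range: TOF vessel intensities are constant")
    mapped <- invert_map(tv, tof_range, ciss_range)
    fused[vessel_mask] <- pmin(pmax(mapped, ciss_range[1]), ciss_range[2])
  }
  out <- nvc_volume(fused, spacing = ciss$spacing, affine = ciss$affine,
                    modality = "FUSED")
  list(fused = out, labels_delta = vessel_mask)
}

#' Stamp fused vessel voxels into a label volume
#'
#' @param labels an [nvc_label_volume()].
#' @param vessel_mask logical mask (the `labels_delta` of [fuse()]).
#' @return Updated `nvc_label_volume` with those voxels set to VESSEL.
#' @export
apply_vessel_label <- function(labels, vessel_mask) {
  stopifnot(inherits(labels, "nvc_label_volume"),
            all(dim(vessel_mask) == dim(labels$labels)))
  lab <- labels$labels
  lab[vessel_mask] <- labels$legend[["VESSEL"]]
  nvc_label_volume(lab, legend = labels$legend, spacing = labels$spacing,
                   affine = labels$affine)
}
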