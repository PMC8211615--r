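# Explicit coarse segmentation: seeded volume growing inside an intensity
# window and a bounding box, then assembly of the four sub-volumes under
# the fixed priority hierarchy nerve > CSF(+vessels) > brainstem > rest.

#' Parameters for seeded volume growing
#'
#' @param seeds n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param lower,upper inclusive intensity window, `lower <= upper`.
#' @param bbox optional [nvc_bbox()] restricting the growth.
#' @param connectivity 6 or 26.
#' @return `nvc_grow_params` list.
#' @export
grow_params <- function(seeds, lower, upper, bbox = NULL,
                        connectivity = 26) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3, byrow = TRUE)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (nrow(seeds) == 0) stop("empty seed list")
  if (!is.numeric(lower) || !is.numeric(upper) || lower > upper)
    stop("window requires lower <= upper")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (!is.null(bbox)) {
    stopifnot(inherits(bbox, "nvc_bbox"))
    inside <- seeds[, 1] >= bbox$lo[1] & seeds[, 1] <= bbox$hi[1] &
      seeds[, 2] >= bbox$lo[2] & seeds[, 2] <= bbox$hi[2] &
      seeds[, 3] >= bbox$lo[3] & seeds[, 3] <= bbox$hi[3]
    if (!all(inside)) stop("all seeds must lie inside the bounding box")
  }
  structure(list(seeds = seeds, lower = lower, upper = upper, bbox = bbox,
                 connectivity = as.integer(connectivity)),
            class = "nvc_grow_params")
}

#' Seeded volume growing
#'
#' Returns the maximal connected set of voxels containing the seeds whose
#' intensity lies in `[lower, upper]`, restricted to the bounding box.
#' Voxels in `barrier` are excluded and block connectivity (used to keep
#' the brainstem growth from leaking through the already-segmented CSF).
#'
#' @param v an [nvc_volume()].
#' @param p an [grow_params()] object.
#' @param barrier optional logical mask of excluded voxels.
#' @return Logical 3-D mask.
#' @export
volume_grow <- function(v, p, barrier = NULL) {
  stopifnot(inherits(v, "nvc_volume"), inherits(p, "nvc_grow_params"))
  dims <- dim(v$data)
  if (any(p$seeds < 1L) || any(p$seeds > matrix(dims, nrow(p$seeds), 3,
                                                byrow = TRUE)))
    stop("seed outside grid")
  a <- v$data
  if (!is.null(barrier)) {
    stopifnot(all(dim(barrier) == dims))
    a <- a + 0      # copy
    a[barrier] <- NaN
  }
  for (s in seq_len(nrow(p$seeds))) {
    val <- a[p$seeds[s, 1], p$seeds[s, 2], p$seeds[s, 3]]
    if (is.na(val) || val < p$lower || val > p$upper)
      stop(sprintf("seed (%d,%d,%d) intensity %s outside window [%g, %g]",
                   p$seeds[s, 1], p$seeds[s, 2], p$seeds[s, 3],
                   format(val), p$lower, p$upper))
  }
  bb <- bbox_or_grid(p$bbox, dims)
  mask <- cpp_flood_fill(as.double(a), as.integer(dims), p$seeds - 1L,
                         p$lower, p$upper, bb$lo - 1L, bb$hi - 1L,
                         p$connectivity)
  array(mask, dims)
}

#' Histogram-derived CSF intensity window
#'
#' The window is centred on the mode of the bright histogram peak (the
#' hyperintense CSF) and extends two standard deviations of the
#' peak-neighbourhood intensities to each side.
#'
#' @param v an [nvc_volume()] with CISS-like contrast.
#' @param nsd half-width in standard deviations (default 2).
#' @return `c(lower, upper)`.
#' @export
csf_window <- function(v, nsd = 2) {
  x <- as.vector(v$data)
  rng <- range(x)
  if (diff(rng) <= 0) stop("constant volume has no bright peak")
  br <- seq(rng[1], rng[2], length.out = 129)
  cnt <- tabulate(cut(x, br, include.lowest = TRUE, labels = FALSE), 128)
  mids <- (br[-1] + br[-129]) / 2
  bright <- mids > mean(rng)
  if (!any(bright)) stop("no bright histogram peak found")
  m <- mids[bright][which.max(cnt[bright])]
  # spread of the whole bright class (everything nearer the peak than the
  # mid-intensity saddle), robust to the peak sharpening that closing causes
  sel <- x[x > (m + mean(rng)) / 2]
  s <- max(sd(sel), 1e-8)
  c(m - nsd * s, m + nsd * s)
}

#' Assemble the label volume from the three explicit masks
#'
#' Overlaps are resolved by the fixed priority hierarchy: nerve first,
#' then CSF (which includes the vascular structures), then brainstem;
#' everything else is REST.  The result is always a partition.
#'
#' @param csf_mask,brainstem_mask,nerve_mask logical masks on one grid.
#' @param template `nvc_volume` supplying the grid geometry.
#' @return An [nvc_label_volume()].
#' @export
assemble_labels <- function(csf_mask, brainstem_mask, nerve_mask,
                            template) {
  stopifnot(all(dim(csf_mask) == dim(brainstem_mask)),
            all(dim(csf_mask) == dim(nerve_mask)))
  leg <- nvc_legend()
  lab <- array(leg[["REST"]], dim(csf_mask))
  lab[brainstem_mask] <- leg[["BRAINSTEM"]]
  lab[csf_mask] <- leg[["CSF_VESSEL"]]
  lab[nerve_mask] <- leg[["NERVE"]]
  nvc_label_volume(lab, legend = leg, template = template)
}

#' Volume-grow the brainstem behind the CSF barrier
#'
#' Grows from the given seeds on the (preprocessed) volume with the
#' previously segmented CSF mask acting as an impenetrable barrier, and an
#' optional bounding box as lateral/dorsal restriction.
#'
#' @param v an [nvc_volume()].
#' @param csf_mask logical CSF mask (barrier).
#' @param p an [grow_params()] object (window chosen around brainstem
#'   intensities).
#' @return Logical mask.
#' @export
segment_brainstem <- function(v, csf_mask, p) {
  stopifnot(all(dim(csf_mask) == dim(v$data)))
  volume_grow(v, p, barrier = csf_mask)
}

#' Import a manually drawn nerve mask
#'
#' Nerve segmentation requires anatomical knowledge and is accepted as a
#' hand annotation (or phantom ground truth) only; no automatic nerve
#' segmentation is attempted.
#'
#' @param path NIfTI file whose nonzero voxels mark the nerves.
#' @param template `nvc_volume` whose grid the mask must match.
#' @return Logical mask.
#' @export
import_nerve_labels <- function(path, template) {
  r <- nifti_read(path)
  if (!all(dim(r$data) == dim(template$data)))
    stop("nerve mask grid does not match the target volume")
  if (max(abs(r$affine - template$affine)) > 1e-4)
    stop("nerve mask affine does not match the target volume")
  m <- array(r$data != 0, dim(r$data))
  if (!any(m)) warning("imported nerve mask is empty")
  m
}
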