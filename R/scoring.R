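# Neurovascular-contact detection at the root entry zone and the ordinal
# 0-5 vessel-quality score.  A contact is a vessel touching the nerve
# with no visible CSF layer in between; the score operationalizes the
# published ordinal scale through centerline display-window coverage so
# it is computable on phantoms (clinical use passes expert scores
# through unchanged).

#' Detect vessel-nerve contact at the root entry zone
#'
#' Contact voxels are vessel voxels 26-adjacent to root-entry-zone voxels
#' (direct adjacency leaves no room for an intervening CSF-labeled
#' voxel); the finding is positive iff that set is nonempty.  Laterality
#' is read from the contact centroid relative to the volume midline along
#' `lr_axis`.
#'
#' @param vessel_mask,rez_mask logical masks on one grid.
#' @param labels optional [nvc_label_volume()] (interface completeness;
#'   adjacency itself already excludes an intervening CSF voxel).
#' @param lr_axis axis index encoding left-right (default 2); voxels above
#'   the midline count as left.
#' @return `nvc_finding`: list with `side` (`"left"`, `"right"`,
#'   `"bilateral"`, `"none"`), `contact` flag, `contact_voxels` (n x 3),
#'   and `loop_type` (manual annotation pass-through, `NA` by default).
#' @export
detect_contact <- function(vessel_mask, rez_mask, labels = NULL,
                           lr_axis = 2L) {
  stopifnot(all(dim(vessel_mask) == dim(rez_mask)))
  if (!any(vessel_mask) || !any(rez_mask)) {
    return(structure(list(side = "none", contact = FALSE,
                          contact_voxels = matrix(integer(), 0, 3),
                          loop_type = NA_character_),
                     class = "nvc_finding"))
  }
  hit <- vessel_mask & dilate1(rez_mask, 26)
  vox <- which(hit, arr.ind = TRUE)
  side <- "none"
  if (nrow(vox) > 0) {
    mid <- (dim(vessel_mask)[lr_axis] + 1) / 2
    left <- vox[, lr_axis] > mid
    side <- if (all(left)) "left" else if (!any(left)) "right" else "bilateral"
  }
  structure(list(side = side, contact = nrow(vox) > 0,
                 contact_voxels = vox, loop_type = NA_character_),
            class = "nvc_finding")
}

#' @export
print.nvc_finding <- function(x, ...) {
  cat(sprintf("<nvc_finding  contact=%s  side=%s  voxels=%d>\n",
              x$contact, x$side, nrow(x$contact_voxels)))
  invisible(x)
}

#' Default CISS vessel display window
#'
#' Intensity range in which vascular content renders as vessel in the
#' CISS/fused volume: the vessel class mean plus/minus `nsd` noise
#' standard deviations under the phantom's stated contrast.
#'
#' @param mean,sigma vessel class mean and noise sd.
#' @param nsd half-width in standard deviations.
#' @return `c(lower, upper)`.
#' @export
vessel_display_window <- function(mean = 200, sigma = 20, nsd = 3) {
  c(mean - nsd * sigma, mean + nsd * sigma)
}

#' Centerline display-window coverage
#'
#' Fraction of ground-truth centerline voxels whose intensity in `v`
#' falls inside the vessel display window.
#'
#' @param v [nvc_volume()] (CISS-only or fused).
#' @param centerline n x 3 matrix of 1-based voxel indices, ordered from
#'   proximal to distal.
#' @param window display window, `c(lower, upper)`.
#' @return Scalar in `[0, 1]`.
#' @export
centerline_coverage <- function(v, centerline,
                                window = vessel_display_window()) {
  if (nrow(centerline) == 0) stop("empty centerline")
  vals <- v$data[centerline]
  mean(vals >= window[1] & vals <= window[2])
}

# Coverage -> ordinal score, shared by score_vessel and its test oracle.
coverage_to_score <- function(c_all, c_prox, c_dist) {
  if (c_all == 0) return(0L)
  if (c_all >= 0.95) return(5L)
  if (c_prox >= 0.8 && c_dist < 0.5) return(3L)
  if (c_all >= 0.5) return(4L)
  if (c_all >= 0.25) return(2L)
  1L
}

#' Ordinal 0-5 vessel-quality score
#'
#' Operationalizes the published ordinal scale by centerline coverage
#' `c`: `c = 0` scores 0 (missing vessel), `c >= 0.95` scores 5 (complete
#' representation); a vessel whose proximal half is well reproduced
#' (`>= 0.8`) while the distal half is mostly missing (`< 0.5`) scores 3
#' (proximal parts shown); otherwise `c >= 0.5` scores 4, `c >= 0.25`
#' scores 2, and any remaining nonzero coverage scores 1.  In clinical
#' mode pass an expert score through `manual`.
#'
#' @param v [nvc_volume()] to assess (CISS-only or fused).
#' @param centerline ordered n x 3 voxel path (proximal first).
#' @param window vessel display window.
#' @param name vessel name for bookkeeping (e.g. `"L.V.A."`, `"PICA"`).
#' @param manual optional expert-entered integer 0-5 overriding the
#'   automatic mode.
#' @return `nvc_vessel_score`: list with `name`, `score`, `coverage`,
#'   `coverage_proximal`, `coverage_distal`.
#' @export
score_vessel <- function(v, centerline, window = vessel_display_window(),
                         name = "vessel", manual = NULL) {
  if (!is.null(manual)) {
    manual <- as.integer(manual)
    if (!manual %in% 0:5) stop("manual score must be an integer 0-5")
    return(structure(list(name = name, score = manual, coverage = NA_real_,
                          coverage_proximal = NA_real_,
                          coverage_distal = NA_real_),
                     class = "nvc_vessel_score"))
  }
  if (nrow(centerline) == 0) stop("empty centerline")
  n <- nrow(centerline)
  half <- floor(n / 2)
  c_all <- centerline_coverage(v, centerline, window)
  c_prox <- centerline_coverage(v, centerline[seq_len(max(half, 1)), ,
                                              drop = FALSE], window)
  c_dist <- centerline_coverage(v, centerline[seq(half + 1, n), ,
                                              drop = FALSE], window)
  structure(list(name = name,
                 score = coverage_to_score(c_all, c_prox, c_dist),
                 coverage = c_all, coverage_proximal = c_prox,
                 coverage_distal = c_dist),
            class = "nvc_vessel_score")
}

#' @export
print.nvc_vessel_score <- function(x, ...) {
  cat(sprintf("<nvc_vessel_score %s  score=%d  coverage=%.3f>\n",
              x$name, x$score, x$coverage))
  invisible(x)
}

#' Write scores and findings as CSV
#'
#' One row per vessel: `vessel, side, score, contact_voxels` (the side and
#' contact count come from the finding, which refers to the assessed
#' root entry zone).
#'
#' @param scores list of `nvc_vessel_score`.
#' @param finding an `nvc_finding`.
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_scores_csv <- function(scores, finding, path) {
  df <- data.frame(
    vessel = vapply(scores, function(s) s$name, ""),
    side = finding$side,
    score = vapply(scores, function(s) s$score, 0L),
    contact_voxels = nrow(finding$contact_voxels))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
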