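# Digital phantom: paired CISS-like / TOF-like volumes with analytic
# ground truth.  The geometry is a stylized posterior fossa: a vertical
# brainstem column bathed in cisternal CSF, a large arterial trunk hugging
# its anterior surface (vertebral/basilar analogue), a smaller
# brainstem-hugging arterial loop (PICA analogue), and a short radial nerve
# root (CN IX/X root entry zone analogue).  The three artifact classes that
# degrade CISS-only visualizations are emulated: flow voids along vessel
# arcs, CSF pulsation speckle near the trunk, and near-brainstem contour
# fusion (the trunk runs within a fraction of a millimetre of the
# brainstem surface by construction).

#' Specification of the synthetic phantom
#'
#' Defaults describe the stated world all package tests run in: a 96^3 grid
#' at 0.4 mm isotropic spacing (a desk-scale stand-in for 512x512x144
#' clinical slabs; all geometry scales with the grid), CISS-like contrast
#' with hyperintense CSF far above the hypointense brainstem, nerves and
#' vessels, TOF-like contrast with vessels far above everything else, and a
#' flow void silencing the middle 30% of the trunk in the CISS volume.
#'
#' @param dims grid size per axis (voxels).
#' @param spacing voxel size per axis (mm); 0.4 mm isotropic by default.
#' @param ciss_means,tof_means named intensity means per tissue class
#'   (`background`, `csf`, `brainstem`, `nerve`, `vessel`).  CISS must rank
#'   CSF above all other classes; TOF must rank vessel above all others.
#' @param ciss_sigma,tof_sigma additive noise standard deviation.
#' @param noise `"gaussian"` (default) or `"rician"`.
#' @param vessel_radii named radii in mm for the `trunk` and `loop` vessels.
#' @param nerve_radius nerve tube radius, mm.
#' @param nerve_gap surface-to-surface clearance between loop vessel and
#'   nerve, mm; negative values make them touch (neurovascular contact).
#' @param flow_void list of arcs, each `list(vessel=, arc=c(t0,t1),
#'   factor=)`: CISS vessel intensity along the arc is pulled toward the
#'   brainstem mean by `factor` (1 = indistinguishable from brainstem).
#' @param edge partial-volume edge width in mm (the ramp over which a
#'   structure blends into its surroundings, emulating the scanner
#'   point-spread function); interiors more than `edge/2` from a boundary
#'   keep the exact class mean.
#' @param pulsation `list(density=, amplitude=)` or `NULL`: fraction of CSF
#'   voxels near the upper trunk replaced by vessel-range speckle.
#' @param true_rigid `nvc_rigid` mapping the TOF frame into the CISS frame;
#'   `NULL` for the default small offset (about 4 degrees, 1.6 mm).
#' @param seed integer RNG seed; a fixed seed makes the phantom bytewise
#'   reproducible.
#' @return `nvc_phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(96, 96, 96), spacing = c(0.4, 0.4, 0.4),
                         ciss_means = c(background = 50, csf = 1000,
                                        brainstem = 400, nerve = 250,
                                        vessel = 200),
                         tof_means = c(background = 60, csf = 100,
                                       brainstem = 120, nerve = 110,
                                       vessel = 1000),
                         ciss_sigma = 20, tof_sigma = 20,
                         noise = c("gaussian", "rician"),
                         vessel_radii = c(trunk = 1.2, loop = 0.9),
                         nerve_radius = 0.8,
                         nerve_gap = 1.2,
                         flow_void = list(list(vessel = "trunk",
                                               arc = c(0.35, 0.65),
                                               factor = 1.0)),
                         pulsation = list(density = 0.02, amplitude = 30),
                         edge = 0.4,
                         true_rigid = NULL,
                         seed = 1L) {
  noise <- match.arg(noise)
  req <- c("background", "csf", "brainstem", "nerve", "vessel")
  stopifnot(all(req %in% names(ciss_means)), all(req %in% names(tof_means)))
  if (ciss_means["csf"] <= max(ciss_means[setdiff(req, "csf")]))
    stop("CISS contrast must have hyperintense CSF above all other classes")
  if (tof_means["vessel"] <= max(tof_means[setdiff(req, "vessel")]))
    stop("TOF contrast must have hyperintense vessels above all other classes")
  extent <- dims * spacing
  if (any(c(vessel_radii, nerve_radius) >= min(extent) / 2))
    stop("tube radius must be below half the grid extent")
  if (is.null(true_rigid)) {
    ax <- c(0.3, 1, 0.5); ax <- ax / sqrt(sum(ax^2))
    true_rigid <- rigid_from_params(c(ax * (4 * pi / 180),
                                      c(1.2, -0.8, 0.6)),
                                    center = extent / 2)
  }
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 ciss_means = ciss_means, tof_means = tof_means,
                 ciss_sigma = ciss_sigma, tof_sigma = tof_sigma,
                 noise = noise, vessel_radii = vessel_radii,
                 nerve_radius = nerve_radius, nerve_gap = nerve_gap,
                 flow_void = flow_void, pulsation = pulsation,
                 edge = edge,
                 true_rigid = true_rigid, seed = as.integer(seed)),
            class = "nvc_phantom_spec")
}

# Analytic geometry in world mm: centerlines, radii, cistern box.
phantom_geometry <- function(spec) {
  E <- spec$dims * spec$spacing
  bx <- 0.62 * E[1]; by <- 0.50 * E[2]       # brainstem axis (x, y)
  Rb <- 0.18 * min(E[1], E[2])               # brainstem radius
  zlo <- 0.06 * E[3]; zhi <- 0.94 * E[3]

  brainstem <- cbind(bx, by, c(zlo, zhi))

  # trunk: vertical vessel hugging the anterior brainstem surface
  rt <- spec$vessel_radii[["trunk"]]
  tseq <- seq(0, 1, length.out = 33)
  trunk <- cbind(bx - (Rb + rt + 0.3),
                 by + 0.05 * E[2] * sin(pi * tseq),
                 zlo + tseq * (zhi - zlo))

  # nerve: radial root at angle th_n, mid-height
  rn <- spec$nerve_radius
  th_n <- 0.65 * pi
  zn <- 0.5 * E[3]
  nlen <- 4.0
  sseq <- seq(0, 1, length.out = 9)
  nerve <- cbind(bx + cos(th_n) * (Rb + sseq * nlen),
                 by + sin(th_n) * (Rb + sseq * nlen),
                 zn)

  # loop: tangential arc around the brainstem passing directly over the
  # nerve at a controlled axial clearance
  rl <- spec$vessel_radii[["loop"]]
  dz <- rl + rn + spec$nerve_gap
  th <- seq(pi, 0.3 * pi, length.out = 49)
  rho <- Rb + 1.2 + rl
  loop <- cbind(bx + cos(th) * rho, by + sin(th) * rho, zn + dz)

  list(extent = E,
       cistern = rbind(0.06 * E, 0.94 * E),
       brainstem = brainstem, brainstem_radius = Rb,
       trunk = trunk, trunk_radius = rt,
       loop = loop, loop_radius = rl,
       nerve = nerve, nerve_radius = rn)
}

# Distance from points to a polyline; also returns the normalized arc
# parameter of the nearest segment point.  Points far outside the
# polyline's bounding box (beyond `cut`) get Inf without exact evaluation.
dist_to_polyline <- function(P, C, cut = Inf) {
  if (nrow(C) < 2) stop("degenerate centerline (<2 points)")
  n <- nrow(P)
  d2 <- rep(Inf, n)
  par <- rep(NA_real_, n)
  lo <- apply(C, 2, min) - cut; hi <- apply(C, 2, max) + cut
  cand <- which(P[, 1] >= lo[1] & P[, 1] <= hi[1] &
                P[, 2] >= lo[2] & P[, 2] <= hi[2] &
                P[, 3] >= lo[3] & P[, 3] <= hi[3])
  if (length(cand) == 0) return(list(dist = sqrt(d2), par = par))
  Q <- P[cand, , drop = FALSE]
  qd2 <- rep(Inf, nrow(Q)); qpar <- rep(NA_real_, nrow(Q))
  nseg <- nrow(C) - 1
  for (s in seq_len(nseg)) {
    a <- C[s, ]; b <- C[s + 1, ]; ab <- b - a
    L2 <- sum(ab^2)
    t <- if (L2 < 1e-12) rep(0, nrow(Q)) else
      ((Q[, 1] - a[1]) * ab[1] + (Q[, 2] - a[2]) * ab[2] +
         (Q[, 3] - a[3]) * ab[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- Q[, 1] - (a[1] + t * ab[1])
    dy <- Q[, 2] - (a[2] + t * ab[2])
    dz <- Q[, 3] - (a[3] + t * ab[3])
    dd <- dx * dx + dy * dy + dz * dz
    upd <- dd < qd2
    qd2[upd] <- dd[upd]
    qpar[upd] <- (s - 1 + t[upd]) / nseg
  }
  d2[cand] <- qd2; par[cand] <- qpar
  list(dist = sqrt(d2), par = par)
}

# Distances/arc-parameters of world points to every phantom structure.
phantom_distances <- function(P, geom) {
  list(bs = dist_to_polyline(P, geom$brainstem,
                             cut = geom$brainstem_radius + 2),
       nv = dist_to_polyline(P, geom$nerve, cut = geom$nerve_radius + 2),
       tr = dist_to_polyline(P, geom$trunk, cut = geom$trunk_radius + 2),
       lp = dist_to_polyline(P, geom$loop, cut = geom$loop_radius + 2))
}

# Hard per-point classification (label-id convention: 0 background,
# 1 csf, 2 brainstem, 3 nerve, 4 vessel) by voxel-center membership;
# this defines the ground-truth masks.
classify_points <- function(P, geom, D = phantom_distances(P, geom)) {
  n <- nrow(P)
  cls <- integer(n)                        # 0 = background
  inbox <- P[, 1] >= geom$cistern[1, 1] & P[, 1] <= geom$cistern[2, 1] &
           P[, 2] >= geom$cistern[1, 2] & P[, 2] <= geom$cistern[2, 2] &
           P[, 3] >= geom$cistern[1, 3] & P[, 3] <= geom$cistern[2, 3]
  cls[inbox] <- 1L                         # csf
  cls[D$bs$dist <= geom$brainstem_radius] <- 2L
  cls[D$nv$dist <= geom$nerve_radius] <- 3L
  in_trunk <- D$tr$dist <= geom$trunk_radius
  in_loop <- D$lp$dist <= geom$loop_radius
  cls[in_trunk | in_loop] <- 4L            # vessel: highest priority
  list(class = cls,
       trunk_par = ifelse(in_trunk, D$tr$par, NA_real_),
       loop_par = ifelse(in_loop, D$lp$par, NA_real_),
       in_trunk = in_trunk, in_loop = in_loop)
}

# Linear edge ramp: 1 at signed depth >= w/2 inside, 0 at >= w/2 outside.
edge_ramp <- function(depth, w) {
  if (w <= 0) return(as.numeric(depth >= 0))
  pmin(pmax(depth / w + 0.5, 0), 1)
}

# Soft (partial-volume) intensity synthesis.  Structures are painted in
# priority order with an edge ramp of width `edge` mm, mimicking the
# scanner point-spread function; without it the images are aliased
# staircases carrying no subvoxel information, and the MI optimum can sit
# visibly off the true transform.  `void_shift` remaps the vessel paint
# intensity along flow-void arcs (CISS only).
synth_intensity <- function(P, geom, means, edge, D,
                            flow_void = list(),
                            brainstem_mean = NULL) {
  # depth inside the cistern box: smallest distance to any face
  depth_box <- pmin(P[, 1] - geom$cistern[1, 1], geom$cistern[2, 1] - P[, 1],
                    P[, 2] - geom$cistern[1, 2], geom$cistern[2, 2] - P[, 2],
                    P[, 3] - geom$cistern[1, 3], geom$cistern[2, 3] - P[, 3])
  I <- rep(means[["background"]], nrow(P))
  mix <- function(I, paint, a) I * (1 - a) + paint * a
  I <- mix(I, means[["csf"]], edge_ramp(depth_box, edge))
  I <- mix(I, means[["brainstem"]],
           edge_ramp(geom$brainstem_radius - D$bs$dist, edge))
  I <- mix(I, means[["nerve"]], edge_ramp(geom$nerve_radius - D$nv$dist, edge))
  vessel_paint <- function(par, vessel) {
    paint <- rep(means[["vessel"]], length(par))
    for (fv in flow_void) {
      if (fv$vessel != vessel) next
      hit <- !is.na(par) & par >= fv$arc[1] & par <= fv$arc[2]
      paint[hit] <- (1 - fv$factor) * paint[hit] +
        fv$factor * brainstem_mean
    }
    paint
  }
  I <- mix(I, vessel_paint(D$tr$par, "trunk"),
           edge_ramp(geom$trunk_radius - D$tr$dist, edge))
  I <- mix(I, vessel_paint(D$lp$par, "loop"),
           edge_ramp(geom$loop_radius - D$lp$dist, edge))
  I
}

add_noise <- function(x, sigma, kind) {
  if (sigma <= 0) return(x)
  if (kind == "gaussian") {
    x + rnorm(length(x), 0, sigma)
  } else {
    sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
  }
}

# Ordered unique voxel path (1-based) for a densely resampled centerline.
centerline_voxels <- function(vol, C, n = 400) {
  s <- seq(0, 1, length.out = nrow(C))
  ss <- seq(0, 1, length.out = n)
  W <- cbind(approx(s, C[, 1], ss)$y, approx(s, C[, 2], ss)$y,
             approx(s, C[, 3], ss)$y)
  V <- round(world_to_voxel(vol, W))
  keep <- !duplicated(V)
  V <- V[keep, , drop = FALSE]
  storage.mode(V) <- "integer"
  attr(V, "par") <- ss[keep]     # arc parameter of each retained voxel
  V
}

#' Generate a paired CISS-like / TOF-like phantom with ground truth
#'
#' Rasterizes the analytic geometry on the CISS grid, applies the CISS
#' artifacts (flow-void attenuation along configured vessel arcs, CSF
#' pulsation speckle near the upper trunk), then evaluates the same
#' anatomy on a grid displaced by the spec's true rigid transform to
#' produce the TOF volume, and finally adds per-modality noise.  The same
#' seed always yields bytewise identical output.
#'
#' @param spec a [phantom_spec()].
#' @return `list(ciss = , tof = , truth = )`.  `truth` carries disjoint
#'   class masks, ordered centerline voxel paths for the two vessels, the
#'   true rigid transform, the contact flag and contact voxel set between
#'   vessel and nerve, and the per-vessel set of flow-void centerline
#'   voxels.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "nvc_phantom_spec"))
  geom <- phantom_geometry(spec)
  dims <- spec$dims

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  affine <- diag(c(spec$spacing, 1))
  template <- nvc_volume(array(0, dims), spacing = spec$spacing,
                         affine = affine)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  P <- voxel_to_world(template, idx)

  D <- phantom_distances(P, geom)
  cf <- classify_points(P, geom, D)
  ciss_clean <- synth_intensity(P, geom, spec$ciss_means, spec$edge, D,
                                flow_void = spec$flow_void,
                                brainstem_mean = spec$ciss_means[["brainstem"]])

  # pulsation speckle: vessel-range dots in the CSF near the upper trunk
  if (!is.null(spec$pulsation)) {
    tx <- geom$trunk[1, 1]
    box_lo <- c(tx - 4, geom$cistern[1, 2], 0.60 * geom$extent[3])
    box_hi <- c(tx + 6, geom$cistern[2, 2], 0.90 * geom$extent[3])
    in_box <- cf$class == 1L &
      P[, 1] >= box_lo[1] & P[, 1] <= box_hi[1] &
      P[, 2] >= box_lo[2] & P[, 2] <= box_hi[2] &
      P[, 3] >= box_lo[3] & P[, 3] <= box_hi[3]
    cand <- which(in_box)
    pick <- cand[runif(length(cand)) < spec$pulsation$density]
    ciss_clean[pick] <- spec$ciss_means[["vessel"]] +
      runif(length(pick), -spec$pulsation$amplitude,
            spec$pulsation$amplitude)
  }

  ciss_data <- array(add_noise(ciss_clean, spec$ciss_sigma, spec$noise), dims)
  ciss <- nvc_volume(ciss_data, spacing = spec$spacing, affine = affine,
                     modality = "CISS")

  # TOF: the same anatomy seen through the displaced acquisition frame
  # (no flow voids: TOF renders flowing blood bright, not void)
  Ptof <- apply_rigid(spec$true_rigid, P)
  Dt <- phantom_distances(Ptof, geom)
  tof_clean <- synth_intensity(Ptof, geom, spec$tof_means, spec$edge, Dt)
  tof_data <- array(add_noise(tof_clean, spec$tof_sigma, spec$noise), dims)
  tof <- nvc_volume(tof_data, spacing = spec$spacing, affine = affine,
                    modality = "TOF")

  masks <- list(
    csf = array(cf$class == 1L, dims),
    brainstem = array(cf$class == 2L, dims),
    nerve = array(cf$class == 3L, dims),
    vessel = array(cf$class == 4L, dims))

  cl_trunk <- centerline_voxels(template, geom$trunk)
  cl_loop <- centerline_voxels(template, geom$loop)

  # flow-void status of each centerline voxel
  void_of <- function(cl, vessel) {
    if (nrow(cl) == 0) return(logical(0))
    par <- attr(cl, "par")
    out <- rep(FALSE, nrow(cl))
    for (fv in spec$flow_void)
      if (fv$vessel == vessel)
        out <- out | (par >= fv$arc[1] & par <= fv$arc[2])
    out
  }

  contact <- masks$vessel & dilate1(masks$nerve, 26)
  truth <- list(masks = masks,
                centerlines = list(trunk = cl_trunk, loop = cl_loop),
                void = list(trunk = void_of(cl_trunk, "trunk"),
                            loop = void_of(cl_loop, "loop")),
                true_rigid = spec$true_rigid,
                contact = any(contact),
                contact_voxels = which(contact, arr.ind = TRUE),
                geometry = geom)
  list(ciss = ciss, tof = tof, truth = truth)
}

#' Phantom with controlled vessel-nerve contact
#'
#' Places the loop vessel either in direct contact with the nerve root
#' (sharing a 26-neighbourhood interface with no CSF voxel in between) or
#' separated from it by a CSF layer at least two voxels thick.
#'
#' @param spec a [phantom_spec()]; its `nerve_gap` is overridden.
#' @param touching logical.
#' @return As [generate_phantom()].
#' @export
contact_phantom <- function(spec = phantom_spec(), touching = TRUE) {
  gap <- if (touching) -0.25 else 3 * max(spec$spacing)
  spec$nerve_gap <- gap
  generate_phantom(spec)
}
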