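# Rigid CISS <-> TOF alignment: closed-form landmark initialization,
# mutual-information refinement over a Gaussian resolution pyramid with a
# derivative-free simplex optimizer, and trilinear reformatting of the
# moving volume onto the fixed grid.

#' Closed-form least-squares rigid fit to paired landmarks
#'
#' Kabsch/Umeyama solution via the SVD of the cross-covariance matrix,
#' with the reflection branch excluded (determinant forced to +1).
#' Minimizes `sum || fixed_i - (R moving_i + t) ||^2` over rotations.
#'
#' @param fixed_pts,moving_pts n x 3 matrices of corresponding world-mm
#'   points, n >= 3, not collinear.
#' @return An [rigid_transform()] mapping moving into fixed coordinates,
#'   with the root-mean-square residual attached as attribute `"rms"`.
#' @export
landmark_rigid <- function(fixed_pts, moving_pts) {
  F <- matrix(as.numeric(fixed_pts), ncol = 3)
  M <- matrix(as.numeric(moving_pts), ncol = 3)
  if (nrow(F) != nrow(M)) stop("landmark sets must be paired")
  if (nrow(F) < 3) stop("need at least 3 landmark pairs")
  fc <- colMeans(F); mc <- colMeans(M)
  Fc <- sweep(F, 2, fc); Mc <- sweep(M, 2, mc)
  svF <- svd(Fc)$d; svM <- svd(Mc)$d
  if (svF[2] < 1e-9 * max(svF[1], 1) || svM[2] < 1e-9 * max(svM[1], 1))
    stop("degenerate landmark set (collinear points)")
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- fc - as.numeric(R %*% mc)
  T <- rigid_transform(R, t)
  res <- F - apply_rigid(T, M)
  attr(T, "rms") <- sqrt(mean(rowSums(res^2)))
  T
}

#' Options for mutual-information registration
#'
#' @param bins joint-histogram bin count per axis (>= 8).
#' @param pyramid_levels number of resolution levels (>= 1); level `l`
#'   samples the fixed grid at stride `2^(l-1)` after Gaussian smoothing.
#' @param sampling fraction of fixed voxels sampled at the finest level
#'   (coarser levels sample densely).
#' @param max_iter simplex iteration budget per level.
#' @param reltol optimizer relative tolerance.
#' @param normalized use normalized MI `(H(F)+H(M))/H(F,M)` instead of
#'   plain MI.
#' @param seed RNG seed for the stratified sampling.
#' @return `nvc_mi_options` list.
#' @export
mi_options <- function(bins = 64, pyramid_levels = 3, sampling = 0.25,
                       max_iter = 400, reltol = 1e-9, normalized = FALSE,
                       seed = 99L) {
  if (bins < 8) stop("bins must be >= 8")
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (sampling <= 0 || sampling > 1) stop("sampling must be in (0, 1]")
  structure(list(bins = as.integer(bins),
                 pyramid_levels = as.integer(pyramid_levels),
                 sampling = sampling, max_iter = as.integer(max_iter),
                 reltol = reltol, normalized = isTRUE(normalized),
                 seed = as.integer(seed)),
            class = "nvc_mi_options")
}

# Separable Gaussian smoothing (voxel units), truncated at 2.5 sigma.
gaussian_smooth <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(2.5 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2)); w <- w / sum(w)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    for (i in seq_along(w)) {
      sh <- c(0, 0, 0); sh[ax] <- i - r - 1
      out <- out + w[i] * shift3(a, sh[1], sh[2], sh[3], 0)
    }
    # renormalize near the borders where the kernel is truncated
    nrm <- array(0, dim(a))
    ones <- array(1, dim(a))
    for (i in seq_along(w)) {
      sh <- c(0, 0, 0); sh[ax] <- i - r - 1
      nrm <- nrm + w[i] * shift3(ones, sh[1], sh[2], sh[3], 0)
    }
    a <- out / nrm
  }
  a
}

# Entropy in bits of a count vector/matrix.
entropy_bits <- function(cnt) {
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Joint-histogram MI between paired samples, binned over fixed ranges.
# With `pv = TRUE` the moving value's mass is shared linearly between its
# two neighbouring bins (partial-volume style), which makes the estimate
# differentiable in the transform parameters; the plain hard-binned form
# is the package's contract definition of MI.
mi_from_samples <- function(fv, mv, f_range, m_range, bins,
                            normalized = FALSE, pv = FALSE) {
  fb <- pmin(pmax(floor((fv - f_range[1]) / diff(f_range) * bins) + 1, 1),
             bins)
  if (pv) {
    u <- pmin(pmax((mv - m_range[1]) / diff(m_range) * bins + 0.5, 1), bins)
    b0 <- pmin(as.integer(floor(u)), bins - 1L)
    jm <- cpp_whist2(as.integer(fb), b0, u - b0, bins)
  } else {
    mb <- pmin(pmax(floor((mv - m_range[1]) / diff(m_range) * bins) + 1, 1),
               bins)
    joint <- tabulate(fb + bins * (mb - 1L), nbins = bins * bins)
    jm <- matrix(joint, bins, bins)
  }
  Hf <- entropy_bits(rowSums(jm))
  Hm <- entropy_bits(colSums(jm))
  Hj <- entropy_bits(jm)
  if (normalized) (Hf + Hm) / max(Hj, .Machine$double.eps)
  else Hf + Hm - Hj
}

# Sample indices of the fixed grid: stride-decimated, then a seeded
# random subset of the requested fraction.
sample_fixed_indices <- function(dims, stride, fraction, seed) {
  gi <- seq(1L, dims[1], by = stride)
  gj <- seq(1L, dims[2], by = stride)
  gk <- seq(1L, dims[3], by = stride)
  idx <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
  if (fraction < 1) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    keep <- sample.int(nrow(idx),
                       size = min(nrow(idx),
                                  max(1000L, round(fraction * nrow(idx)))))
    idx <- idx[sort(keep), , drop = FALSE]
  }
  idx
}

# Composite 3 x 4 map taking 0-based fixed voxel indices to continuous
# 0-based moving voxel coordinates under T (moving -> fixed in world).
sampling_matrix <- function(fixed_vol, moving_vol, T) {
  Tm <- rbind(cbind(T$rotation, T$translation), c(0, 0, 0, 1))
  B <- solve(moving_vol$affine) %*% solve(Tm) %*% fixed_vol$affine
  B[1:3, , drop = FALSE]
}

# Core MI evaluation.  `idx0` is a precomputed n x 3 double matrix of
# 0-based fixed voxel indices, `fv` the fixed intensities at those voxels,
# `moving_arr` a bare double array.  Returns NA on empty overlap.
mi_eval <- function(fv, idx0, fixed_vol, moving_arr, moving_vol, T,
                    f_range, m_range, bins, normalized, pv = FALSE) {
  B <- sampling_matrix(fixed_vol, moving_vol, T)
  mv <- cpp_affine_trilinear(moving_arr, dim(moving_arr), idx0, B)
  keep <- !is.na(mv)
  if (!any(keep)) return(NA_real_)
  mi_from_samples(fv[keep], mv[keep], f_range, m_range, bins, normalized,
                  pv = pv)
}

#' Mutual information between two volumes under a rigid transform
#'
#' `MI = H(F) + H(M) - H(F, M)` in bits, from the joint histogram of fixed
#' intensities against trilinearly resampled moving intensities over the
#' overlapping field of view; samples falling outside the moving volume
#' are excluded.
#'
#' @param fixed,moving [nvc_volume()] objects.
#' @param T an [rigid_transform()] mapping moving world into fixed world.
#' @param opt an [mi_options()] object; `sampling = 1` evaluates every
#'   fixed voxel.
#' @return MI in bits (scalar).
#' @export
mutual_information <- function(fixed, moving, T = rigid_transform(),
                               opt = mi_options(sampling = 1)) {
  idx <- sample_fixed_indices(dim(fixed$data), 1L, opt$sampling, opt$seed)
  fv <- fixed$data[idx]
  idx0 <- idx - 1; storage.mode(idx0) <- "double"
  ma <- fixed_double(moving$data)
  mi <- mi_eval(fv, idx0, fixed, ma, moving, T,
                range(fixed$data), range(moving$data), opt$bins,
                opt$normalized)
  if (is.na(mi)) stop("empty overlap between the two fields of view")
  mi
}

# strip attributes once so Rcpp takes the vector without copying
fixed_double <- function(a) {
  v <- as.vector(a)
  storage.mode(v) <- "double"
  dim(v) <- dim(a)
  v
}

#' Rigid registration by mutual-information maximization
#'
#' Refines an initial transform (typically from [landmark_rigid()])
#' coarse-to-fine over a Gaussian resolution pyramid, maximizing the
#' mutual information with a Nelder-Mead simplex over the 6 rigid
#' parameters (axis-angle rotation about the fixed-volume center plus
#' translation).  The result never degrades the initializer: if the
#' optimizer ends below the initial MI, the initializer is returned with
#' `converged = FALSE`.
#'
#' @param fixed,moving [nvc_volume()] objects.
#' @param init initial [rigid_transform()].
#' @param opt an [mi_options()] object.
#' @return An `nvc_rigid` with attributes `mi`, `mi_init` and `converged`.
#' @export
register_volumes <- function(fixed, moving, init = rigid_transform(),
                             opt = mi_options()) {
  center <- world_center(fixed)
  f_range <- range(fixed$data)
  m_range <- range(moving$data)

  # initial parameters relative to the center-of-rotation convention
  rv <- rotation_to_vector(init$rotation)
  tau <- init$translation - (center - as.numeric(init$rotation %*% center))
  par <- c(rv, tau)

  for (lev in seq(opt$pyramid_levels, 1)) {
    stride <- 2L^(lev - 1L)
    sigma <- if (stride > 1L) stride / 2 else 0
    fa <- gaussian_smooth(fixed$data, sigma)
    ma <- fixed_double(gaussian_smooth(moving$data, sigma))
    # coarsest level: dense; finer levels: the configured fraction
    frac <- if (lev == opt$pyramid_levels) 1 else opt$sampling
    idx <- sample_fixed_indices(dim(fixed$data), stride, frac,
                                opt$seed + lev)
    fv <- fa[idx]
    idx0 <- idx - 1; storage.mode(idx0) <- "double"
    obj <- function(p) {
      mi <- mi_eval(fv, idx0, fixed, ma, moving,
                    rigid_from_params(p, center),
                    f_range, m_range, opt$bins, opt$normalized,
                    pv = TRUE)
      if (is.na(mi)) return(1e6)
      -mi
    }
    # simplex scale shrinks with the pyramid: wide exploration at the
    # coarse level, sub-voxel refinement at the finest
    scl <- c(rep(0.15, 3), rep(4, 3)) * stride / 2^(opt$pyramid_levels - 1)
    fit <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = opt$max_iter, reltol = opt$reltol,
                                parscale = scl))
    par <- fit$par
  }

  result <- rigid_from_params(par, center)
  mi_opts_full <- mi_options(bins = opt$bins, pyramid_levels = 1,
                             sampling = opt$sampling, seed = opt$seed,
                             normalized = opt$normalized)
  mi_res <- mutual_information(fixed, moving, result, mi_opts_full)
  mi_init <- mutual_information(fixed, moving, init, mi_opts_full)
  if (mi_res < mi_init) {
    out <- init
    attr(out, "mi") <- mi_init
    attr(out, "mi_init") <- mi_init
    attr(out, "converged") <- FALSE
    warning("optimizer did not improve on the initializer; returning init")
    return(out)
  }
  attr(result, "mi") <- mi_res
  attr(result, "mi_init") <- mi_init
  attr(result, "converged") <- TRUE
  result
}

# Axis-angle vector (radians) from a rotation matrix (inverse Rodrigues).
rotation_to_vector <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  th <- acos(pmin(pmax(c_, -1), 1))
  if (th < 1e-10) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near half-turn: extract axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    if (ax[1] > 0) { ax[2] <- B[1, 2] / ax[1] * sign(1); ax[3] <- B[1, 3] / ax[1] }
    ax <- ax / sqrt(sum(ax^2))
    return(ax * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  ax * th
}

#' Reformat the moving volume onto the fixed grid
#'
#' Trilinear interpolation at the fixed voxel centers mapped through the
#' inverse transform; points outside the moving field of view get 0.  The
#' output shares dims, spacing and affine with `fixed_grid`.
#'
#' @param moving an [nvc_volume()].
#' @param fixed_grid `nvc_volume` supplying the target grid.
#' @param T [rigid_transform()] mapping moving world into fixed world.
#' @return Resampled `nvc_volume` (modality preserved from `moving`).
#' @export
reformat <- function(moving, fixed_grid, T = rigid_transform()) {
  dims <- dim(fixed_grid$data)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  world <- voxel_to_world(fixed_grid, idx)
  mw <- apply_rigid(rigid_inverse(T), world)
  mvx <- world_to_voxel(moving, mw) - 1
  vals <- cpp_trilinear(as.double(moving$data),
                        as.integer(dim(moving$data)), mvx, 0)
  nvc_volume(array(vals, dims), spacing = fixed_grid$spacing,
             affine = fixed_grid$affine, modality = moving$modality)
}
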