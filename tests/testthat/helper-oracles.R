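# Independent brute-force oracles.  These deliberately re-derive each
# operation with the dumbest possible implementation so the package code
# is checked against something it shares no path with.

# Exhaustive flood fill: fixpoint iteration over all voxel pairs.
oracle_flood_fill <- function(a, seeds, lower, upper, connectivity,
                              bbox_lo = c(1, 1, 1), bbox_hi = dim(a)) {
  d <- dim(a)
  ok <- function(i, j, k) {
    i >= bbox_lo[1] && i <= bbox_hi[1] && j >= bbox_lo[2] &&
      j <= bbox_hi[2] && k >= bbox_lo[3] && k <= bbox_hi[3] &&
      a[i, j, k] >= lower && a[i, j, k] <= upper
  }
  mask <- array(FALSE, d)
  for (s in seq_len(nrow(seeds)))
    mask[seeds[s, 1], seeds[s, 2], seeds[s, 3]] <- TRUE
  repeat {
    changed <- FALSE
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (mask[i, j, k]) next
      if (!ok(i, j, k)) next
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
        ii <- i + dx; jj <- j + dy; kk <- k + dz
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
            kk > d[3]) next
        if (mask[ii, jj, kk]) { mask[i, j, k] <- TRUE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  mask
}

# Naive grey dilation/erosion/closing with explicit loops.
oracle_morph <- function(a, radius, op) {
  d <- dim(a)
  out <- array(NA_real_, d)
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                     dz = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, ]
  pad <- if (op == "max") -Inf else Inf
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    vals <- pad
    for (r in seq_len(nrow(off))) {
      ii <- i + off$dx[r]; jj <- j + off$dy[r]; kk <- k + off$dz[r]
      v <- if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
               kk > d[3]) pad else a[ii, jj, kk]
      vals <- if (op == "max") max(vals, v) else min(vals, v)
    }
    out[i, j, k] <- vals
  }
  out
}

oracle_closing <- function(a, radius = 1) {
  oracle_morph(oracle_morph(a, radius, "max"), radius, "min")
}

# One dense Perona-Malik step with explicit loops (flux form, Neumann).
oracle_diffusion_step <- function(a, kappa, dt) {
  d <- dim(a)
  out <- a
  g <- function(s) exp(-(s / kappa)^2)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    nb <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
    for (o in nb) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
          kk > d[3]) next            # zero flux across the boundary
      dv <- a[ii, jj, kk] - a[i, j, k]
      acc <- acc + g(abs(dv)) * dv
    }
    out[i, j, k] <- a[i, j, k] + dt * acc
  }
  out
}

# MI of paired discrete samples by direct probability enumeration.
oracle_mi <- function(f, m) {
  tab <- table(f, m)
  p <- tab / sum(tab)
  pf <- rowSums(p); pm <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pf[i] * pm[j]))
  unname(mi)
}

# Pearson chi-square by explicit expected-count loop.
oracle_chisq <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    E <- rs[i] * cs[j] / N
    stat <- stat + (tab[i, j] - E)^2 / E
  }
  unname(stat)
}

# Closed-form front-to-back compositing of two homogeneous slabs.
oracle_two_slabs <- function(a1, c1, a2, c2) {
  list(color = c1 * a1 + c2 * a2 * (1 - a1), alpha = a1 + a2 * (1 - a1))
}

# Ordinal score from the published-scale threshold table (independent of
# the package's coverage_to_score).
oracle_score_table <- function(c_all, c_prox, c_dist) {
  if (c_all == 0) 0L
  else if (c_all >= 0.95) 5L
  else if (c_prox >= 0.8 && c_dist < 0.5) 3L
  else if (c_all >= 0.5) 4L
  else if (c_all >= 0.25) 2L
  else 1L
}

# Shared fixture: two homogeneous axis-aligned slabs rendered head-on.
two_slab_render <- function(a1, a2, step) {
  d <- c(40, 16, 16)
  a <- array(0, d)
  a[5:12, , ] <- 1      # slab 1 (hit first by the +x ray)
  a[20:27, , ] <- 2     # slab 2
  v <- nvc_volume(a, spacing = c(1, 1, 1))
  lab <- array(0L, d); lab[a == 1] <- 1L; lab[a == 2] <- 2L
  lv <- nvc_label_volume(lab, legend = c(REST = 0L, S1 = 1L, S2 = 2L),
                         template = v)
  tf <- transfer_function(list(
    `0` = list(color = c(0, 0, 0), intensity = 0, opacity = 0),
    `1` = list(color = c(1, 0, 0), intensity = 0, opacity = a1),
    `2` = list(color = c(0, 0, 1), intensity = 0, opacity = a2)))
  cam <- camera(direction = c(1, 0, 0), up = c(0, 0, 1),
                image_size = c(9, 9), window_mm = c(8, 8), step = step)
  render_volume(v, lv, tf, cam)
}

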