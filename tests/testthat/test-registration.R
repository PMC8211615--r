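rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("landmark fit recovers exact transforms and rejects degeneracy", {
  set.seed(41)
  pts <- matrix(runif(15, -10, 10), 5, 3)
  # identical sets -> identity
  T0 <- landmark_rigid(pts, pts)
  expect_lt(max(abs(T0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(T0$translation)), 1e-9)

  # known rotation + translation, exact recovery
  R <- rot_z(30); t <- c(1, 2, 3)
  moved <- pts %*% t(R) + matrix(t, 5, 3, byrow = TRUE)
  Tr <- landmark_rigid(moved, pts)        # fixed = moved, moving = pts
  expect_lt(max(abs(Tr$rotation - R)), 1e-9)
  expect_lt(max(abs(Tr$translation - t)), 1e-9)
  expect_lt(attr(Tr, "rms"), 1e-9)

  # reflection-only correspondence: det stays +1, residual positive
  mirrored <- pts %*% diag(c(-1, 1, 1))
  Tm <- landmark_rigid(mirrored, pts)
  expect_equal(det(Tm$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(Tm, "rms"), 0.1)

  # collinear points
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_rigid(line, line), "degenerate landmark set")
  expect_error(landmark_rigid(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("rigid transform objects validate and compose correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "proper")
  T <- nvcfuse:::rigid_from_params(c(0.1, -0.2, 0.15, 1, 2, 3),
                                   center = c(5, 5, 5))
  p <- matrix(rnorm(9), 3)
  back <- apply_rigid(rigid_inverse(T), apply_rigid(T, p))
  expect_equal(back, p, tolerance = 1e-12)
  rv <- c(0.05, 0.1, -0.07)
  expect_equal(nvcfuse:::rotation_to_vector(
    nvcfuse:::rotation_from_vector(rv)), rv, tolerance = 1e-10)
})

test_that("MI of a volume with itself is its marginal entropy", {
  set.seed(42)
  v <- nvc_volume(array(rnorm(10^3), c(10, 10, 10)))
  mi <- mutual_information(v, v, rigid_transform(),
                           mi_options(bins = 16, sampling = 1))
  x <- as.vector(v$data)
  b <- pmin(floor((x - min(x)) / (max(x) - min(x)) * 16) + 1, 16)
  H <- -sum(prop.table(table(b)) * log2(prop.table(table(b))))
  expect_equal(mi, H, tolerance = 1e-12)
})

test_that("MI matches a hand-enumerable joint histogram on two-valued volumes", {
  # quadrant pattern: fixed splits left/right, moving splits front/back
  d <- c(8, 8, 8)
  f <- array(0, d); f[5:8, , ] <- 1
  m <- array(0, d); m[, 5:8, ] <- 1
  vf <- nvc_volume(f); vm <- nvc_volume(m)
  mi <- mutual_information(vf, vm, rigid_transform(),
                           mi_options(bins = 8, sampling = 1))
  expect_equal(mi, oracle_mi(as.vector(f), as.vector(m)), tolerance = 1e-12)
  expect_equal(mi, 0, tolerance = 1e-12)   # independent quadrants

  # correlated case: moving = fixed -> MI = 1 bit
  mi2 <- mutual_information(vf, vf, rigid_transform(),
                            mi_options(bins = 8, sampling = 1))
  expect_equal(mi2, oracle_mi(as.vector(f), as.vector(f)),
               tolerance = 1e-12)
  expect_equal(mi2, 1, tolerance = 1e-12)
})

test_that("MI of independent random volumes is near zero and never negative", {
  set.seed(43)
  a <- nvc_volume(array(runif(20^3), c(20, 20, 20)))
  b <- nvc_volume(array(runif(20^3), c(20, 20, 20)))
  mi <- mutual_information(a, b, rigid_transform(),
                           mi_options(bins = 16, sampling = 1))
  expect_gte(mi, 0)
  expect_lt(mi, 0.05)
})

test_that("MI is symmetric under swapping roles with the inverse transform", {
  # exact symmetry whenever samples land on grid points (no resampling
  # blur): identity and whole-voxel translations
  ph <- small_phantom()
  opt <- mi_options(bins = 32, sampling = 1)
  a <- mutual_information(ph$ciss, ph$tof, rigid_transform(), opt)
  b <- mutual_information(ph$tof, ph$ciss, rigid_transform(), opt)
  expect_equal(a, b, tolerance = 1e-12)

  Tv <- rigid_transform(translation = c(0.8, -0.4, 0.4))  # whole voxels
  a2 <- mutual_information(ph$ciss, ph$tof, Tv, opt)
  b2 <- mutual_information(ph$tof, ph$ciss, rigid_inverse(Tv), opt)
  expect_equal(a2, b2, tolerance = 1e-6)
  expect_gte(a2, 0)

  expect_error(mutual_information(ph$ciss, ph$tof,
                                  rigid_transform(translation = c(1e4, 0, 0))),
               "empty overlap")
})

test_that("reformat is exact on identity and on affine ramps", {
  ph <- small_phantom()
  same <- reformat(ph$ciss, ph$ciss, rigid_transform())
  expect_equal(same$data, ph$ciss$data, tolerance = 1e-12)

  # trilinear interpolation reproduces a linear ramp exactly under a
  # half-voxel shift (interior)
  d <- c(10, 10, 10)
  ramp <- array(0, d)
  for (i in 1:d[1]) ramp[i, , ] <- i
  v <- nvc_volume(ramp, spacing = c(1, 1, 1))
  T <- rigid_transform(translation = c(0.5, 0, 0))
  out <- reformat(v, v, T)
  interior <- 2:9
  # moving sampled at x - 0.5 -> values shifted down by half a voxel
  expect_equal(out$data[interior, 3, 3], ramp[interior, 3, 3] - 0.5,
               tolerance = 1e-12)

  # output grid always matches the fixed grid
  T2 <- nvcfuse:::rigid_from_params(c(0.2, 0.1, 0, 3, -2, 1))
  out2 <- reformat(ph$tof, ph$ciss, T2)
  expect_identical(dim(out2$data), dim(ph$ciss$data))
  expect_identical(out2$affine, ph$ciss$affine)
})

test_that("registration refines a landmark init and never degrades it", {
  ph <- small_phantom()
  ctr <- nvcfuse:::world_center(ph$ciss)
  truth <- ph$truth$true_rigid

  # init at truth: result keeps MI at least as high, parameters close
  opt <- mi_options(pyramid_levels = 2, sampling = 0.2, max_iter = 150,
                    seed = 7)
  T <- register_volumes(ph$ciss, ph$tof, truth, opt)
  expect_gte(attr(T, "mi"), attr(T, "mi_init"))
  err <- rigid_error(T, truth, ref_point = ctr)
  expect_lt(err["rot_deg"], 1.0)
  expect_lt(err["trans_mm"], 0.25)

  # moving == fixed: identity recovered
  Ti <- register_volumes(ph$ciss, ph$ciss, rigid_transform(),
                         mi_options(pyramid_levels = 2, sampling = 0.2,
                                    max_iter = 100, seed = 8))
  ei <- rigid_error(Ti, rigid_transform(), ref_point = ctr)
  expect_lt(ei["rot_deg"], 0.5)
  expect_lt(ei["trans_mm"], 0.2)
})
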