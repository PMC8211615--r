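test_that("an all-transparent transfer function renders pure background", {
  ph <- small_phantom()
  lv <- nvc_label_volume(array(0L, dim(ph$ciss$data)), template = ph$ciss)
  tf <- transfer_function(list(`0` = list(color = c(0, 0, 0),
                                          intensity = 0, opacity = 0)))
  r <- render_volume(ph$ciss, lv, tf,
                     named_camera("ap", image_size = c(48, 48)))
  expect_true(all(r$rgb == 0))
  expect_true(all(r$alpha == 0))
})

test_that("a single opaque voxel projects to a localized red spot", {
  d <- c(24, 24, 24)
  a <- array(0, d); a[12, 8, 15] <- 100
  v <- nvc_volume(a, spacing = c(1, 1, 1))
  lab <- array(0L, d); lab[12, 8, 15] <- 4L
  lv <- nvc_label_volume(lab, template = v)
  tf <- transfer_function(list(
    `0` = list(color = c(0, 0, 0), intensity = 0, opacity = 0),
    `4` = list(color = c(1, 0, 0), intensity = 0, opacity = 1)))
  cam <- named_camera("ap", image_size = c(48, 48))
  r <- render_volume(v, lv, tf, cam)
  red <- which(r$rgb[, , 1] > 0.5, arr.ind = TRUE)
  expect_gt(nrow(red), 0)
  expect_true(all(r$rgb[, , 2] < 1e-6))     # pure red, no green/blue
  # the red pixels sit at the voxel's orthographic projection
  w <- voxel_to_world(v, matrix(c(12, 8, 15), 1))
  pr <- camera_project(v, cam, w)
  expect_lt(max(abs(red[, "row"] - pr[1, "row"])), 3)
  expect_lt(max(abs(red[, "col"] - pr[1, "col"])), 3)
})

test_that("two-slab compositing matches the closed form within 1%", {
  # per-sample opacities chosen so that a slab of 8 voxels at step = 1
  # accumulates alpha1/alpha2 overall: alpha_slab = 1 - (1 - a)^8
  a1 <- 1 - (1 - 0.35)^(1 / 8)
  a2 <- 1 - (1 - 0.6)^(1 / 8)
  want <- oracle_two_slabs(0.35, c(1, 0, 0), 0.6, c(0, 0, 1))
  r <- two_slab_render(a1, a2, step = 1)
  center <- c(5, 5)
  got <- c(r$rgb[center[1], center[2], 1], r$rgb[center[1], center[2], 3])
  expect_equal(got[1], want$color[1], tolerance = 0.01)
  expect_equal(got[2], want$color[3], tolerance = 0.01)
  expect_equal(r$alpha[center[1], center[2]], want$alpha, tolerance = 0.01)

  # halving the step changes the result by < 0.5% (convergence)
  r2 <- two_slab_render(a1, a2, step = 0.5)
  expect_lt(abs(r2$rgb[5, 5, 1] - r$rgb[5, 5, 1]), 0.005)
  expect_lt(abs(r2$alpha[5, 5] - r$alpha[5, 5]), 0.005)
})

test_that("accumulated opacity stays in [0, 1] and rays terminate early", {
  ph <- small_phantom()
  cls <- array(0L, dim(ph$ciss$data))
  cls[ph$truth$masks$csf] <- 1L
  cls[ph$truth$masks$brainstem] <- 2L
  cls[ph$truth$masks$nerve] <- 3L
  lv <- nvc_label_volume(cls, template = ph$ciss)
  r <- render_volume(ph$ciss, lv, default_tf(),
                     named_camera("ap", image_size = c(64, 64)))
  expect_gte(min(r$alpha), 0)
  expect_lte(max(r$alpha), 1)
  expect_gt(max(r$alpha), 0.9)   # something opaque was hit
})

test_that("default transfer function follows the atlas color contract", {
  tf <- default_tf()
  leg <- nvc_legend()
  rest <- tf[[as.character(leg[["REST"]])]]
  expect_true(all(rest$opacity == 0))
  vessel <- tf[[as.character(leg[["VESSEL"]])]]
  expect_gt(vessel$color[1], 2 * vessel$color[2])   # red-dominant
  csf <- tf[[as.character(leg[["CSF_VESSEL"]])]]
  # CSF-mean intensity renders transparent, vessel-range content does not
  op_at <- function(e, x) approx(e$intensity, e$opacity, x, rule = 2)$y
  expect_equal(op_at(csf, 1000), 0)
  expect_gt(op_at(csf, 200), 0.5)
  expect_error(camera(direction = c(1, 0, 0), up = c(2, 0, 0)),
               "degenerate camera")
})

test_that("fusion increases red pixels along the vessel projection", {
  sp <- phantom_spec(dims = c(48, 48, 48), seed = 8,
                     flow_void = list(list(vessel = "trunk",
                                           arc = c(0.3, 0.7), factor = 1)))
  ph <- generate_phantom(sp)
  pre <- preprocess_volume(ph$ciss)
  cls <- array(0L, dim(pre$data))
  cls[ph$truth$masks$csf] <- 1L
  cls[ph$truth$masks$brainstem] <- 2L
  cls[ph$truth$masks$nerve] <- 3L
  lv <- nvc_label_volume(cls, template = pre)

  tof_ref <- reformat(ph$tof, pre, ph$truth$true_rigid)
  m <- extract_tof_vessels(tof_ref)
  fz <- fuse(pre, tof_ref, m)
  lv_f <- apply_vessel_label(lv, m)

  cam <- named_camera("ap", image_size = c(96, 96))
  r_ciss <- render_volume(pre, lv, default_tf(), cam)
  r_fus <- render_volume(fz$fused, lv_f, default_tf(), cam)

  # pixels under the true vessel projection
  vx <- which(ph$truth$masks$vessel, arr.ind = TRUE)
  pr <- camera_project(pre, cam, voxel_to_world(pre, vx))
  px <- unique(round(pr))
  px <- px[px[, 1] >= 1 & px[, 1] <= 96 & px[, 2] >= 1 & px[, 2] <= 96, ]
  red_count <- function(r) {
    sum(r$rgb[cbind(px[, "row"], px[, "col"], 1)] > 0.3 &
          r$rgb[cbind(px[, "row"], px[, "col"], 1)] >
            r$rgb[cbind(px[, "row"], px[, "col"], 3)])
  }
  expect_gte(red_count(r_fus), red_count(r_ciss))
  expect_gt(red_count(r_fus), 0)
})
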