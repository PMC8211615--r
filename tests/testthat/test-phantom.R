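test_that("same seed gives bytewise identical phantoms", {
  sp <- phantom_spec(dims = c(32, 32, 32), seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$ciss$data, b$ciss$data)
  expect_identical(a$tof$data, b$tof$data)
  expect_identical(a$truth$masks, b$truth$masks)
})

test_that("zero-noise, artifact-free intensities equal class means on mask interiors", {
  ph <- clean_phantom()
  m <- phantom_spec()$ciss_means
  # interiors: one erosion step keeps us clear of the partial-volume ramp
  expect_lt(max(abs(ph$ciss$data[erode1(ph$truth$masks$csf)] - m[["csf"]])),
            1e-9)
  expect_lt(max(abs(ph$ciss$data[erode1(ph$truth$masks$brainstem)] -
                      m[["brainstem"]])), 1e-9)
  expect_lt(max(abs(ph$ciss$data[erode1(ph$truth$masks$vessel)] -
                      m[["vessel"]])), 1e-9)
})

test_that("flow void with factor 1 makes vessel indistinguishable from brainstem", {
  # nerve_gap pushes the loop junction above the void arc so the arc is
  # not repainted by the (non-void) loop vessel where the two tubes meet
  sp <- phantom_spec(dims = c(48, 48, 48), ciss_sigma = 0, tof_sigma = 0,
                     pulsation = NULL, nerve_gap = 4,
                     flow_void = list(list(vessel = "trunk",
                                           arc = c(0.3, 0.65), factor = 1)),
                     seed = 2)
  ph <- generate_phantom(sp)
  cl <- ph$truth$centerlines$trunk
  void <- ph$truth$void$trunk
  expect_gt(sum(void), 0)
  vals <- ph$ciss$data[cl[void, , drop = FALSE]]
  m <- sp$ciss_means
  # keep clear of the two arc transition zones
  core <- which(void)
  core <- core[core > min(which(void)) + 2 & core < max(which(void)) - 2]
  expect_lt(max(abs(ph$ciss$data[cl[core, , drop = FALSE]] -
                      m[["brainstem"]])), 1e-6)
  # outside the arc the vessel keeps its own mean
  keep <- which(!void)
  keep <- keep[keep > 3 & keep < nrow(cl) - 3 &
                 abs(keep - min(which(void))) > 3 &
                 abs(keep - max(which(void))) > 3]
  expect_lt(max(abs(ph$ciss$data[cl[keep, , drop = FALSE]] -
                      m[["vessel"]])), 1e-6)
})

test_that("ground-truth masks partition and centerlines lie inside their tubes", {
  ph <- small_phantom()
  M <- ph$truth$masks
  overlap <- (M$csf + M$brainstem + M$nerve + M$vessel)
  expect_true(all(overlap <= 1))
  for (vn in c("trunk", "loop")) {
    cl <- ph$truth$centerlines[[vn]]
    expect_true(all(M$vessel[cl]))
  }
})

test_that("CISS and TOF have the stated contrast structure", {
  ph <- small_phantom()
  M <- ph$truth$masks
  csf_m <- mean(ph$ciss$data[erode1(M$csf)])
  other <- mean(ph$ciss$data[erode1(M$brainstem)])
  sig <- phantom_spec()$ciss_sigma
  expect_gt(csf_m - other, 3 * sig)          # hyperintense CSF
  tof_v <- mean(ph$tof$data[erode1(M$vessel)])
  # TOF vessel mean dominates every other class (measure csf region on the
  # TOF grid indirectly through its global histogram upper tail)
  expect_gt(tof_v, mean(ph$tof$data) + 3 * phantom_spec()$tof_sigma)
})

test_that("contact phantoms control the vessel-nerve interface", {
  sp <- phantom_spec(dims = c(48, 48, 48), seed = 5)
  pt <- contact_phantom(sp, touching = TRUE)
  pf <- contact_phantom(sp, touching = FALSE)

  expect_true(pt$truth$contact)
  expect_gt(nrow(pt$truth$contact_voxels), 0)
  expect_false(pf$truth$contact)

  # morphology oracle: contact voxels lie in dilated(vessel) & dilated(nerve)
  both <- dilate26(pt$truth$masks$vessel) & dilate26(pt$truth$masks$nerve)
  cv <- pt$truth$contact_voxels
  expect_true(all(both[cv]))

  # separated case: at least a 2-voxel CSF layer, so even one dilation of
  # each mask leaves no shared voxel
  expect_equal(sum(dilate26(pf$truth$masks$vessel) &
                     dilate26(pf$truth$masks$nerve) &
                     pf$truth$masks$csf), 0)
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(vessel_radii = c(trunk = 50, loop = 0.9)),
               "radius")
  expect_error(phantom_spec(ciss_means = c(background = 50, csf = 100,
                                           brainstem = 400, nerve = 250,
                                           vessel = 200)),
               "hyperintense CSF")
  expect_error(nvcfuse:::dist_to_polyline(matrix(0, 2, 3),
                                          matrix(0, 1, 3)),
               "degenerate centerline")
})
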