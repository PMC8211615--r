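mk_vol <- function(a) nvc_volume(a, spacing = c(1, 1, 1))

test_that("volume growing equals the exhaustive flood-fill oracle on small grids", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(3:4, 1)
    a <- array(sample(0:3, n^3, replace = TRUE), c(n, n, n))
    conn <- sample(c(6, 26), 1)
    lower <- 1; upper <- 2
    cand <- which(a >= lower & a <= upper, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    seed <- cand[sample(nrow(cand), 1), , drop = FALSE]
    got <- volume_grow(mk_vol(a), grow_params(seed, lower, upper,
                                              connectivity = conn))
    want <- oracle_flood_fill(a, seed, lower, upper, conn)
    expect_identical(got, want)
  }
})

test_that("bounding boxes clip the growth to the seed's side", {
  a <- array(1, c(3, 3, 3))           # hand-built cross in one slab
  a[] <- 0
  a[2, , 2] <- 1; a[, 2, 2] <- 1
  v <- mk_vol(a)
  full <- volume_grow(v, grow_params(c(2, 2, 2), 1, 1, connectivity = 6))
  expect_identical(which(full), which(a == 1))

  bb <- nvc_bbox(c(1, 1, 1), c(3, 2, 3))
  clipped <- volume_grow(v, grow_params(c(2, 2, 2), 1, 1, bbox = bb,
                                        connectivity = 6))
  want <- oracle_flood_fill(a, matrix(c(2, 2, 2), 1), 1, 1, 6,
                            c(1, 1, 1), c(3, 2, 3))
  expect_identical(clipped, want)
  expect_true(all(which(clipped, arr.ind = TRUE)[, 2] <= 2))
})

test_that("uniform in-window volume grows to the whole grid", {
  v <- mk_vol(array(5, c(4, 4, 4)))
  m <- volume_grow(v, grow_params(c(1, 1, 1), 4, 6))
  expect_true(all(m))
})

test_that("seed and window preconditions are enforced", {
  v <- mk_vol(array(1:27, c(3, 3, 3)))
  expect_error(volume_grow(v, grow_params(c(1, 1, 1), 100, 200)),
               "seed \\(1,1,1\\)")
  expect_error(grow_params(matrix(numeric(), 0, 3), 0, 1), "empty seed")
  expect_error(grow_params(c(1, 1, 1), 2, 1), "lower <= upper")
  expect_error(volume_grow(v, grow_params(c(9, 1, 1), 0, 100)),
               "seed outside grid")
})

test_that("label assembly follows the fixed priority hierarchy", {
  set.seed(32)
  d <- c(5, 5, 5)
  tpl <- mk_vol(array(0, d))
  csf <- array(runif(prod(d)) < 0.5, d)
  bs <- array(runif(prod(d)) < 0.5, d)
  nv <- array(runif(prod(d)) < 0.5, d)
  lv <- assemble_labels(csf, bs, nv, tpl)
  leg <- nvc_legend()

  # per-voxel oracle
  want <- array(leg[["REST"]], d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    want[i, j, k] <- if (nv[i, j, k]) leg[["NERVE"]]
      else if (csf[i, j, k]) leg[["CSF_VESSEL"]]
      else if (bs[i, j, k]) leg[["BRAINSTEM"]]
      else leg[["REST"]]
  }
  expect_identical(lv$labels, array(as.integer(want), d))

  # a voxel in all three masks is NERVE; in none, REST
  all3 <- csf & bs & nv
  if (any(all3)) expect_true(all(lv$labels[all3] == leg[["NERVE"]]))
  none <- !(csf | bs | nv)
  if (any(none)) expect_true(all(lv$labels[none] == leg[["REST"]]))
})

test_that("brainstem growing respects the CSF barrier and is monotone in it", {
  ph <- small_phantom()
  pre <- preprocess_volume(ph$ciss)
  win <- csf_window(pre)
  seed <- which(abs(pre$data - mean(win)) == min(abs(pre$data - mean(win))),
                arr.ind = TRUE)[1, ]
  csf <- volume_grow(pre, grow_params(seed, win[1], win[2]))

  bs_seed <- nvcfuse:::mask_seed(ph$truth$masks$brainstem)
  p <- grow_params(bs_seed, 300, 500,
                   bbox = nvcfuse:::mask_bbox(ph$truth$masks$brainstem),
                   connectivity = 6)
  bs <- segment_brainstem(pre, csf, p)
  expect_gte(dice_coef(bs, ph$truth$masks$brainstem), 0.90)
  expect_equal(sum(bs & csf), 0)

  # removing the barrier can only enlarge the mask
  bs_free <- volume_grow(pre, p)
  expect_true(all(bs_free[bs]))

  # barrier covering the whole grid starves the seed
  expect_error(segment_brainstem(pre, array(TRUE, dim(pre$data)), p),
               "outside window")
})

test_that("nerve labels are imported, grid-checked and warn when empty", {
  ph <- small_phantom()
  tpl <- ph$ciss
  path <- file.path(tempdir(), "nerve.nii.gz")
  m <- ph$truth$masks$nerve
  lv <- nvc_label_volume(array(as.integer(m), dim(m)),
                         legend = c(REST = 0L, NERVE = 1L),
                         template = tpl)
  write_labels(lv, path)
  back <- import_nerve_labels(path, tpl)
  expect_identical(back, m)

  small <- nvc_volume(array(0, c(8, 8, 8)), spacing = tpl$spacing)
  expect_error(import_nerve_labels(path, small), "grid")

  empty <- nvc_label_volume(array(0L, dim(m)),
                            legend = c(REST = 0L, NERVE = 1L),
                            template = tpl)
  path2 <- file.path(tempdir(), "nerve0.nii.gz")
  write_labels(empty, path2)
  expect_warning(import_nerve_labels(path2, tpl), "empty")
})
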