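test_that("contact detection separates touching from clear phantoms", {
  sp <- phantom_spec(dims = c(48, 48, 48), seed = 14)
  pt <- contact_phantom(sp, touching = TRUE)
  pf <- contact_phantom(sp, touching = FALSE)

  f1 <- detect_contact(pt$truth$masks$vessel, pt$truth$masks$nerve)
  expect_true(f1$contact)
  expect_true(f1$side != "none")
  # contact set within one dilation of the ground-truth contact set
  truth_dil <- dilate26(array(FALSE, dim(pt$ciss$data)) |
                          (function(m) { m[pt$truth$contact_voxels] <- TRUE; m })(
                            array(FALSE, dim(pt$ciss$data))))
  expect_true(all(truth_dil[f1$contact_voxels]))

  f2 <- detect_contact(pf$truth$masks$vessel, pf$truth$masks$nerve)
  expect_false(f2$contact)
  expect_identical(f2$side, "none")

  # empty vessel mask -> side none
  f3 <- detect_contact(array(FALSE, dim(pt$ciss$data)),
                       pt$truth$masks$nerve)
  expect_identical(f3$side, "none")
  expect_false(f3$contact)
})

# build a volume + straight centerline where exactly `frac` of the path
# (a chosen subset) carries in-window intensity
coverage_fixture <- function(visible) {
  n <- length(visible)
  d <- c(n + 4, 9, 9)
  a <- array(1000, d)                      # far outside the window
  cl <- cbind(seq_len(n) + 2, 5, 5)
  a[cl[visible, , drop = FALSE]] <- 200    # window center
  list(v = nvc_volume(a, spacing = c(1, 1, 1)), cl = cl)
}

test_that("vessel scores match the independent threshold-table oracle", {
  set.seed(51)
  cases <- list(
    rep(FALSE, 40),                              # c = 0 -> 0
    rep(TRUE, 40),                               # c = 1 -> 5
    c(rep(TRUE, 16), rep(FALSE, 24)),            # proximal 80%, distal 0 -> 3
    c(rep(TRUE, 30), rep(FALSE, 10)),            # c = 0.75 -> 4
    c(rep(TRUE, 12), rep(FALSE, 28)),            # c = 0.3 -> 2
    c(rep(TRUE, 4), rep(FALSE, 36))              # c = 0.1 -> 1
  )
  for (vis in cases) {
    fx <- coverage_fixture(vis)
    s <- score_vessel(fx$v, fx$cl)
    half <- floor(length(vis) / 2)
    want <- oracle_score_table(mean(vis), mean(vis[seq_len(half)]),
                               mean(vis[-seq_len(half)]))
    expect_identical(s$score, want)
  }
  # random patterns against the oracle
  for (rep in 1:20) {
    vis <- runif(30) < runif(1)
    fx <- coverage_fixture(vis)
    s <- score_vessel(fx$v, fx$cl)
    want <- oracle_score_table(mean(vis), mean(vis[1:15]), mean(vis[16:30]))
    expect_identical(s$score, want)
  }
})

test_that("score is monotone in coverage for the coverage-driven levels", {
  # uniformly scattered visibility avoids the proximal/distal level 3
  set.seed(52)
  n <- 40
  ord <- sample(n)       # fill in random order -> balanced halves
  prev <- -1L
  for (k in c(0, 5, 9, 15, 21, 30, 37, 39, 40)) {
    vis <- rep(FALSE, n); vis[ord[seq_len(k)]] <- TRUE
    fx <- coverage_fixture(vis)
    s <- score_vessel(fx$v, fx$cl)
    if (s$score != 3L) {           # level 3 is shape-, not coverage-driven
      expect_gte(s$score, prev)
      prev <- s$score
    }
  }
})

test_that("manual clinical scores pass through and errors are raised", {
  fx <- coverage_fixture(rep(TRUE, 10))
  s <- score_vessel(fx$v, fx$cl, manual = 3)
  expect_identical(s$score, 3L)
  expect_error(score_vessel(fx$v, fx$cl, manual = 7), "0-5")
  expect_error(score_vessel(fx$v, matrix(numeric(), 0, 3)),
               "empty centerline")
})

test_that("fusion never lowers the score of a flow-void vessel", {
  for (seed in 1:3) {
    sp <- phantom_spec(dims = c(48, 48, 48), seed = 20 + seed,
                       flow_void = list(list(vessel = "trunk",
                                             arc = c(0.3, 0.62 + 0.04 * seed),
                                             factor = 1)))
    ph <- generate_phantom(sp)
    pre <- preprocess_volume(ph$ciss)
    tof_ref <- reformat(ph$tof, pre, ph$truth$true_rigid)
    fz <- fuse(pre, tof_ref, extract_tof_vessels(tof_ref))
    for (vn in names(ph$truth$centerlines)) {
      cl <- ph$truth$centerlines[[vn]]
      expect_gte(score_vessel(fz$fused, cl, name = vn)$score,
                 score_vessel(pre, cl, name = vn)$score)
    }
  }
})

test_that("scores and findings export to the documented CSV shape", {
  fx <- coverage_fixture(rep(TRUE, 10))
  s <- score_vessel(fx$v, fx$cl, name = "trunk")
  ph <- contact_phantom(phantom_spec(dims = c(48, 48, 48), seed = 14), TRUE)
  f <- detect_contact(ph$truth$masks$vessel, ph$truth$masks$nerve)
  path <- file.path(tempdir(), "scores.csv")
  df <- write_scores_csv(list(s), f, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("vessel", "side", "score", "contact_voxels"))
  expect_identical(back$score, 5L)
  expect_gt(back$contact_voxels, 0)
})
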