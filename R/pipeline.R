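# End-to-end orchestration: phantom -> preprocess -> segment -> register
# -> fuse -> render -> score -> stats, driven by a single config (list or
# JSON file).  Every output is reproducible from config + seed alone.

default_config <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    n_subjects = 1L,
    write_volumes = TRUE,
    phantom = list(),
    preprocess = list(iterations = 5, kappa = "auto", dt = 1 / 7,
                      close_radius = 1),
    segmentation = list(brainstem_window = c(300, 500),
                        csf_connectivity = 26, brainstem_connectivity = 6),
    registration = list(bins = 64, pyramid_levels = 3, sampling = 0.25,
                        max_iter = 400, landmark_jitter = 0.3,
                        skip_mi = FALSE),
    fusion = list(ciss_range = c(150, 250)),
    render = list(views = "ap", image_size = c(192, 192)),
    scoring = list(window = vessel_display_window())
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config validation: `out_dir` is required")
  cfg
}

pipeline_log <- function(con, stage, ...) {
  kv <- c(...)
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage=", stage,
                 if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                   collapse = " ")) else "")
  writeLines(line, con)
}

# Voxel of `mask` nearest to its centroid (a stand-in for the seed a user
# would click inside the structure).
mask_seed <- function(mask) {
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("cannot seed an empty mask")
  ctr <- colMeans(vox)
  vox[which.min(rowSums(sweep(vox, 2, ctr)^2)), ]
}

mask_bbox <- function(mask, margin = 2L) {
  vox <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  nvc_bbox(pmax(apply(vox, 2, min) - margin, 1L),
           pmin(apply(vox, 2, max) + margin, d))
}

run_subject <- function(cfg, subject, dirs, logcon) {
  leg <- nvc_legend()
  stage <- "phantom"
  sdir <- function(d) file.path(d, sprintf("subject%02d", subject))
  for (d in dirs) dir.create(sdir(d), recursive = TRUE, showWarnings = FALSE)

  spec <- do.call(phantom_spec,
                  c(cfg$phantom, list(seed = cfg$seed * 1000L + subject)))
  ph <- generate_phantom(spec)
  pipeline_log(logcon, stage, c(subject = subject, seed = spec$seed,
                                dims = paste(spec$dims, collapse = "x")))
  if (isTRUE(cfg$write_volumes)) {
    write_volume(ph$ciss, file.path(sdir(dirs[["phantom"]]), "ciss.nii.gz"))
    write_volume(ph$tof, file.path(sdir(dirs[["phantom"]]), "tof.nii.gz"))
  }

  stage <- "preprocess"
  pp <- cfg$preprocess
  pre <- preprocess_volume(ph$ciss, iterations = pp$iterations,
                           kappa = pp$kappa, dt = pp$dt,
                           close_radius = pp$close_radius)
  pipeline_log(logcon, stage, c(iterations = pp$iterations,
                                close_radius = pp$close_radius))
  if (isTRUE(cfg$write_volumes))
    write_volume(pre, file.path(sdir(dirs[["preprocess"]]), "pre.nii.gz"))

  stage <- "segment"
  sg <- cfg$segmentation
  win <- csf_window(pre)
  csf_seed <- which(abs(pre$data - mean(win)) ==
                      min(abs(pre$data - mean(win))), arr.ind = TRUE)[1, ]
  csf <- volume_grow(pre, grow_params(csf_seed, win[1], win[2],
                                      connectivity = sg$csf_connectivity))
  bs_seed <- mask_seed(ph$truth$masks$brainstem)
  bs <- segment_brainstem(pre, csf,
                          grow_params(bs_seed, sg$brainstem_window[1],
                                      sg$brainstem_window[2],
                                      bbox = mask_bbox(ph$truth$masks$brainstem),
                                      connectivity = sg$brainstem_connectivity))
  nerve <- ph$truth$masks$nerve     # manual annotation stand-in
  labels <- assemble_labels(csf, bs, nerve, pre)
  pipeline_log(logcon, stage,
               c(csf_window = sprintf("%.1f:%.1f", win[1], win[2]),
                 csf_voxels = sum(csf), brainstem_voxels = sum(bs)))
  if (isTRUE(cfg$write_volumes))
    write_labels(labels, file.path(sdir(dirs[["segment"]]), "labels.nii.gz"))

  stage <- "register"
  rg <- cfg$registration
  geom <- ph$truth$geometry
  fixed_lm <- rbind(geom$cistern[1, ], geom$cistern[2, ],
                    c(geom$cistern[1, 1], geom$cistern[2, 2],
                      geom$cistern[1, 3]),
                    world_center(ph$ciss))
  moving_lm <- apply_rigid(rigid_inverse(ph$truth$true_rigid), fixed_lm)
  if (rg$landmark_jitter > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed + 17L)
    moving_lm <- moving_lm + matrix(rnorm(length(moving_lm), 0,
                                          rg$landmark_jitter),
                                    nrow(moving_lm))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  init <- landmark_rigid(fixed_lm, moving_lm)
  T <- if (isTRUE(rg$skip_mi)) init else
    register_volumes(ph$ciss, ph$tof, init,
                     mi_options(bins = rg$bins,
                                pyramid_levels = rg$pyramid_levels,
                                sampling = rg$sampling,
                                max_iter = rg$max_iter,
                                seed = spec$seed + 23L))
  err <- rigid_error(T, ph$truth$true_rigid,
                     ref_point = world_center(ph$ciss))
  pipeline_log(logcon, stage,
               c(rot_err_deg = sprintf("%.4f", err["rot_deg"]),
                 trans_err_mm = sprintf("%.4f", err["trans_mm"])))
  jsonlite::write_json(rigid_to_list(T),
                       file.path(sdir(dirs[["register"]]), "transform.json"),
                       auto_unbox = TRUE, digits = NA)

  stage <- "fuse"
  tof_ref <- reformat(ph$tof, pre, T)
  vmask <- extract_tof_vessels(tof_ref)
  fz <- fuse(pre, tof_ref, vmask, ciss_range = cfg$fusion$ciss_range)
  labels_fused <- apply_vessel_label(labels, fz$labels_delta)
  pipeline_log(logcon, stage, c(vessel_voxels = sum(vmask)))
  if (isTRUE(cfg$write_volumes)) {
    write_volume(tof_ref, file.path(sdir(dirs[["fuse"]]), "tof_ref.nii.gz"))
    write_volume(fz$fused, file.path(sdir(dirs[["fuse"]]), "fused.nii.gz"))
    write_labels(labels_fused,
                 file.path(sdir(dirs[["fuse"]]), "labels_fused.nii.gz"))
  }

  stage <- "render"
  for (view in cfg$render$views) {
    cam <- named_camera(view, image_size = cfg$render$image_size)
    write_render(render_volume(pre, labels, default_tf(), cam),
                 file.path(sdir(dirs[["render"]]),
                           sprintf("ciss_%s.png", view)))
    write_render(render_volume(fz$fused, labels_fused, default_tf(), cam),
                 file.path(sdir(dirs[["render"]]),
                           sprintf("fused_%s.png", view)))
  }
  pipeline_log(logcon, stage, c(views = paste(cfg$render$views,
                                              collapse = ",")))

  stage <- "score"
  win_s <- cfg$scoring$window
  rows <- list()
  for (vn in names(ph$truth$centerlines)) {
    cl <- ph$truth$centerlines[[vn]]
    for (mod in c("ciss", "fused")) {
      vol <- if (mod == "ciss") pre else fz$fused
      sc <- score_vessel(vol, cl, window = win_s, name = vn)
      rows[[length(rows) + 1]] <-
        data.frame(subject = subject, vessel = vn, modality = mod,
                   coverage = sprintf("%.6f", sc$coverage),
                   score = sc$score)
    }
  }
  finding <- detect_contact(vmask, nerve)
  pipeline_log(logcon, stage, c(contact = finding$side))
  list(scores = do.call(rbind, rows),
       finding = data.frame(subject = subject, side = finding$side,
                            contact = finding$contact,
                            contact_voxels = nrow(finding$contact_voxels)))
}

#' Run the full pipeline from a single config
#'
#' Executes phantom generation, preprocessing, explicit segmentation,
#' rigid registration, vessel fusion, rendering of the before/after
#' views, vessel scoring and the paired statistics for each subject, all
#' deterministic given `config$seed`.  Outputs are laid out in stage
#' subdirectories under `config$out_dir` with a machine-parseable
#' `log.txt`.
#'
#' @param config list or path to a JSON file.  Required: `out_dir`.
#'   Optional keys (with defaults): `seed`, `n_subjects`, `phantom`
#'   (arguments of [phantom_spec()]), `preprocess`, `segmentation`,
#'   `registration`, `fusion`, `render`, `scoring`, `write_volumes`.
#' @return Invisibly, a list with the scores and findings data frames and
#'   the run directory.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  run_dir <- cfg$out_dir
  stages <- c("phantom", "preprocess", "segment", "register", "fuse",
              "render", "scores", "stats")
  dirs <- setNames(file.path(run_dir, stages), stages)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(run_dir, "log.txt"), "w")
  on.exit(close(logcon))

  all_scores <- list(); all_findings <- list()
  for (s in seq_len(cfg$n_subjects)) {
    res <- tryCatch(run_subject(cfg, s, dirs, logcon),
                    error = function(e)
                      stop(sprintf("pipeline failed for subject %d: %s",
                                   s, conditionMessage(e)), call. = FALSE))
    all_scores[[s]] <- res$scores
    all_findings[[s]] <- res$finding
  }
  scores <- do.call(rbind, all_scores)
  findings <- do.call(rbind, all_findings)
  write.csv(scores, file.path(dirs[["scores"]], "scores.csv"),
            row.names = FALSE)
  write.csv(findings, file.path(dirs[["scores"]], "findings.csv"),
            row.names = FALSE)

  before <- scores$score[scores$modality == "ciss"]
  after <- scores$score[scores$modality == "fused"]
  stat_row <- tryCatch({
    tt <- paired_t(before, after)
    data.frame(test = "paired_t", n = tt$n,
               mean_diff = sprintf("%.6f", tt$mean_diff),
               sd_diff = sprintf("%.6f", tt$sd_diff),
               t = sprintf("%.6f", tt$t), df = tt$df,
               p = sprintf("%.6g", tt$p), note = "")
  }, error = function(e)
    data.frame(test = "paired_t", n = length(before), mean_diff = NA,
               sd_diff = NA, t = NA, df = NA, p = NA,
               note = conditionMessage(e)))
  write.csv(stat_row, file.path(dirs[["stats"]], "stats.csv"),
            row.names = FALSE)
  pipeline_log(logcon, "done", c(subjects = cfg$n_subjects))
  invisible(list(scores = scores, findings = findings, run_dir = run_dir))
}
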