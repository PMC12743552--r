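#' Run one pipeline stage
#'
#' Thin orchestration over the analysis modules, mirroring the end-to-end
#' workflow: simulate inputs, screen docked poses, detect per-frame
#' contacts, aggregate survival tables, analyze pulling curves, fit BLI
#' sensorgram sets, and summarize AFM cycles. Each stage reads/writes the
#' plain CSV/JSON formats of the corresponding module and appends a run
#' log (`ifd_run.log`) with the stage, seed and parameters. Identical
#' config + seed reproduces identical artifacts (timestamps live only in
#' the log).
#'
#' @param subcommand one of `"simulate"`, `"screen-poses"`, `"contacts"`,
#'   `"survival"`, `"pulling"`, `"bli-fit"`, `"afm"`.
#' @param config named list of stage parameters, or path to a JSON/YAML
#'   file holding one. Common fields: `out_dir` (output directory),
#'   stage-specific input paths and criteria overrides (see Details).
#' @param seed integer seed forwarded to every stochastic stage.
#'
#' @details Stage-specific config fields:
#' \describe{
#'   \item{simulate}{`what`: any of "trajectory", "smd", "bli", "afm"
#'     (default all); generator overrides under `trajectory`, `smd`,
#'     `bli`, `afm` sublists.}
#'   \item{contacts}{`trajectory` (multi-MODEL PDB path), `partner_a`,
#'     `partner_b` (chain vectors), optional `hbond`/`saltbridge`
#'     criteria sublists, `frame_interval_ns`.}
#'   \item{survival}{`trajectories`: vector of run PDB paths (>= 2), plus
#'     the `contacts` fields; `threshold` (default 10).}
#'   \item{pulling}{`curve`: force-curve CSV; `smooth_window`.}
#'   \item{bli-fit}{`dir`: sensorgram-set directory with manifest.}
#'   \item{afm}{`cycles`: AFM CSV; `bin_width`.}
#'   \item{screen-poses}{`reference` (PDB), `ref_receptor`, `ref_ligand`,
#'     `poses_dir` (directory of pose PDBs), `pose_receptor`,
#'     `pose_blocker`, optional `scores_csv` (pose_id, score),
#'     `min_covered`, `contact_cutoff`.}
#' }
#' @return Invisibly, a list of the stage's main results (also written to
#'   `out_dir`).
#' @export
ifd_run <- function(subcommand = c("simulate", "screen-poses", "contacts",
                                   "survival", "pulling", "bli-fit", "afm"),
                    config = list(), seed = 1) {
  subcommand <- match.arg(subcommand)
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(subcommand,
    "simulate"     = stage_simulate(cfg, seed, out_dir),
    "screen-poses" = stage_screen_poses(cfg, out_dir),
    "contacts"     = stage_contacts(cfg, out_dir),
    "survival"     = stage_survival(cfg, out_dir),
    "pulling"      = stage_pulling(cfg, out_dir),
    "bli-fit"      = stage_bli_fit(cfg, out_dir),
    "afm"          = stage_afm(cfg, out_dir))
  log_line <- sprintf("[%s] ifd %s seed=%d config=%s",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      subcommand, seed,
                      jsonlite::toJSON(cfg, auto_unbox = TRUE))
  cat(log_line, "\n", file = file.path(out_dir, "ifd_run.log"),
      append = TRUE, sep = "")
  invisible(res)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package; use JSON instead")
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  config
}

cfg_hbond <- function(cfg) {
  do.call(hbond_criteria, cfg$hbond %||% list())
}
cfg_saltbridge <- function(cfg) {
  do.call(salt_bridge_criteria, cfg$saltbridge %||% list())
}

stage_simulate <- function(cfg, seed, out_dir) {
  what <- cfg$what %||% c("trajectory", "smd", "bli", "afm")
  res <- list()
  if ("trajectory" %in% what) {
    tcfg <- cfg$trajectory %||% list()
    toy <- make_toy_complex(
      hb_distance = tcfg$hb_distance %||% rep(2.9, 3),
      sb_distance = tcfg$sb_distance %||% rep(3.5, 2))
    gen <- make_trajectory(
      toy, occupancy = as.list(tcfg$p %||% rep(0.6, nrow(toy$manifest))),
      n_frames = tcfg$n_frames %||% 500,
      frame_interval_ns = tcfg$frame_interval_ns %||% 0.1, seed = seed)
    write_structure(gen$trajectory, file.path(out_dir, "trajectory.pdb"))
    jsonlite::write_json(
      list(seed = seed,
           truth_survival_pct = as.list(100 * rowMeans(gen$truth))),
      file.path(out_dir, "trajectory_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    res$trajectory <- gen
  }
  if ("smd" %in% what) {
    scfg <- cfg$smd %||% list()
    gen <- do.call(make_smd_curve, c(scfg, list(seed = seed)))
    write_force_curve(gen$curve, file.path(out_dir, "smd_curve.csv"))
    jsonlite::write_json(c(list(seed = seed), gen$truth),
                         file.path(out_dir, "smd_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$smd <- gen
  }
  if ("bli" %in% what) {
    bcfg <- cfg$bli %||% list()
    gen <- do.call(make_sensorgram_set, c(bcfg, list(seed = seed)))
    write_sensorgram_set(gen$curves, file.path(out_dir, "sensorgrams"))
    jsonlite::write_json(c(list(seed = seed), gen$truth),
                         file.path(out_dir, "sensorgrams", "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    res$bli <- gen
  }
  if ("afm" %in% what) {
    acfg <- cfg$afm %||% list()
    gen <- do.call(make_afm_cycles, c(acfg, list(seed = seed)))
    write_afm_cycles(gen$cycles, file.path(out_dir, "afm_cycles.csv"))
    jsonlite::write_json(c(list(seed = seed), gen$truth),
                         file.path(out_dir, "afm_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$afm <- gen
  }
  res
}

stage_contacts <- function(cfg, out_dir) {
  traj <- read_trajectory(cfg$trajectory,
                          frame_interval_ns = cfg$frame_interval_ns %||% 0.1)
  dets <- lapply(seq_len(traj$n_frames), function(i) {
    xyz <- frame_coords(traj, i)
    rbind(detect_hbonds(traj$topology, cfg$partner_a, cfg$partner_b,
                        cfg_hbond(cfg), xyz = xyz),
          detect_salt_bridges(traj$topology, cfg$partner_a, cfg$partner_b,
                              cfg_saltbridge(cfg), xyz = xyz))
  })
  write_contacts_csv(dets, file.path(out_dir, "contacts.csv"))
  occ <- occupancy_matrix(dets, traj$frame_interval_ns)
  invisible(list(occupancy = occ, detections = dets))
}

stage_survival <- function(cfg, out_dir) {
  paths <- cfg$trajectories
  if (length(paths) < 2) stop("survival needs >= 2 run trajectories")
  runs <- lapply(paths, function(p) {
    occ <- trajectory_contacts(
      read_trajectory(p, frame_interval_ns = cfg$frame_interval_ns %||% 0.1),
      cfg$partner_a, cfg$partner_b,
      hbond = cfg_hbond(cfg), saltbridge = cfg_saltbridge(cfg))
    list(hb = survival_rates(subset_occupancy(occ, "hbond")),
         sb = survival_rates(subset_occupancy(occ, "saltbridge")))
  })
  tab <- rbind(
    aggregate_runs(lapply(runs, `[[`, "hb"), kind = "hbond"),
    aggregate_runs(lapply(runs, `[[`, "sb"), kind = "saltbridge"))
  filt <- filter_table(tab, cfg$threshold %||% 10)
  write_survival_csv(tab, file.path(out_dir, "survival_all.csv"))
  write_survival_csv(filt, file.path(out_dir, "survival_filtered.csv"))
  hb <- filt[filt$kind == "hbond", , drop = FALSE]
  if (nrow(hb) > 0)
    utils::write.csv(heatmap_matrix(hb),
                     file.path(out_dir, "heatmap_hbond.csv"))
  invisible(list(table = tab, filtered = filt))
}

#' Restrict an occupancy matrix to one interaction kind
#'
#' @param occ an `ifd_occupancy`.
#' @param kind `"hbond"` or `"saltbridge"`.
#' @return An `ifd_occupancy` with only the matching keys.
#' @export
subset_occupancy <- function(occ, kind) {
  sel <- occ$keys$kind == kind
  new_occupancy(occ$keys[sel, , drop = FALSE],
                occ$presence[sel, , drop = FALSE], occ$frame_interval_ns)
}

stage_pulling <- function(cfg, out_dir) {
  curve <- read_force_curve(cfg$curve)
  pr <- rupture_force(curve, smooth_window = cfg$smooth_window %||% 1)
  jsonlite::write_json(
    list(rupture_force_pN = pr$rupture_force,
         rupture_time_ns = pr$rupture_time,
         dissociation_time_ns = pr$dissociation_time),
    file.path(out_dir, "pulling_result.json"), auto_unbox = TRUE,
    digits = NA, na = "null")
  invisible(pr)
}

stage_bli_fit <- function(cfg, out_dir) {
  curves <- read_sensorgram_set(cfg$dir)
  fit <- fit_langmuir_global(curves,
                             per_curve_rmax = isTRUE(cfg$per_curve_rmax))
  jsonlite::write_json(
    list(kon_Ms = fit$kon, koff_s = fit$koff, KD_M = fit$KD,
         Rmax_nm = fit$Rmax, rss = fit$rss),
    file.path(out_dir, "kinetic_fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

stage_afm <- function(cfg, out_dir) {
  cycles <- read_afm_cycles(cfg$cycles)
  freq <- adhesion_frequency(cycles)
  dist <- tryCatch(rupture_distribution(cycles,
                                        bin_width = cfg$bin_width %||% 5),
                   error = function(e) NULL)
  jsonlite::write_json(
    list(mean_adhesion_pct = freq$mean_pct, sem_adhesion_pct = freq$sem_pct,
         n_substrates = freq$n_substrates,
         xc_pN = if (!is.null(dist)) dist$xc_pN else NULL,
         mean_force_pN = if (!is.null(dist)) dist$mean_force_pN else NULL),
    file.path(out_dir, "afm_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(frequency = freq, distribution = dist))
}

stage_screen_poses <- function(cfg, out_dir) {
  ref <- read_structure(cfg$reference)
  pose_files <- sort(list.files(cfg$poses_dir, pattern = "\\.pdb$",
                                full.names = TRUE))
  if (length(pose_files) == 0) stop("no pose PDBs in ", cfg$poses_dir)
  poses <- lapply(pose_files, read_structure)
  names(poses) <- sub("\\.pdb$", "", basename(pose_files))
  scores <- NULL
  if (!is.null(cfg$scores_csv)) {
    sc <- utils::read.csv(cfg$scores_csv)
    scores <- stats::setNames(sc$score, sc$pose_id)
  }
  rank <- rank_poses(poses, cfg$pose_receptor, cfg$pose_blocker,
                     ref, cfg$ref_receptor, cfg$ref_ligand,
                     external_scores = scores,
                     min_covered = cfg$min_covered %||% 0.5,
                     contact_cutoff = cfg$contact_cutoff %||% 4.5)
  utils::write.csv(rank, file.path(out_dir, "pose_ranking.csv"),
                   row.names = FALSE)
  invisible(rank)
}
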