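#' Configuration for the illumination-comparison experiment
#'
#' Fixes everything about the simulated comparison grid: the phantom, the
#' desk-scale rig, per-zoom calibration strategy, matching parameters, the
#' per-zoom adaptive pattern table, and the per-repeat pose perturbation
#' (the virtual analogue of manually rotating the model under the
#' microscope). Defaults reproduce the full 5-zoom x 4-method x 10-repeat
#' design (200 reconstructions).
#'
#' @param zooms Zoom levels (default 1.1-1.5 by 0.1).
#' @param methods Illumination methods to compare.
#' @param n_repeats Reconstructions per (zoom, method) cell (default 10).
#' @param rig A [rig_config()] (desk profile default).
#' @param scene_seed,complexity Phantom generator inputs.
#' @param noise_sigma Sensor noise sd, counts.
#' @param calibration `"estimated"` (Zhang calibration on synthetic corner
#'   observations, default) or `"true"` (exact rig geometry).
#' @param corner_noise_px Corner noise for estimated calibration (default
#'   0.2 px).
#' @param n_calib_poses Calibration pose pairs per zoom (default 19).
#' @param pattern_table Tibble zoom/d/s for the adaptive method (default
#'   [default_pattern_table()]; regenerate with [build_zoom_lookup()]).
#' @param sgbm_n_paths 4 (desk default) or 8 aggregation paths.
#' @param z_bounds Scene depth bounds (mm) sizing the disparity search.
#' @param n_samples Error-metric subset size (default 5000).
#' @param gt_points Ground-truth reference cloud size.
#' @param pose_max_rot_deg,pose_max_trans_mm Per-repeat pose perturbation
#'   bounds (default +/-15 deg, +/-5 mm).
#' @param random_pattern_density Lit fraction of the random speckle pattern.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(zooms = seq(1.1, 1.5, by = 0.1),
                              methods = c("environmental", "microscope_spot",
                                          "random_pattern", "adaptive_pattern"),
                              n_repeats = 10L,
                              rig = rig_config("desk"),
                              scene_seed = 0L, complexity = 1,
                              noise_sigma = 2,
                              calibration = c("estimated", "true"),
                              corner_noise_px = 0.2, n_calib_poses = 19L,
                              pattern_table = default_pattern_table(),
                              sgbm_n_paths = 4L,
                              z_bounds = c(165, 235),
                              n_samples = 5000L, gt_points = 40000L,
                              pose_max_rot_deg = 15, pose_max_trans_mm = 5,
                              random_pattern_density = 0.2) {
  calibration <- match.arg(calibration)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(zooms = zooms, methods = methods,
                 n_repeats = as.integer(n_repeats), rig = rig,
                 scene_seed = as.integer(scene_seed), complexity = complexity,
                 noise_sigma = noise_sigma, calibration = calibration,
                 corner_noise_px = corner_noise_px,
                 n_calib_poses = as.integer(n_calib_poses),
                 pattern_table = pattern_table,
                 sgbm_n_paths = as.integer(sgbm_n_paths),
                 z_bounds = z_bounds, n_samples = as.integer(n_samples),
                 gt_points = as.integer(gt_points),
                 pose_max_rot_deg = pose_max_rot_deg,
                 pose_max_trans_mm = pose_max_trans_mm,
                 random_pattern_density = random_pattern_density),
            class = "experiment_config")
}

#' Default adaptive-pattern lookup table
#'
#' The stored per-zoom (d, s) winners of the Bayesian pattern optimization
#' (`build_zoom_lookup(experiment_config(), master_seed = 0)` with the
#' default 10 random + 15 expected-improvement evaluations), mirroring the
#' workflow of optimizing once and keeping the results in a lookup table.
#' Regenerate with [build_zoom_lookup()] after changing the scene, rig or
#' matcher configuration.
#'
#' @return Tibble with columns `zoom`, `d`, `s`.
#' @export
default_pattern_table <- function() {
  tibble::tibble(zoom = c(1.1, 1.2, 1.3, 1.4, 1.5),
                 d = c(3L, 4L, 6L, 4L, 8L),
                 s = c(5L, 4L, 5L, 5L, 5L))
}

pattern_for_zoom <- function(table, zoom) {
  i <- which(abs(table$zoom - zoom) <= 1e-9)
  if (length(i) != 1) {
    stop(sprintf("no adaptive pattern parameters for zoom %.2f", zoom),
         call. = FALSE)
  }
  pattern_params(table$d[i], table$s[i])
}

# seeded per-repeat phantom pose: base placement composed with a bounded
# random rotation about the phantom origin plus a translation jitter
perturbed_pose <- function(config, pose_seed) {
  local_seed(pose_seed)
  R <- random_rotation(config$pose_max_rot_deg)
  t_ <- stats::runif(3, -config$pose_max_trans_mm, config$pose_max_trans_mm)
  compose_transforms(default_scene_pose(config$rig$aim_distance_mm),
                     rigid_transform(R, t_))
}

build_illumination <- function(method, config, params_used, seed) {
  if (method == "adaptive_pattern") {
    pat <- generate_dot_pattern(params_used)
    illumination_config("adaptive_pattern", pattern = pat,
                        noise_sigma = config$noise_sigma)
  } else if (method == "random_pattern") {
    pat <- generate_random_pattern(density = config$random_pattern_density,
                                   seed = derive_seed(seed, 9))
    illumination_config("random_pattern", pattern = pat,
                        noise_sigma = config$noise_sigma)
  } else {
    illumination_config(method, noise_sigma = config$noise_sigma)
  }
}

sgbm_for_entry <- function(entry, config) {
  rng <- disparity_range(entry, config$z_bounds[1], config$z_bounds[2])
  sgbm_params(block_size = 3L, min_disparity = rng$min_disparity,
              num_disparities = rng$num_disparities,
              n_paths = config$sgbm_n_paths)
}

# one full pipeline pass: render -> reconstruct -> register -> score
evaluate_reconstruction <- function(scene, gt_cloud, rig, entry, illum, pose,
                                    config, seed) {
  pair <- render_stereo_pair(scene, rig, illum, seed = seed, pose = pose)
  params <- sgbm_for_entry(entry, config)
  cloud <- reconstruct_mire(pair$left, pair$right, entry, params)
  valid_fraction <- attr(cloud, "valid_fraction")
  est_targets <- localize_fiducials_3d(cloud, scene, pose = pose)
  tr <- horn_align(est_targets, fiducial_target_points(scene))
  err <- reconstruction_error(cloud, gt_cloud, tr, scene$roi,
                              n_samples = config$n_samples,
                              seed = derive_seed(seed, 11))
  list(rmse = err$rmse, mean_abs = err$mean_abs,
       valid_fraction = valid_fraction, n_cropped = err$n_cropped,
       fiducial_rms = attr(tr, "rms"), transform = tr, cloud = cloud)
}

#' Per-zoom calibration entries for an experiment
#'
#' @param config An [experiment_config()].
#' @param master_seed Experiment master seed.
#' @return A list of `calibration_entry`, one per configured zoom.
#' @export
experiment_calibration <- function(config, master_seed = 0L) {
  lapply(seq_along(config$zooms), function(zi) {
    zoom <- config$zooms[zi]
    rig <- make_zoom_rig(zoom, config$rig)
    if (config$calibration == "true") {
      calibration_entry_from_rig(rig)
    } else {
      obs <- render_calibration_set(rig, board_spec(),
                                    n_poses = config$n_calib_poses,
                                    seed = derive_seed(master_seed, 21, zi),
                                    corner_noise_px = config$corner_noise_px)
      # the simulated cameras are distortion-free and the checkerboard is
      # small relative to the field, which leaves distortion coefficients
      # ill-conditioned under corner noise; freeze them at zero here
      calibrate_stereo(obs, zoom = zoom, estimate_distortion = FALSE)
    }
  })
}

#' Run the illumination-comparison experiment
#'
#' For every (zoom, method, repeat) cell: the phantom is re-posed by a seeded
#' bounded random rotation/translation (shared across methods within a
#' (zoom, repeat) pair so comparisons are paired), the stereo pair is
#' rendered under the method's illumination, reconstructed, registered to
#' the ground truth via the fiducials, and scored inside the ROI. Failed
#' reconstructions (too few marker points, or a reconstruction missing the
#' ROI) are recorded with `rmse = Inf` and flagged, never dropped. Every
#' record carries the seeds needed to replay it in isolation.
#'
#' @param config An [experiment_config()].
#' @param master_seed Master seed; all per-record seeds derive from it.
#' @param calibrations Optional precomputed result of
#'   [experiment_calibration()] (computed on the fly otherwise).
#' @param keep_clouds Attach each record's ROI-cropped registered cloud (as a
#'   list column) for later heat-map rendering.
#' @param progress Print one line per completed cell.
#' @return Tibble of `experiment records`: zoom, method, repeat_index,
#'   pose_seed, render_seed, rmse, mean_abs, valid_fraction, fiducial_rms,
#'   failed, d, s (pattern methods), and optionally `cloud`.
#' @export
run_experiment <- function(config = experiment_config(), master_seed = 0L,
                           calibrations = NULL, keep_clouds = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  scene <- generate_phantom(config$scene_seed, config$complexity)
  gt_cloud <- sample_ground_truth_cloud(scene, config$gt_points,
                                        seed = derive_seed(master_seed, 31))
  calibrations <- calibrations %||% experiment_calibration(config, master_seed)

  rows <- list()
  clouds <- list()
  ri <- 0L
  for (zi in seq_along(config$zooms)) {
    zoom <- config$zooms[zi]
    rig <- make_zoom_rig(zoom, config$rig)
    entry <- calibrations[[zi]]
    for (rep_i in seq_len(config$n_repeats)) {
      pose_seed <- derive_seed(master_seed, 41, zi, rep_i)
      pose <- perturbed_pose(config, pose_seed)
      for (mi in seq_along(config$methods)) {
        method <- config$methods[mi]
        render_seed <- derive_seed(master_seed, 51, zi, rep_i, mi)
        params_used <- if (method == "adaptive_pattern") {
          pattern_for_zoom(config$pattern_table, zoom)
        } else NULL
        illum <- build_illumination(method, config, params_used, render_seed)
        res <- tryCatch(
          evaluate_reconstruction(scene, gt_cloud, rig, entry, illum, pose,
                                  config, render_seed),
          error = function(e) {
            list(rmse = Inf, mean_abs = Inf, valid_fraction = NA_real_,
                 n_cropped = 0L, fiducial_rms = NA_real_, cloud = NULL,
                 message = conditionMessage(e))
          })
        ri <- ri + 1L
        rows[[ri]] <- tibble::tibble(
          zoom = zoom, method = method, repeat_index = rep_i,
          pose_seed = pose_seed, render_seed = render_seed,
          rmse = res$rmse, mean_abs = res$mean_abs,
          valid_fraction = res$valid_fraction,
          fiducial_rms = res$fiducial_rms,
          failed = !is.finite(res$rmse),
          d = if (is.null(params_used)) NA_integer_ else params_used$dot_distance_d,
          s = if (is.null(params_used)) NA_integer_ else params_used$dot_size_s)
        if (keep_clouds) {
          clouds[[ri]] <- if (is.null(res$cloud)) NULL else {
            cropped_registered_cloud(res$cloud, res$transform, scene$roi)
          }
        }
        if (progress) {
          message(sprintf("zoom %.1f rep %d %-16s rmse %.3f mm (valid %.2f)",
                          zoom, rep_i, method, res$rmse,
                          res$valid_fraction %||% NA_real_))
        }
      }
    }
  }
  records <- dplyr::bind_rows(rows)
  if (keep_clouds) records$cloud <- clouds
  attr(records, "config") <- config
  attr(records, "master_seed") <- as.integer(master_seed)
  records
}

cropped_registered_cloud <- function(cloud, transform, roi) {
  moved <- transform_points(transform, cloud$points)
  inside <- moved[, 1] >= roi$lower[1] & moved[, 1] <= roi$upper[1] &
    moved[, 2] >= roi$lower[2] & moved[, 2] <= roi$upper[2] &
    moved[, 3] >= roi$lower[3] & moved[, 3] <= roi$upper[3]
  point_cloud(moved[inside, , drop = FALSE], frame = "ground_truth")
}

#' Summarize experiment records into the per-cell comparison table
#'
#' Arithmetic mean and sample standard deviation (denominator n - 1) of the
#' finite RMSE values per (zoom, method) cell; failed reconstructions are
#' counted separately, never silently dropped.
#'
#' @param records Tibble from [run_experiment()].
#' @return Tibble: zoom, method, mean_rmse, sd_rmse, n, n_failed.
#' @export
summarize_records <- function(records) {
  stopifnot(all(c("zoom", "method", "rmse") %in% names(records)))
  out <- records |>
    dplyr::group_by(.data$zoom, .data$method) |>
    dplyr::summarise(
      mean_rmse = mean(.data$rmse[is.finite(.data$rmse)]),
      sd_rmse = stats::sd(.data$rmse[is.finite(.data$rmse)]),
      n = sum(is.finite(.data$rmse)),
      n_failed = sum(!is.finite(.data$rmse)),
      .groups = "drop")
  empty <- out$n == 0
  if (any(empty)) {
    stop("no successful reconstructions in cell(s): ",
         paste(sprintf("(zoom %.1f, %s)", out$zoom[empty], out$method[empty]),
               collapse = ", "), call. = FALSE)
  }
  out
}

#' Write the experiment report files
#'
#' Writes the records and summary as CSV, per-method Z-difference heat maps
#' (grayscale PGM on a shared symmetric color scale, plus a combined ggplot
#' when clouds are present), and a JSON manifest with the configuration
#' digest and every seed needed for bit-exact replay.
#'
#' @param records Records from `run_experiment(..., keep_clouds = TRUE)`
#'   (heat maps are skipped with a warning for records without clouds).
#' @param out_dir Output directory.
#' @param heatmap_zoom Zoom level whose repeats feed the heat maps (default:
#'   highest zoom present).
#' @param grid_mm Heat-map cell size.
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(records, out_dir, heatmap_zoom = NULL, grid_mm = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rec_path <- file.path(out_dir, "records.csv")
  utils::write.csv(dplyr::select(records, -dplyr::any_of("cloud")), rec_path,
                   row.names = FALSE)
  files <- c(files, rec_path)
  sum_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summarize_records(records), sum_path, row.names = FALSE)
  files <- c(files, sum_path)

  config <- attr(records, "config")
  heatmap_zoom <- heatmap_zoom %||% max(records$zoom)
  if (!is.null(records[["cloud"]]) && !is.null(config)) {
    scene <- generate_phantom(config$scene_seed, config$complexity)
    gt_cloud <- sample_ground_truth_cloud(scene, config$gt_points,
                                          seed = derive_seed(attr(records, "master_seed") %||% 0L, 31))
    maps <- list()
    for (method in unique(records$method)) {
      i <- which(records$method == method &
                   abs(records$zoom - heatmap_zoom) < 1e-9 &
                   !vapply(records$cloud, is.null, TRUE))
      if (length(i) == 0) {
        warning("no stored cloud for method ", method, "; heat map skipped")
        next
      }
      cl <- records$cloud[[i[1]]]
      maps[[method]] <- z_difference_heatmap(cl, gt_cloud, grid_mm = grid_mm)
    }
    if (length(maps)) {
      limit <- max(vapply(maps, function(m) {
        mx <- suppressWarnings(max(abs(m$values), na.rm = TRUE))
        if (is.finite(mx)) mx else 0
      }, 1))
      limit <- max(limit, 1e-6)
      for (method in names(maps)) {
        hm_path <- file.path(out_dir, sprintf("heatmap_%s.pgm", method))
        write_heatmap_pgm(maps[[method]], hm_path, limit)
        files <- c(files, hm_path)
      }
    }
  } else {
    warning("records carry no clouds; heat maps skipped", call. = FALSE)
  }

  manifest <- list(schema = "stereomire-experiment-manifest", version = 1L,
                   master_seed = attr(records, "master_seed"),
                   n_records = nrow(records),
                   zooms = unique(records$zoom),
                   methods = unique(records$method),
                   heatmap_zoom = heatmap_zoom,
                   seeds = records[, c("zoom", "method", "repeat_index",
                                       "pose_seed", "render_seed")])
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, man_path)
  invisible(files)
}

# signed heat map to 8-bit grayscale: 128 = 0, symmetric limits, masked = 0
write_heatmap_pgm <- function(hm, path, limit) {
  v <- hm$values
  g <- round(128 + 127 * pmin(1, pmax(-1, as.vector(v) / limit)))
  g[!is.finite(g)] <- 0
  write_pgm(matrix(as.integer(g), nrow(v), ncol(v)), path)
}

#' Optimize the adaptive pattern per zoom over the full pipeline
#'
#' Runs [optimize_pattern()] for every zoom with the end-to-end evaluator
#' (render with the candidate dot pattern, reconstruct, register, score
#' against the ground truth at a fixed phantom pose), and returns the
#' per-zoom lookup table of best parameters; histories are attached.
#'
#' @param config An [experiment_config()] (its zooms are optimized).
#' @param master_seed Master seed.
#' @param n_init,n_iter Optimization protocol (defaults 10 random + 15
#'   guided evaluations).
#' @param n_eval_poses Phantom poses averaged per candidate evaluation
#'   (default 2). A single fixed pose lets the optimizer overfit that pose;
#'   averaging over a couple of draws from the experiment's pose
#'   distribution optimizes the error the comparison actually measures. A
#'   candidate that fails at any pose scores `+Inf` (fragility is
#'   penalized).
#' @param calibrations Optional precomputed [experiment_calibration()].
#' @param progress Print per-zoom progress.
#' @return Tibble zoom/d/s/error_mm/n_evals with attribute `histories`
#'   (list of `opt_result`).
#' @export
build_zoom_lookup <- function(config = experiment_config(), master_seed = 0L,
                              n_init = 10L, n_iter = 15L, n_eval_poses = 2L,
                              calibrations = NULL, progress = FALSE) {
  scene <- generate_phantom(config$scene_seed, config$complexity)
  gt_cloud <- sample_ground_truth_cloud(scene, config$gt_points,
                                        seed = derive_seed(master_seed, 31))
  calibrations <- calibrations %||% experiment_calibration(config, master_seed)
  rows <- list()
  histories <- list()
  for (zi in seq_along(config$zooms)) {
    zoom <- config$zooms[zi]
    rig <- make_zoom_rig(zoom, config$rig)
    entry <- calibrations[[zi]]
    eval_seed <- derive_seed(master_seed, 61, zi)
    eval_poses <- lapply(seq_len(n_eval_poses), function(k) {
      if (k == 1) default_scene_pose(config$rig$aim_distance_mm)
      else perturbed_pose(config, derive_seed(master_seed, 63, zi, k))
    })
    evaluator <- function(params) {
      illum <- illumination_config("adaptive_pattern",
                                   pattern = generate_dot_pattern(params),
                                   noise_sigma = config$noise_sigma)
      mean(vapply(eval_poses, function(pose) {
        evaluate_reconstruction(scene, gt_cloud, rig, entry, illum, pose,
                                config, eval_seed)$rmse
      }, numeric(1)))
    }
    res <- optimize_pattern(evaluator, n_init = n_init, n_iter = n_iter,
                            seed = derive_seed(master_seed, 62, zi))
    histories[[zi]] <- res
    rows[[zi]] <- tibble::tibble(zoom = zoom,
                                 d = res$best_params$dot_distance_d,
                                 s = res$best_params$dot_size_s,
                                 error_mm = res$best_error,
                                 n_evals = nrow(res$history))
    if (progress) {
      message(sprintf("zoom %.1f: best (d=%d, s=%d), rmse %.4f mm",
                      zoom, rows[[zi]]$d, rows[[zi]]$s, rows[[zi]]$error_mm))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "histories") <- histories
  out
}

#' Save / load an adaptive pattern lookup table as JSON
#'
#' @param table Tibble zoom/d/s (optionally error_mm, n_evals).
#' @param path JSON path.
#' @return `path` invisibly; `load_pattern_lookup()` returns the tibble.
#' @export
save_pattern_lookup <- function(table, path) {
  jsonlite::write_json(list(schema = "stereomire-pattern-lookup", version = 1L,
                            entries = table),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_pattern_lookup
#' @export
load_pattern_lookup <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "stereomire-pattern-lookup")) {
    stop("not a pattern lookup table: ", path, call. = FALSE)
  }
  tibble::as_tibble(payload$entries)
}
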