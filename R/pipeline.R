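# Experiment orchestration: reference configuration, master-seed fan-out,
# the three-condition comparison (no scatter / scatter / corrected), and
# scatter-map validation.

#' Reference run configuration
#'
#' Collects every tunable of the pipeline with the reference defaults:
#' 120 kVp + 4 mm Al beam at 1 mGy entrance kerma, 40 x 40 cm detector at
#' 1 mm effective pitch, 30/70 keV thresholds, 25 blocker positions at 1/25
#' dose each, shadow-core sampling with 3 columns, cubic interpolation and
#' 5 mm Gaussian smoothing.
#'
#' @param sizes phantom sizes to run.
#' @param kvp,filtration_mm_al beam settings.
#' @param total_mgy entrance air kerma of the composite acquisition, mGy.
#' @param n_photons,max_order,rayleigh,coarse_n,coarse_smooth_nodes Monte
#'   Carlo transport settings (see [simulate_scatter()]).
#' @param n_positions blocker positions (= frames).
#' @param k_center,median_window,sigma_mm scatter-estimator settings (see
#'   [sample_scatter()] and [reconstruct_scatter_map()]).
#' @param epsilon count floor used when subtracting scatter.
#' @param thresholds_kev,sigma_kev,sensor_mm detector settings.
#' @param detector_cm,pitch_mm,binning,sdd_cm,sid_cm,blocker_plane_cm
#'   geometry settings.
#' @param reference_pmma_mm open-beam reference slab thickness.
#' @param weights_mode `"per_state"`: cancellation weights recalibrated for
#'   each scatter condition (default); `"frozen"`: calibrated once on the
#'   scatter-free condition and reused (ablation).
#' @param dse_denominator `"ka"` or `"sqrt_ka"` (see [compute_dse()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(sizes = c("small", "standard", "large"),
                       kvp = 120, filtration_mm_al = 4, total_mgy = 1,
                       n_photons = 2e6, max_order = 3, rayleigh = FALSE,
                       coarse_n = 25, coarse_smooth_nodes = 1.5,
                       n_positions = 25, k_center = 3, median_window = 5,
                       sigma_mm = 5, epsilon = 1e-3,
                       thresholds_kev = c(30, 70), sigma_kev = 1.6,
                       sensor_mm = 0.75,
                       detector_cm = 40, pitch_mm = 0.1, binning = 10L,
                       sdd_cm = 180, sid_cm = 150, blocker_plane_cm = 20,
                       reference_pmma_mm = 60,
                       weights_mode = c("per_state", "frozen"),
                       dse_denominator = "ka", seed = 1L) {
  weights_mode <- match.arg(weights_mode)
  cfg <- as.list(environment())
  if (cfg$n_photons < 1) stop("n_photons must be >= 1")
  if (cfg$total_mgy <= 0) stop("total_mgy must be positive")
  if (!all(cfg$sizes %in% c("small", "standard", "large")))
    stop("unknown phantom size")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(run_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> sizes: %s; %g kVp + %g mm Al; %g mGy; %g photon histories; seed %d\n",
              paste(x$sizes, collapse = "/"), x$kvp, x$filtration_mm_al,
              x$total_mgy, x$n_photons, x$seed))
  invisible(x)
}

config_geometry <- function(cfg)
  beam_geometry(cfg$sdd_cm, cfg$sid_cm, cfg$detector_cm, cfg$pitch_mm,
                cfg$binning, cfg$blocker_plane_cm)

config_detector <- function(cfg)
  detector_model(cfg$thresholds_kev, cfg$sigma_kev, cfg$sensor_mm)

# DEC rows for every insert in both subtraction images of one state.
dec_for_state <- function(de1, de2, rois) {
  rows <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    rbind(
      data.frame(image = "s", material = roi$material,
                 thickness = roi$thickness,
                 dec = compute_dec(de1$i_s, de2$i_s, roi)$dec),
      data.frame(image = "b", material = roi$material,
                 thickness = roi$thickness,
                 dec = compute_dec(de1$i_b, de2$i_b, roi)$dec))
  })
  do.call(rbind, rows)
}

#' Run the full simulation experiment
#'
#' For each phantom size: simulates the blocker-free primary and scatter
#' images at the configured kerma, acquires two independent moving-blocker
#' frame sets, reconstructs the per-bin scatter maps, validates them against
#' the expected-scatter truth, builds the three scatter conditions (no
#' scatter / with scatter / corrected) in two noise realizations each,
#' performs the dual-energy subtraction with per-state calibrated weights,
#' and computes per-insert DEC.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: writes the DEC report (TSV), the
#'   configuration (YAML), and phantom descriptions for provenance.
#' @param progress print per-stage progress lines.
#' @return An `experiment` list: per-size results (`truth` maps, `maps`
#'   estimates, `scatter_error`, `weights`, `dec` tables, seeds) plus
#'   `config` and the open-beam `reference`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           progress = FALSE) {
  geometry <- config_geometry(config)
  detector <- config_detector(config)
  say <- function(...) if (progress) message(sprintf(...))
  spectrum <- normalize_to_kerma(
    generate_spectrum(config$kvp, config$filtration_mm_al), config$total_mgy)
  rod <- blocker_positions(config$n_positions, geometry)
  mc_opts <- list(n_photons = config$n_photons, max_order = config$max_order,
                  rayleigh = config$rayleigh, coarse_n = config$coarse_n,
                  coarse_smooth_nodes = config$coarse_smooth_nodes)

  ref_ph <- reference_phantom(config$reference_pmma_mm, geometry)
  reference <- apply_detector(project_primary(ref_ph, spectrum, geometry),
                              detector = detector, sample = FALSE)
  say("open-beam reference done")

  sizes <- stats::setNames(vector("list", length(config$sizes)), config$sizes)
  for (size in config$sizes) {
    phantom <- build_phantom(size, geometry)
    say("[%s] primary projection", size)
    primary <- project_primary(phantom, spectrum, geometry)
    say("[%s] scatter transport (%g histories)", size, config$n_photons)
    scatter <- simulate_scatter(
      phantom, spectrum, geometry,
      n_photons = config$n_photons,
      seed = stage_seed(config$seed, paste0("mc-", size)),
      max_order = config$max_order, rayleigh = config$rayleigh,
      coarse_n = config$coarse_n,
      coarse_smooth_nodes = config$coarse_smooth_nodes, expand = FALSE)

    say("[%s] blocker frames", size)
    fsets <- lapply(1:2, function(r)
      acquire_frame_set(phantom, spectrum, geometry, detector, rod,
                        seed = stage_seed(config$seed,
                                          paste0("frames-", size, "-", r)),
                        scatter = scatter, primary = primary))
    truth <- fsets[[1]]$truth
    maps <- lapply(fsets, function(fs)
      reconstruct_scatter_map(
        sample_scatter(fs, config$k_center, config$median_window),
        geometry, config$sigma_mm))
    err <- scatter_error_metrics(truth$scatter, maps[[1]], geometry, phantom)
    err$le$map <- err$he$map <- NULL   # keep the summary, drop bulky maps
    say("[%s] scatter map error: mean %.3f%%, max %.3f%%",
        size, err$mean_pct, err$max_pct)

    rm(primary); gc(FALSE)

    states <- c("none", "uncorrected", "corrected")
    images <- list()
    for (r in 1:2) {
      sseed <- function(tag) stage_seed(config$seed,
                                        paste0(tag, "-", size, "-", r))
      exp_none <- truth$primary
      exp_unc <- list(le = truth$primary$le + truth$scatter$le,
                      he = truth$primary$he + truth$scatter$he)
      draw <- function(maps_exp, tag) with_seed(sseed(tag), new_binned_image(
        matrix(stats::rpois(length(maps_exp$le), maps_exp$le), nrow(maps_exp$le)),
        matrix(stats::rpois(length(maps_exp$he), maps_exp$he), nrow(maps_exp$he)),
        kerma_mgy = config$total_mgy))
      img_none <- draw(exp_none, "img-none")
      img_unc <- draw(exp_unc, "img-unc")
      img_cor <- subtract_scatter(img_unc, maps[[r]], config$epsilon)
      images[[r]] <- list(none = img_none, uncorrected = img_unc,
                          corrected = img_cor)
    }

    rois <- lapply(seq_len(nrow(phantom$inserts)), function(i)
      roi_spec(phantom, geometry, i))
    weights <- list(); dec <- list(); des <- list()
    for (state in states) {
      lp <- lapply(1:2, function(r) open_beam_log(images[[r]][[state]], reference))
      w <- calibrate_weights(lp[[1]], phantom, geometry)
      weights[[state]] <- w
      if (config$weights_mode == "frozen" && state != "none") w <- weights$none
      de <- lapply(lp, de_subtract, weights = w, scatter_state = state)
      des[[state]] <- de
      dec[[state]] <- dec_for_state(de[[1]], de[[2]], rois)
    }
    say("[%s] DEC done", size)

    sizes[[size]] <- list(phantom = phantom, truth = truth, maps = maps,
                          scatter_error = err, weights = weights,
                          dec = dec, subtractions = des,
                          frame_seeds = vapply(fsets, function(f)
                            as.numeric(f$frames[[1]]$seed), numeric(1)))
  }
  experiment <- structure(list(sizes = sizes, config = config,
                               reference = reference),
                          class = "experiment")
  if (!is.null(out_dir)) write_experiment(experiment, out_dir)
  experiment
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment> sizes: %s; seed %d\n",
              paste(names(x$sizes), collapse = ", "), x$config$seed))
  for (s in names(x$sizes))
    cat(sprintf("  %s: scatter-map error mean %.3f%% max %.3f%%\n", s,
                x$sizes[[s]]$scatter_error$mean_pct,
                x$sizes[[s]]$scatter_error$max_pct))
  invisible(x)
}

#' Validate an estimated scatter map against the truth
#'
#' Recomputes the per-bin percentage-error summary for one phantom size of an
#' experiment and extracts 1-D row profiles (truth vs estimate) for visual
#' comparison.
#'
#' @param experiment a [run_experiment()] result.
#' @param size phantom size to validate.
#' @param profile_rows detector row indices for the 1-D profiles.
#' @return List with `metrics` (per-bin mean/max percentage error) and
#'   `profiles` (data frame: row, column position, bin, truth, estimate).
#' @export
validate_scatter <- function(experiment, size = names(experiment$sizes)[1],
                             profile_rows = NULL) {
  res <- experiment$sizes[[size]]
  if (is.null(res)) stop("size not present in experiment: ", size)
  geometry <- config_geometry(experiment$config)
  metrics <- scatter_error_metrics(res$truth$scatter, res$maps[[1]], geometry,
                                   res$phantom)
  n <- nrow(res$truth$scatter$le)
  if (is.null(profile_rows))
    profile_rows <- round(n * c(0.25, 0.5, 0.75))
  pc <- pixel_centers(geometry)
  profiles <- do.call(rbind, lapply(profile_rows, function(r)
    do.call(rbind, lapply(c("le", "he"), function(b)
      data.frame(row = r, x_mm = pc, bin = b,
                 truth = res$truth$scatter[[b]][r, ],
                 estimate = res$maps[[1]][[b]][r, ])))))
  list(metrics = metrics, profiles = profiles)
}

write_experiment <- function(experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- dec_report(experiment)
  utils::write.table(report, file.path(out_dir, "dec_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- experiment$config
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  for (s in names(experiment$sizes))
    write_phantom_description(experiment$sizes[[s]]$phantom,
                              file.path(out_dir, paste0("phantom_", s, ".txt")))
  err <- do.call(rbind, lapply(names(experiment$sizes), function(s)
    data.frame(size = s,
               mean_pct = experiment$sizes[[s]]$scatter_error$mean_pct,
               max_pct = experiment$sizes[[s]]$scatter_error$max_pct)))
  utils::write.table(err, file.path(out_dir, "scatter_error.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
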