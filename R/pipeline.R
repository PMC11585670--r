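#' Configuration of an end-to-end experiment
#'
#' Bundles every parameter of a simulated E2E measurement session: the plan
#' specification, the dosimeter chain, the true-shift distribution, noise
#' levels, fit settings, and gamma criteria. A config plus a seed determines
#' a session bit-for-bit.
#'
#' @param dosimeter `"gel"`, `"film_coronal"`, or `"film_sagittal"`.
#' @param plan a [plan_spec()].
#' @param n_measurements measurements per session (default 5).
#' @param shift_sd per-axis SD (mm) of the true rigid shifts (default 0.2).
#' @param delivery_noise_sd_fraction per-voxel Gaussian noise fraction added
#'   to the delivered dose (default 0.001, the recalculated-plan level).
#' @param gel list of gel-chain parameters: `slope`, `intercept`, `noise_sd`
#'   (s^-1), `readout_spacing`, `output_spacing`.
#' @param film list of film-chain parameters: `curve` (a
#'   [calibration_curve()]), `plane_offset`, `pixel_spacing`, `od_noise_sd`,
#'   `marker_jitter_sd`.
#' @param roi_margin margin (mm) around the PTV bounding boxes for the fit
#'   ROI (default 5).
#' @param fit a [fit_settings()].
#' @param gamma a [gamma_params()].
#' @param seed integer master seed.
#' @return An object of class `e2e_config`.
#' @export
e2e_config <- function(dosimeter = c("gel", "film_coronal", "film_sagittal"),
                       plan = plan_spec(),
                       n_measurements = 5, shift_sd = 0.2,
                       delivery_noise_sd_fraction = 0.001,
                       gel = list(slope = 0.4, intercept = 1.2,
                                  noise_sd = 0,
                                  readout_spacing = c(0.78, 0.78, 2.0),
                                  output_spacing = c(1, 1, 1)),
                       film = list(curve = calibration_curve(10, 25),
                                   plane_offset = 0,
                                   pixel_spacing = c(1, 1),
                                   od_noise_sd = 0, marker_jitter_sd = 0),
                       roi_margin = 5,
                       fit = fit_settings(),
                       gamma = gamma_params(),
                       seed = 1L) {
  dosimeter <- match.arg(dosimeter)
  structure(list(dosimeter = dosimeter, plan = plan,
                 n_measurements = as.integer(n_measurements),
                 shift_sd = shift_sd,
                 delivery_noise_sd_fraction = delivery_noise_sd_fraction,
                 gel = gel, film = film, roi_margin = roi_margin,
                 fit = fit, gamma = gamma, seed = as.integer(seed)),
            class = "e2e_config")
}

#' Run a full end-to-end experiment on synthetic data
#'
#' Reproduces the study design in silico for one measurement session:
#' generate the dual-cone plan, draw `n_measurements` ground-truth rigid
#' shifts, push each delivered dose through the configured dosimeter chain
#' (gel: dose to R2 to normalised dose; film: plane extraction, OD
#' conversion, marker registration, 3D placement), recover each shift with
#' the correlation-ratio/Hooke-Jeeves fit, compute displacement vectors, and
#' run the gamma analysis on the *registered but unfitted* pair (so residual
#' geometric error is visible in the gamma, as in the measurement protocol).
#' Fully reproducible from the config's seed.
#'
#' @param config an [e2e_config()].
#' @return An object of class `session_report`: `measurements` (one row per
#'   measurement: ground-truth and fitted shifts, per-axis errors, planar/3D
#'   vectors, gamma pass rate, fit diagnostics), `aggregates` (session mean
#'   and SD per quantity), and `config`.
#' @export
run_e2e_experiment <- function(config) {
  stopifnot(inherits(config, "e2e_config"))
  plan <- generate_plan_dose(config$plan)
  roi_boxes <- ptv_roi_boxes(plan, margin = config$roi_margin)
  session <- simulate_session(plan, config$n_measurements,
                              shift_sd = config$shift_sd,
                              noise_sd_fraction = config$delivery_noise_sd_fraction,
                              seed = config$seed)
  set.seed(config$seed + 1L)
  chain_seeds <- sample.int(.Machine$integer.max, config$n_measurements)
  rows <- lapply(seq_along(session), function(i) {
    meas <- session[[i]]
    if (config$dosimeter == "gel") {
      g <- config$gel
      readout <- simulate_gel(meas$dose, slope = g$slope,
                              intercept = g$intercept,
                              noise_sd = g$noise_sd,
                              readout_spacing = g$readout_spacing,
                              seed = chain_seeds[i])
      measured <- gel_to_dose(readout, max(plan$dose$values),
                              output_spacing = g$output_spacing)
      fit <- fit_dose_to_readout(plan$dose, measured, roi_boxes,
                                 settings = config$fit)
      gam <- gamma_map(plan$dose, measured, config$gamma)
    } else {
      f <- config$film
      plane <- if (config$dosimeter == "film_coronal") "coronal" else "sagittal"
      scan <- simulate_film(meas$dose, plane = plane,
                            plane_offset = f$plane_offset, curve = f$curve,
                            pixel_spacing = f$pixel_spacing,
                            od_noise_sd = f$od_noise_sd,
                            marker_jitter_sd = f$marker_jitter_sd,
                            seed = chain_seeds[i])
      reg <- register_markers(scan)
      dose2d <- od_to_dose(scan, f$curve)
      placement <- place_film_in_3d(dose2d, scan$pixel_spacing,
                                    scan$origin2d, plane,
                                    scan$plane_offset, transform = reg,
                                    valid = attr(scan, "valid"))
      fit <- fit_dose_to_readout(plan$dose, placement, roi_boxes,
                                 settings = config$fit)
      gam <- gamma_film(plan$dose, placement, config$gamma)
    }
    tru <- meas$true_transform$translation
    vec <- displacement_vectors(fit$shift)
    data.frame(measurement = i, dosimeter = config$dosimeter,
               true_dx = tru[1], true_dy = tru[2], true_dz = tru[3],
               fit_dx = fit$shift[1], fit_dy = fit$shift[2],
               fit_dz = fit$shift[3],
               err_dx = fit$shift[1] - tru[1],
               err_dy = fit$shift[2] - tru[2],
               err_dz = fit$shift[3] - tru[3],
               v_xy = vec["v_xy"], v_xz = vec["v_xz"],
               v_yz = vec["v_yz"], v_3d = vec["v_3d"],
               similarity = fit$similarity,
               n_evaluations = fit$n_evaluations,
               gamma_pass_rate = gam$pass_rate,
               gamma_n_evaluated = gam$n_evaluated,
               row.names = NULL)
  })
  measurements <- do.call(rbind, rows)
  stats <- session_statistics(as.matrix(measurements[, c("fit_dx", "fit_dy",
                                                         "fit_dz")]))
  gamma_stats <- data.frame(
    quantity = "gamma_pass_rate",
    mean = mean(measurements$gamma_pass_rate),
    sd = if (nrow(measurements) >= 2) sd(measurements$gamma_pass_rate)
         else NA_real_)
  structure(list(measurements = measurements,
                 aggregates = rbind(stats, gamma_stats),
                 config = config),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("session_report:", x$config$dosimeter, "dosimeter,",
      nrow(x$measurements), "measurements\n")
  cat("  per-axis fitted shifts (mm):\n")
  print(round(x$measurements[, c("fit_dx", "fit_dy", "fit_dz", "v_3d",
                                 "gamma_pass_rate")], 4))
  cat("  session aggregates:\n")
  agg <- x$aggregates
  agg$mean <- round(agg$mean, 4); agg$sd <- round(agg$sd, 4)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write a session report to disk
#'
#' One machine-readable CSV per table (per-measurement records and session
#' aggregates) plus a plain-text manifest of the configuration, written
#' deterministically (identical inputs give byte-identical files).
#'
#' @param report a `session_report`.
#' @param dir output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_session_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             aggregates = file.path(dir, "aggregates.csv"),
             manifest = file.path(dir, "manifest.txt"))
  write.csv(report$measurements, paths["measurements"], row.names = FALSE)
  write.csv(report$aggregates, paths["aggregates"], row.names = FALSE)
  cfg <- report$config
  lines <- c(
    paste0("dosimeter: ", cfg$dosimeter),
    paste0("n_measurements: ", cfg$n_measurements),
    paste0("shift_sd_mm: ", cfg$shift_sd),
    paste0("delivery_noise_sd_fraction: ", cfg$delivery_noise_sd_fraction),
    paste0("roi_margin_mm: ", cfg$roi_margin),
    paste0("seed: ", cfg$seed),
    paste0("plan_grid_dim: ", paste(cfg$plan$dim, collapse = "x")),
    paste0("plan_spacing_mm: ", paste(cfg$plan$spacing, collapse = " ")),
    paste0("ptv_max_dose_Gy: ", cfg$plan$ptv_max_dose),
    paste0("gamma: ", 100 * cfg$gamma$dose_criterion_fraction, "%/",
           cfg$gamma$distance_criterion, "mm, threshold ",
           100 * cfg$gamma$threshold_fraction, "%"))
  writeLines(lines, paths["manifest"])
  invisible(paths)
}

#' Compare dosimeter kinds across sessions
#'
#' Aligns per-axis shifts, planar displacement vectors (the gel shifts
#' projected into each film plane), 3D vectors, and gamma pass rates across
#' dosimeter kinds, measurement by measurement, plus a row of session means.
#' Reports with differing measurement counts are aligned on the common
#' subset with a warning; absent reports produce explicit `NA` gaps.
#'
#' @param report_gel a `session_report` from a gel session (or `NULL`).
#' @param report_film_coronal,report_film_sagittal film `session_report`s
#'   (or `NULL`).
#' @return data.frame with one row per aligned measurement and a final
#'   `"mean"` row.
#' @export
compare_dosimeters <- function(report_gel, report_film_coronal = NULL,
                               report_film_sagittal = NULL) {
  reports <- list(gel = report_gel, film_cor = report_film_coronal,
                  film_sag = report_film_sagittal)
  reports_present <- Filter(Negate(is.null), reports)
  if (length(reports_present) == 0) stop("no session reports supplied")
  counts <- vapply(reports_present, function(r) nrow(r$measurements), 0L)
  n <- min(counts)
  if (length(unique(counts)) > 1)
    warning("mismatched measurement counts: aligning on the first ", n,
            " measurements")
  pick <- function(rep, col) {
    if (is.null(rep)) rep(NA_real_, n) else rep$measurements[[col]][seq_len(n)]
  }
  out <- data.frame(
    measurement = seq_len(n),
    gel_dx = pick(reports$gel, "fit_dx"),
    gel_dy = pick(reports$gel, "fit_dy"),
    gel_dz = pick(reports$gel, "fit_dz"),
    gel_v_xz = pick(reports$gel, "v_xz"),
    gel_v_yz = pick(reports$gel, "v_yz"),
    gel_v_3d = pick(reports$gel, "v_3d"),
    gel_gamma = pick(reports$gel, "gamma_pass_rate"),
    film_cor_dx = pick(reports$film_cor, "fit_dx"),
    film_cor_dz = pick(reports$film_cor, "fit_dz"),
    film_cor_v_xz = pick(reports$film_cor, "v_xz"),
    film_cor_gamma = pick(reports$film_cor, "gamma_pass_rate"),
    film_sag_dy = pick(reports$film_sag, "fit_dy"),
    film_sag_dz = pick(reports$film_sag, "fit_dz"),
    film_sag_v_yz = pick(reports$film_sag, "v_yz"),
    film_sag_gamma = pick(reports$film_sag, "gamma_pass_rate"))
  means <- c(measurement = NA, colMeans(out[, -1, drop = FALSE]))
  out <- rbind(out, means)
  out$row_kind <- c(rep("measurement", n), "mean")
  out
}
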