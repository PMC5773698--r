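#' Calibration set: paired spectra and reference glucose
#'
#' @param X normalized spectra (samples x wavenumbers).
#' @param y reference glucose (mg/dl).
#' @param grid the `wn_grid` of the spectra.
#' @param metadata optional list (site label, acquisition times, ...).
#' @return a `calibration_set`.
#' @export
calibration_set <- function(X, y, grid, metadata = list()) {
  X <- as.matrix(X)
  stopifnot(inherits(grid, "wn_grid"), nrow(X) == length(y),
            ncol(X) == length(grid$points))
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("calibration set must be finite")
  }
  structure(list(X = X, y = y, grid = grid, metadata = metadata),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d pairs x %d wavenumbers%s\n",
              nrow(x$X), ncol(x$X),
              if (!is.null(x$metadata$site)) paste0(" (", x$metadata$site, ")")
              else ""))
  invisible(x)
}

merge_args <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown key '", unknown[1], "' in ", where, " configuration")
  }
  utils::modifyList(defaults, user)
}

#' Configuration of a full glucose correlation experiment
#'
#' Bundles the skin, instrument, protocol, glucose-excursion, meter and
#' chemometrics parameters of one simulated oral-glucose-tolerance
#' experiment. Defaults follow the measurement protocol: 23 spectrum/
#' reference pairs on a 5-minute cadence, glucose intake 20 minutes after
#' the start, both probe sites acquired in every slot, 950--1240 cm^-1
#' scans at 1.38 cm^-1 per point.
#'
#' @param skin,instrument,protocol,glucose,meter,chemometrics,grid named
#'   lists overriding individual defaults (unknown keys are rejected).
#' @param seed integer seed driving the whole experiment.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(skin = list(), instrument = list(),
                              protocol = list(), glucose = list(),
                              meter = list(), chemometrics = list(),
                              grid = list(), seed = 1L) {
  cfg <- structure(list(
    skin = merge_args(list(
      extent_um = 1320, resolution_um = 5.5, ridge_period_um = 450,
      curvature = 0, gland_density_cm2 = 350, s_max_mean = 2,
      s_max_sd = 0.5, tau_min = 15, pore_sigma_um = 50,
      min_pore_spacing_um = 120, ridge_top_threshold = 0.9,
      baseline_b0 = 1, baseline_b1 = 0.5, kappa_glucose = 1e-3,
      secretion_noise_rel = 0.15, secretion_band_noise_rel = 0.2,
      secretion_band_shift_cm1 = 2, glucose_mg_dl = 100), skin, "skin"),
    instrument = merge_args(list(
      beam_diameter_um = 90, focal_distance_mm = 50.4, n_pixels = 30,
      step_um = 44, imaging_wavenumber = 1040, rep_rate_hz = 47500,
      pulse_width_ns = 500, lockin_tc_ms = 30, n_repeats = 16,
      cell_f0_hz = 47500, cell_q = 17, noise_sigma = 45),
      instrument, "instrument"),
    protocol = merge_args(list(
      duration_min = 120, cadence_min = 5, intake_min = 20,
      n_pairs = 23, t_image_min = 2), protocol, "protocol"),
    glucose = merge_args(list(
      baseline_mg_dl = 90, peak_rise_mg_dl = 80, drift_sd_mg_dl = 1,
      t_absorb_min = 20, t_elim_min = 80), glucose, "glucose"),
    meter = merge_args(list(sigma_rel = 0.05), meter, "meter"),
    chemometrics = merge_args(list(max_lv = 10, method = "plsr"),
                              chemometrics, "chemometrics"),
    grid = merge_args(list(start = 950, stop = 1240, step = 1.38),
                      grid, "grid"),
    seed = as.integer(seed)
  ), class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  p <- cfg$protocol
  if (p$n_pairs < 3) stop("protocol needs n_pairs >= 3 for cross-validation")
  if (abs(p$duration_min %% p$cadence_min) > 1e-9 &&
      abs(p$cadence_min - p$duration_min %% p$cadence_min) > 1e-9) {
    stop("reference cadence must divide the experiment duration")
  }
  if (cfg$glucose$baseline_mg_dl <= 0) stop("baseline glucose must be positive")
  if (p$intake_min >= p$duration_min) {
    stop("glucose intake must fall inside the experiment duration")
  }
  last <- p$t_image_min + (p$n_pairs - 1) * p$cadence_min
  if (last > p$duration_min) {
    stop("protocol does not fit: last pair at ", last,
         " min exceeds the ", p$duration_min, " min duration")
  }
  invisible(cfg)
}

#' Run one simulated glucose correlation experiment
#'
#' Executes the full image-guided protocol: hand wash (secretion clock
#' reset), initial 2-D position scan at the imaging wavenumber, probe-site
#' selection (darkest valley point and brightest ridge point), then for
#' each reference slot a 16-repeat averaged wavenumber scan at both sites
#' (pulse-energy normalized) paired with an invasive reference-meter
#' reading, a final position scan confirming the finger did not move, and
#' per-site leave-one-out PLSR (or PCR) calibration with clinical-accuracy
#' evaluation.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_result`: per-site `calibration`, `cv`,
#'   `reports` (named `non_secreting` / `secreting`), the `sites`
#'   selection, before/after `images`, the `glucose_profile`, acquisition
#'   `times_min`, `displacement_um`, and a run `log`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  validate_experiment_config(config)
  set.seed(config$seed)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  inst <- do.call(instrument_config, config$instrument)
  grid <- do.call(make_wavenumber_grid, config$grid)
  p <- config$protocol

  note("hand wash: secretion clock reset to 0 min (seed %d)", config$seed)
  map <- do.call(generate_skin_map, config$skin)
  note("skin map: %d pores on %g um field", nrow(map$pores), map$extent)

  profile <- ogtt_glucose_profile(
    duration_min = p$duration_min, intake_min = p$intake_min,
    baseline_mg_dl = config$glucose$baseline_mg_dl,
    peak_rise_mg_dl = config$glucose$peak_rise_mg_dl,
    cadence_min = p$cadence_min,
    t_absorb_min = config$glucose$t_absorb_min,
    t_elim_min = config$glucose$t_elim_min,
    drift_sd_mg_dl = config$glucose$drift_sd_mg_dl)
  map <- set_glucose_profile(map, profile)
  note("oral glucose tolerance profile: intake at %g min", p$intake_min)

  image_before <- raster_scan(map, t = p$t_image_min, config = inst)
  sel <- select_probe_sites(image_before)
  note("position scan at %g cm^-1, t = %g min: %d blob(s); dark (%g, %g) um, bright (%g, %g) um",
       inst$imaging_wavenumber, p$t_image_min, nrow(sel$blobs$summaries),
       sel$dark_site$x_um, sel$dark_site$y_um,
       sel$bright_site$x_um, sel$bright_site$y_um)

  meter <- meter_model(config$meter$sigma_rel)
  times <- p$t_image_min + (seq_len(p$n_pairs) - 1) * p$cadence_min
  nw <- length(grid$points)
  X <- list(non_secreting = matrix(NA_real_, p$n_pairs, nw),
            secreting = matrix(NA_real_, p$n_pairs, nw))
  pos <- list(non_secreting = c(sel$dark_site$x_um, sel$dark_site$y_um),
              secreting = c(sel$bright_site$x_um, sel$bright_site$y_um))
  y <- numeric(p$n_pairs)
  for (k in seq_len(p$n_pairs)) {
    g_true <- map$glucose_fun(times[k])
    for (site in names(X)) {
      s <- acquire_spectrum(map, pos[[site]], times[k], grid, inst)
      s <- normalize_by_pulse_energy(s, inst)
      X[[site]][k, ] <- s$values
    }
    y[k] <- reference_meter_reading(g_true, meter)
  }
  note("acquired %d pairs at both sites (cadence %g min, 16-repeat averaged, pulse-energy normalized)",
       p$n_pairs, p$cadence_min)

  image_after <- raster_scan(map, t = times[p$n_pairs] + p$t_image_min,
                             config = inst)
  displacement_um <- 0  # finger fixed to the cell throughout
  note("final position scan: probing-site displacement %g um", displacement_um)

  calibration <- cv <- reports <- list()
  for (site in names(X)) {
    cs <- calibration_set(X[[site]], y, grid,
                          metadata = list(site = site, times_min = times))
    res <- loo_cv(cs$X, cs$y, max_lv = config$chemometrics$max_lv,
                  method = config$chemometrics$method)
    rep_ <- evaluate_experiment(res$y_cv, y,
                                rmsec = res$rmsec_by_lv[res$chosen_lv],
                                rmsecv = res$rmsecv_by_lv[res$chosen_lv])
    calibration[[site]] <- cs
    cv[[site]] <- res
    reports[[site]] <- rep_
    note("%s site: %d latent variable(s), RMSE-CV %.2f mg/dl, MARD %.2f%%",
         site, res$chosen_lv, res$rmsecv_by_lv[res$chosen_lv], rep_$mard)
  }

  structure(list(config = config, sites = sel,
                 images = list(before = image_before, after = image_after),
                 calibration = calibration, cv = cv, reports = reports,
                 glucose_profile = profile, times_min = times,
                 displacement_um = displacement_um, log = log),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", length(x$times_min), "pairs per site\n")
  for (site in names(x$reports)) {
    r <- x$reports[[site]]
    cat(sprintf("  %-14s MARD %6.2f %%  MAD %6.2f mg/dl  zone A %3.0f %%\n",
                site, r$mard, r$mad, 100 * r$zone_fractions[["A"]]))
  }
  invisible(x)
}

#' Replicate the experiment and pool the results
#'
#' Runs independently seeded replicates of the full protocol and pools
#' them: per-replicate MARD/MAD per site plus pooled Clarke tallies and
#' pooled accuracy over the concatenated prediction pairs (the pooling
#' used when several experiments are reported on one error grid).
#'
#' @param config an [experiment_config()] (its `seed` is ignored).
#' @param n_reps number of replicates.
#' @param seed seed for the replicate seed sequence.
#' @return a `replicate_summary`: data.frame `per_rep`, list `pooled`
#'   (per-site `evaluation_report` over concatenated pairs), `n_reps`.
#' @export
run_replicates <- function(config = experiment_config(), n_reps = 5,
                           seed = 1L) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  rows <- list(); pairs <- list(non_secreting = NULL, secreting = NULL)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[i]
    res <- run_experiment(cfg)
    for (site in names(res$reports)) {
      r <- res$reports[[site]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, seed = rep_seeds[i], site = site,
        chosen_lv = res$cv[[site]]$chosen_lv,
        rmsecv = r$rmsecv, mard = r$mard, mad = r$mad,
        zone_a = r$zone_fractions[["A"]])
      pairs[[site]] <- rbind(pairs[[site]],
                             cbind(ref = res$calibration[[site]]$y,
                                   pred = res$cv[[site]]$y_cv))
    }
  }
  pooled <- lapply(pairs, function(m) {
    evaluate_experiment(m[, "pred"], m[, "ref"])
  })
  structure(list(per_rep = do.call(rbind, rows), pooled = pooled,
                 n_reps = n_reps),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary>", x$n_reps, "replicate(s)\n")
  agg <- stats::aggregate(cbind(mard, mad) ~ site, data = x$per_rep, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-14s mean MARD %6.2f %%  mean MAD %6.2f mg/dl  pooled zone A %3.0f %%\n",
                agg$site[i], agg$mard[i], agg$mad[i],
                100 * x$pooled[[agg$site[i]]]$zone_fractions[["A"]]))
  }
  invisible(x)
}
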