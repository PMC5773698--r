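#' Synthetic fingertip skin map
#'
#' Ground truth for the forward model: a periodic friction-ridge height
#' field, eccrine sweat pores placed on ridge tops by a thinned Poisson
#' process, and per-analyte concentration fields (skin baseline tracking
#' the ridges, a spatially uniform interstitial glucose term, and
#' lactate-rich secretion spots growing around each pore after hand
#' washing).
#'
#' Matrices are indexed `[iy, ix]`; physical positions are `(x, y)` in
#' micrometres with cell centers at `(i - 1/2) * resolution`.
#'
#' @param extent_um side length of the simulated square of skin (um).
#' @param resolution_um ground-truth cell size (um).
#' @param ridge_period_um friction-ridge spacing (um); adult fingertips run
#'   around 450 um.
#' @param curvature bending of the ridges (1/um); 0 gives straight ridges,
#'   a positive value bends them into the U shapes seen on some fingertip
#'   regions.
#' @param gland_density_cm2 eccrine gland density (glands per cm^2); the
#'   volar distal phalanx carries about 350.
#' @param s_max_mean,s_max_sd mean and sd of the per-pore saturated
#'   secretion amplitude (concentration units); gamma-distributed.
#' @param tau_min secretion time constant (minutes); 15 min saturates the
#'   signal about one hour after washing.
#' @param pore_sigma_um Gaussian radius of the secretion spot around a pore
#'   duct (um).
#' @param min_pore_spacing_um minimum center-to-center pore distance (um).
#' @param ridge_top_threshold ridge-field value above which a position
#'   counts as a ridge top (pore ducts open there).
#' @param baseline_b0,baseline_b1 skin-baseline concentration is
#'   `b0 + b1 * ridge_field`: valleys darker than ridge tops.
#' @param kappa_glucose interstitial glucose concentration per mg/dl of
#'   blood glucose (concentration units / (mg/dl)).
#' @param secretion_noise_rel relative sd of the minute-to-minute secretion
#'   amount fluctuation applied per pore at each acquisition (0 disables
#'   it).
#' @param secretion_band_noise_rel relative sd of the per-band height
#'   fluctuation of the secretion spectrum at each acquisition, emulating
#'   the varying composition (lactate, urea, minerals, water) of freshly
#'   secreted sweat; 0 freezes the secretion spectrum to the library
#'   lactate shape.
#' @param secretion_band_shift_cm1 sd of the per-band center shift (cm^-1)
#'   at each acquisition (hydration/counter-ion state of the residue);
#'   0 disables it.
#' @param glucose_mg_dl resting blood glucose (mg/dl) used until a profile
#'   is attached with [set_glucose_profile()].
#' @param seed optional integer; when non-NULL the RNG is seeded so the map
#'   is reproducible.
#' @return A `skin_map` object.
#' @export
generate_skin_map <- function(extent_um = 1320,
                              resolution_um = 5.5,
                              ridge_period_um = 450,
                              curvature = 0,
                              gland_density_cm2 = 350,
                              s_max_mean = 2,
                              s_max_sd = 0.5,
                              tau_min = 15,
                              pore_sigma_um = 50,
                              min_pore_spacing_um = 120,
                              ridge_top_threshold = 0.9,
                              baseline_b0 = 1,
                              baseline_b1 = 0.5,
                              kappa_glucose = 1e-3,
                              secretion_noise_rel = 0.15,
                              secretion_band_noise_rel = 0.2,
                              secretion_band_shift_cm1 = 2,
                              glucose_mg_dl = 100,
                              seed = NULL) {
  stopifnot(extent_um > 0, resolution_um > 0, ridge_period_um > 0,
            gland_density_cm2 >= 0, tau_min > 0, pore_sigma_um > 0)
  if (!is.null(seed)) set.seed(seed)

  n <- max(2L, round(extent_um / resolution_um))
  centers <- (seq_len(n) - 0.5) * resolution_um
  xc <- matrix(centers, n, n, byrow = TRUE)   # [iy, ix] -> x
  yc <- matrix(centers, n, n, byrow = FALSE)  # [iy, ix] -> y
  u <- xc + curvature * (yc - extent_um / 2)^2
  ridge <- 0.5 * (1 + cos(2 * pi * u / ridge_period_um))

  ridge_fun <- function(x, y) {
    0.5 * (1 + cos(2 * pi * (x + curvature * (y - extent_um / 2)^2) /
                     ridge_period_um))
  }

  area_cm2 <- (extent_um / 1e4)^2
  n_pores <- if (gland_density_cm2 > 0) stats::rpois(1, gland_density_cm2 * area_cm2) else 0L
  if (n_pores * min_pore_spacing_um^2 > extent_um^2) {
    stop("gland density too high: ", n_pores, " pores cannot keep a ",
         min_pore_spacing_um, " um minimum spacing within ", extent_um,
         " um of skin")
  }
  px <- numeric(0); py <- numeric(0)
  tries <- 0L; max_tries <- 10000L * max(1L, n_pores)
  while (length(px) < n_pores) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("gland density too high: could not place ", n_pores,
           " pores on ridge tops with ", min_pore_spacing_um,
           " um minimum spacing")
    }
    cx <- stats::runif(1, 0, extent_um)
    cy <- stats::runif(1, 0, extent_um)
    if (ridge_fun(cx, cy) < ridge_top_threshold) next
    if (length(px) > 0 &&
        min(sqrt((px - cx)^2 + (py - cy)^2)) < min_pore_spacing_um) next
    px <- c(px, cx); py <- c(py, cy)
  }
  if (n_pores > 0) {
    if (s_max_mean <= 0) {
      s_max <- rep(0, n_pores)
    } else if (s_max_sd <= 0) {
      s_max <- rep(s_max_mean, n_pores)
    } else {
      shape <- (s_max_mean / s_max_sd)^2
      s_max <- stats::rgamma(n_pores, shape = shape,
                             rate = shape / s_max_mean)
    }
    pores <- data.frame(x = px, y = py, s_max = s_max, tau = tau_min)
  } else {
    pores <- data.frame(x = numeric(0), y = numeric(0),
                        s_max = numeric(0), tau = numeric(0))
  }

  # per-pore unit secretion spot on the fine grid, cached for reuse
  spots <- lapply(seq_len(nrow(pores)), function(i) {
    exp(-((xc - pores$x[i])^2 + (yc - pores$y[i])^2) /
          (2 * pore_sigma_um^2))
  })

  structure(list(
    extent = extent_um, resolution = resolution_um, n = n,
    centers = centers,
    ridge_period = ridge_period_um, curvature = curvature,
    ridge_field = ridge, ridge_fun = ridge_fun,
    ridge_top_threshold = ridge_top_threshold,
    pores = pores, pore_spots = spots, pore_sigma = pore_sigma_um,
    baseline_b0 = baseline_b0, baseline_b1 = baseline_b1,
    kappa_glucose = kappa_glucose,
    secretion_noise_rel = secretion_noise_rel,
    secretion_band_noise_rel = secretion_band_noise_rel,
    secretion_band_shift_cm1 = secretion_band_shift_cm1,
    glucose_fun = local({
      g0 <- glucose_mg_dl
      function(t) rep(g0, length(t))
    })
  ), class = "skin_map")
}

#' @export
print.skin_map <- function(x, ...) {
  cat(sprintf(paste0("<skin_map> %g x %g um at %g um resolution, ",
                     "ridge period %g um, %d pores\n"),
              x$extent, x$extent, x$resolution, x$ridge_period,
              nrow(x$pores)))
  invisible(x)
}

#' Eccrine secretion kinetics after hand washing
#'
#' Secretion re-accumulates from zero at the washed-skin state and
#' saturates exponentially: `s(t) = s_max * (1 - exp(-t / tau))`. With the
#' default `tau = 15` min the level passes 98% of saturation by one hour.
#'
#' @param t minutes since hand washing (vectorized, must be >= 0).
#' @param pore list or one-row data.frame with `s_max` and `tau`.
#' @return secretion amplitude(s), same length as `t`.
#' @export
secretion_level <- function(t, pore) {
  if (any(t < 0)) stop("time since washing must be non-negative")
  pore$s_max * (1 - exp(-t / pore$tau))
}

#' Ridge field value at physical positions
#'
#' @param map a `skin_map`.
#' @param x,y positions (um), vectorized.
#' @return ridge height in `[0, 1]`.
#' @export
ridge_at <- function(map, x, y) map$ridge_fun(x, y)

#' Per-analyte concentration fields at a time point
#'
#' Evaluates the ground-truth concentration of each analyte on the map's
#' fine grid: the static skin baseline, the uniform glucose field driven by
#' the attached blood-glucose profile, and the lactate secretion spots with
#' amplitudes `secretion_level(t, pore) * (1 + jitter)`.
#'
#' @param map a `skin_map`.
#' @param t minutes since hand washing.
#' @param jitter optional per-pore relative amount fluctuation (length =
#'   number of pores); defaults to zero.
#' @param glucose_mg_dl optional override of the profile value at `t`.
#' @return named list of matrices: `skin_baseline`, `glucose`,
#'   `sodium_lactate`.
#' @export
skin_concentration_fields <- function(map, t, jitter = NULL,
                                      glucose_mg_dl = NULL) {
  stopifnot(inherits(map, "skin_map"), t >= 0)
  n <- map$n
  if (is.null(glucose_mg_dl)) glucose_mg_dl <- map$glucose_fun(t)
  baseline <- map$baseline_b0 + map$baseline_b1 * map$ridge_field
  glucose <- matrix(map$kappa_glucose * glucose_mg_dl, n, n)
  lactate <- matrix(0, n, n)
  npore <- nrow(map$pores)
  if (is.null(jitter)) jitter <- rep(0, npore)
  if (npore > 0) {
    amp <- secretion_level(t, map$pores) * pmax(0, 1 + jitter)
    for (i in seq_len(npore)) {
      if (amp[i] != 0) lactate <- lactate + amp[i] * map$pore_spots[[i]]
    }
  }
  list(skin_baseline = baseline, glucose = glucose,
       sodium_lactate = lactate)
}

# draw one acquisition's secretion fluctuations from the current RNG
# stream: per-pore amount jitter plus per-band height scales of the
# secretion spectrum (shared across pores: one sweat composition per
# acquisition)
draw_secretion_jitter <- function(map) {
  npore <- nrow(map$pores)
  amp <- if (npore == 0 || map$secretion_noise_rel <= 0) {
    rep(0, npore)
  } else {
    pmax(-0.9, stats::rnorm(npore, 0, map$secretion_noise_rel))
  }
  nb <- nrow(default_bands("sodium_lactate"))
  band_scale <- if (map$secretion_band_noise_rel <= 0) {
    rep(1, nb)
  } else {
    pmax(0.1, 1 + stats::rnorm(nb, 0, map$secretion_band_noise_rel))
  }
  band_shift <- if (map$secretion_band_shift_cm1 <= 0) {
    rep(0, nb)
  } else {
    stats::rnorm(nb, 0, map$secretion_band_shift_cm1)
  }
  list(amp = amp, band_scale = band_scale, band_shift = band_shift)
}

#' Add a sweat pore at a chosen position
#'
#' Mainly for controlled experiments: appends a pore (and its secretion
#' spot) to an existing map at an exact position, bypassing the Poisson
#' placement.
#'
#' @param map a `skin_map`.
#' @param x_um,y_um pore position (um).
#' @param s_max saturated secretion amplitude.
#' @param tau_min secretion time constant (minutes).
#' @return the updated map.
#' @export
add_pore <- function(map, x_um, y_um, s_max, tau_min = 15) {
  stopifnot(inherits(map, "skin_map"))
  map$pores <- rbind(map$pores,
                     data.frame(x = x_um, y = y_um, s_max = s_max,
                                tau = tau_min))
  xc <- matrix(map$centers, map$n, map$n, byrow = TRUE)
  yc <- matrix(map$centers, map$n, map$n, byrow = FALSE)
  map$pore_spots[[length(map$pore_spots) + 1L]] <-
    exp(-((xc - x_um)^2 + (yc - y_um)^2) / (2 * map$pore_sigma^2))
  map
}

#' Attach a blood-glucose time course to a skin map
#'
#' @param map a `skin_map`.
#' @param profile a [ogtt_glucose_profile()] result, or a function
#'   `t -> mg/dl`.
#' @return the map with its `glucose_fun` replaced (linear interpolation,
#'   clamped at the profile ends).
#' @export
set_glucose_profile <- function(map, profile) {
  stopifnot(inherits(map, "skin_map"))
  if (is.function(profile)) {
    map$glucose_fun <- profile
  } else {
    map$glucose_fun <- stats::approxfun(profile$times, profile$values,
                                        rule = 2)
  }
  map
}
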