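#' @title File formats
#' @description CSV writers emit numeric fields at 17 significant digits so
#'   write-then-read round trips are bit exact.
#' @noRd
fmt17 <- function(x) formatC(x, digits = 17, format = "g")

check_rectangular <- function(path, sep = ",") {
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("malformed CSV '", path, "': row ", bad, " has ", nf[bad],
         " field(s), expected ", nf[1])
  }
  invisible(nf[1])
}

#' Write / read a calibration set as CSV
#'
#' First column `reference_glucose_mg_dl`, one further column per
#' wavenumber with the wavenumber value (cm^-1) as its header.
#'
#' @param cs a [calibration_set()].
#' @param path file path.
#' @return `write_calibration_csv` returns `path` invisibly;
#'   `read_calibration_csv` returns a `calibration_set`.
#' @export
write_calibration_csv <- function(cs, path) {
  stopifnot(inherits(cs, "calibration_set"))
  header <- c("reference_glucose_mg_dl", fmt17(cs$grid$points))
  rows <- vapply(seq_along(cs$y), function(i) {
    paste(c(fmt17(cs$y[i]), fmt17(cs$X[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  check_rectangular(path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "reference_glucose_mg_dl") {
    stop("malformed calibration CSV: first column must be reference_glucose_mg_dl")
  }
  wn <- as.numeric(names(df)[-1])
  if (any(is.na(wn))) {
    stop("malformed calibration CSV: non-numeric wavenumber header at column ",
         which(is.na(wn))[1] + 1)
  }
  step <- if (length(wn) > 1) stats::median(diff(wn)) else 1
  grid <- structure(list(start = wn[1], stop = wn[length(wn)] + step,
                         step = step, points = wn), class = "wn_grid")
  calibration_set(as.matrix(df[, -1, drop = FALSE]),
                  df[[1]], grid)
}

#' Write / read a spectrum as CSV
#'
#' Columns `wavenumber_cm-1`, `value`.
#'
#' @param s a `pa_spectrum` (or `component_spectrum`).
#' @param path file path.
#' @export
write_spectrum_csv <- function(s, path) {
  writeLines(c("wavenumber_cm-1,value",
               paste(fmt17(s$grid$points), fmt17(s$values), sep = ",")),
             path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  check_rectangular(path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("wavenumber_cm-1", "value"))) {
    stop("malformed spectrum CSV: expected columns wavenumber_cm-1, value")
  }
  wn <- df[["wavenumber_cm-1"]]
  step <- if (length(wn) > 1) stats::median(diff(wn)) else 1
  grid <- structure(list(start = wn[1], stop = wn[length(wn)] + step,
                         step = step, points = wn), class = "wn_grid")
  structure(list(grid = grid, values = df$value, position = c(NA, NA),
                 time = NA, normalized = NA), class = "pa_spectrum")
}

#' Import a laser pulse-energy curve from CSV
#'
#' Columns `wavenumber_cm-1`, `energy_nJ`.
#'
#' @param path file path.
#' @return data.frame with `wavenumber_cm_1`, `energy_nJ` suitable for
#'   [instrument_config()].
#' @export
read_pulse_energy_csv <- function(path) {
  check_rectangular(path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("wavenumber_cm-1", "energy_nJ"))) {
    stop("malformed pulse-energy CSV: expected columns wavenumber_cm-1, energy_nJ")
  }
  data.frame(wavenumber_cm_1 = df[["wavenumber_cm-1"]],
             energy_nJ = df[["energy_nJ"]])
}

#' Write / read a raster image as plain numeric CSV
#'
#' Values only (one row per image row); geometry travels separately.
#'
#' @param image a `pa_image`.
#' @param path file path.
#' @param pixel_pitch_um,origin_um,wavenumber,time geometry restored on
#'   read.
#' @export
write_pa_image_csv <- function(image, path) {
  stopifnot(inherits(image, "pa_image"))
  rows <- apply(image$values, 1, function(r) paste(fmt17(r), collapse = ","))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_pa_image_csv
#' @export
read_pa_image_csv <- function(path, pixel_pitch_um = 44,
                              origin_um = c(0, 0), wavenumber = 1040,
                              time = NA) {
  check_rectangular(path)
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  structure(list(values = vals, pixel_pitch = pixel_pitch_um,
                 origin = origin_um, wavenumber = wavenumber, time = time),
            class = "pa_image")
}

#' Export a raster image as PNG
#'
#' Grayscale, min--max scaled to `[0, 1]` (a constant image maps to 0).
#'
#' @param image a `pa_image`.
#' @param path file path.
#' @export
write_pa_image_png <- function(image, path) {
  stopifnot(inherits(image, "pa_image"))
  v <- image$values
  rng <- range(v)
  scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  png::writePNG(scaled, path)
  invisible(path)
}

#' Write / read an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- unclass(report)
  x$zone_counts <- as.list(x$zone_counts)
  x$zone_fractions <- as.list(x$zone_fractions)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$zone_counts <- unlist(x$zone_counts)
  x$zone_fractions <- unlist(x$zone_fractions)
  structure(x, class = "evaluation_report")
}

#' Serialize a probe-site selection to JSON
#'
#' Pixel and physical coordinates of both sites plus the blob table.
#'
#' @param sel a `site_selection`.
#' @param path file path.
#' @export
write_site_selection_json <- function(sel, path) {
  stopifnot(inherits(sel, "site_selection"))
  jsonlite::write_json(list(
    dark_site = sel$dark_site, bright_site = sel$bright_site,
    degenerate = sel$degenerate, blobs = sel$blobs$summaries
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an experiment configuration (YAML or JSON)
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`).
#' Unknown keys are rejected by name on read.
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("skin", "instrument", "protocol", "glucose", "meter",
             "chemometrics", "grid", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop("unknown key '", unknown[1], "' in experiment configuration")
  }
  do.call(experiment_config, x)
}
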