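#' Segment secretion blobs in a position-scan image
#'
#' Bright eccrine-secretion blobs sit on the friction-ridge background.
#' Pixels brighter than `median + k_mad * MAD` form the foreground;
#' 8-connected components with at least `min_area` pixels are kept as
#' blobs. A constant image yields zero blobs.
#'
#' @param image a `pa_image`.
#' @param k_mad robust threshold multiplier (MAD scaled to the normal,
#'   [stats::mad()]).
#' @param min_area minimum blob area (pixels).
#' @return a `blob_set`: list with `labels` (integer matrix, 0 =
#'   background) and `summaries` (data.frame: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `centroid_x_um`, `centroid_y_um`,
#'   `mean_intensity`).
#' @export
segment_blobs <- function(image, k_mad = 3, min_area = 2) {
  stopifnot(inherits(image, "pa_image"))
  v <- image$values
  if (any(!is.finite(v))) stop("image must be finite-valued")
  thr <- stats::median(v) + k_mad * stats::mad(v)
  fg <- v > thr
  labels <- label_components_8(fg)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    keep <- which(areas >= min_area)
    relab <- integer(max(labels))
    relab[keep] <- seq_along(keep)
    labels[labels > 0] <- relab[labels[labels > 0]]
  }
  ctr <- pixel_centers(image)
  nlab <- max(labels)
  summaries <- do.call(rbind, lapply(seq_len(nlab), function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    data.frame(label = l, area = nrow(idx),
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
               centroid_x_um = mean(ctr$x[idx[, 2]]),
               centroid_y_um = mean(ctr$y[idx[, 1]]),
               mean_intensity = mean(v[idx]))
  }))
  if (is.null(summaries)) {
    summaries <- data.frame(label = integer(0), area = integer(0),
                            centroid_row = numeric(0),
                            centroid_col = numeric(0),
                            centroid_x_um = numeric(0),
                            centroid_y_um = numeric(0),
                            mean_intensity = numeric(0))
  }
  structure(list(labels = labels, summaries = summaries,
                 threshold = thr), class = "blob_set")
}

# 8-connected component labeling by breadth-first search.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- (j - 1L) * nr + i
    labels[queue] <- nxt
    while (length(queue) > 0) {
      p <- queue[1L]; queue <- queue[-1L]
      pi <- ((p - 1L) %% nr) + 1L
      pj <- ((p - 1L) %/% nr) + 1L
      for (dj in -1:1) for (di in -1:1) {
        qi <- pi + di; qj <- pj + dj
        if (qi < 1L || qi > nr || qj < 1L || qj > nc) next
        if (mask[qi, qj] && labels[qi, qj] == 0L) {
          labels[qi, qj] <- nxt
          queue <- c(queue, (qj - 1L) * nr + qi)
        }
      }
    }
  }
  labels
}

# row-major rank of pixel (i, j) in an nr x nc image (ties in site
# selection are broken by this ordering)
row_major_rank <- function(i, j, nc) (i - 1) * nc + j

#' Select the secreting and non-secreting probe sites
#'
#' Implements the probing rule of the image-guided protocol: the bright
#' site is the brightest pixel inside a secretion blob (the whole-image
#' maximum when no blob was segmented, e.g. right after hand washing), and
#' the dark site is the darkest pixel of the inter-ridge valley at least
#' `d_min_px` pixels away from every blob pixel. Ties are broken in
#' row-major pixel order, and an all-equal image is flagged degenerate.
#'
#' @param image a `pa_image` taken at the imaging wavenumber.
#' @param blobs a [segment_blobs()] result; computed from `image` when
#'   missing.
#' @param d_min_px minimum Euclidean pixel distance between the dark site
#'   and any blob pixel (2 px = 88 um, about one beam diameter).
#' @return a `site_selection`: list with `dark_site` and `bright_site`
#'   (each `row`, `col`, `x_um`, `y_um`, `value`), `blobs`, `degenerate`.
#' @export
select_probe_sites <- function(image, blobs = segment_blobs(image),
                               d_min_px = 2) {
  stopifnot(inherits(image, "pa_image"))
  v <- image$values
  nr <- nrow(v); nc <- ncol(v)
  ctr <- pixel_centers(image)
  degenerate <- max(v) == min(v)

  pick <- function(candidates, value_order) {
    # candidates: logical matrix; returns c(i, j) of the extreme value with
    # row-major tie-break
    vv <- ifelse(candidates, v, NA)
    target <- if (value_order == "max") max(vv, na.rm = TRUE) else min(vv, na.rm = TRUE)
    idx <- which(!is.na(vv) & vv == target, arr.ind = TRUE)
    idx[order(row_major_rank(idx[, 1], idx[, 2], nc))[1L], ]
  }

  in_blob <- blobs$labels > 0
  bright <- if (any(in_blob)) pick(in_blob, "max") else pick(matrix(TRUE, nr, nc), "max")

  if (any(in_blob)) {
    bidx <- which(in_blob, arr.ind = TRUE)
    far <- matrix(TRUE, nr, nc)
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      d2 <- min((bidx[, 1] - i)^2 + (bidx[, 2] - j)^2)
      far[i, j] <- d2 >= d_min_px^2
    }
  } else {
    far <- matrix(TRUE, nr, nc)
  }
  if (!any(far)) {
    stop("no pixel lies at least ", d_min_px, " px from every blob; ",
         "rescan a larger or cleaner field before selecting a dark site")
  }
  dark <- pick(far, "min")
  if (dark[1] == bright[1] && dark[2] == bright[2]) {
    # distinct-pixel contract: move the dark site to the next row-major
    # candidate (only reachable on degenerate images)
    far2 <- far; far2[dark[1], dark[2]] <- FALSE
    if (any(far2)) dark <- pick(far2, "min")
  }

  site <- function(ij) list(row = unname(ij[1]), col = unname(ij[2]),
                            x_um = ctr$x[ij[2]], y_um = ctr$y[ij[1]],
                            value = v[ij[1], ij[2]])
  structure(list(dark_site = site(dark), bright_site = site(bright),
                 blobs = blobs, degenerate = degenerate),
            class = "site_selection")
}

#' @export
print.site_selection <- function(x, ...) {
  cat(sprintf(
    "<site_selection> dark (%g, %g) um [%.3g], bright (%g, %g) um [%.3g], %d blobs%s\n",
    x$dark_site$x_um, x$dark_site$y_um, x$dark_site$value,
    x$bright_site$x_um, x$bright_site$y_um, x$bright_site$value,
    nrow(x$blobs$summaries), if (x$degenerate) " (degenerate image)" else ""))
  invisible(x)
}

#' Difference spectrum between two probe sites
#'
#' Pointwise `bright - dark`, used to expose the chemical signature of the
#' secretion blob against the shared skin background.
#'
#' @param bright,dark `pa_spectrum` objects on the same grid and in the
#'   same normalization state.
#' @return a `pa_spectrum` of the difference.
#' @export
difference_spectrum <- function(bright, dark) {
  stopifnot(inherits(bright, "pa_spectrum"), inherits(dark, "pa_spectrum"))
  if (!same_grid(bright$grid, dark$grid)) {
    stop("spectra are on different wavenumber grids")
  }
  if (!identical(bright$normalized, dark$normalized)) {
    stop("spectra differ in pulse-energy normalization state")
  }
  out <- bright
  out$values <- bright$values - dark$values
  out
}

#' Identify the analyte behind a difference spectrum
#'
#' Scores every library analyte by the Pearson correlation between the
#' mean-centered difference spectrum and the mean-centered library
#' spectrum; the best-scoring analyte is reported. On fingertip scans the
#' winner is sodium lactate, the dominant component of eccrine secretion.
#'
#' @param diff a `pa_spectrum` (typically from [difference_spectrum()]).
#' @param library named list of `component_spectrum` objects on the same
#'   grid (e.g. [default_spectral_library()]).
#' @return an `analyte_match`: list with `scores` (named numeric) and
#'   `best` (identifier, or `NA` when the difference has zero variance).
#' @export
match_analyte <- function(diff, library) {
  stopifnot(inherits(diff, "pa_spectrum"), length(library) > 0)
  for (cs in library) {
    if (!same_grid(cs$grid, diff$grid)) {
      stop("library spectrum '", cs$analyte, "' is on a different grid")
    }
  }
  d <- diff$values - mean(diff$values)
  if (stats::sd(d) == 0) {
    scores <- stats::setNames(rep(NA_real_, length(library)), names(library))
    return(structure(list(scores = scores, best = NA_character_),
                     class = "analyte_match"))
  }
  scores <- vapply(library, function(cs) {
    s <- cs$values - mean(cs$values)
    if (stats::sd(s) == 0) return(0)
    stats::cor(d, s)
  }, numeric(1))
  structure(list(scores = scores, best = names(scores)[which.max(scores)]),
            class = "analyte_match")
}

#' Monitor secretion at a site over time
#'
#' Acquires spectra at one position over a sequence of times and extracts
#' the signal at the grid points nearest the 1070 and 1140 cm^-1 lactate
#' channels, the bands that grow after hand washing at secreting pores.
#'
#' @param map a `skin_map`.
#' @param position_um probing position (um).
#' @param times_min ascending times (minutes since washing).
#' @param grid a `wn_grid`.
#' @param config an [instrument_config()].
#' @param channels_cm_1 monitored wavenumbers (cm^-1).
#' @param noise logical.
#' @param seed optional RNG seed.
#' @return data.frame with `time_min` and one column per channel (named
#'   `wn_<actual grid wavenumber>`).
#' @export
monitor_secretion <- function(map, position_um, times_min,
                              grid = make_wavenumber_grid(950, 1240, 1.38),
                              config = instrument_config(),
                              channels_cm_1 = c(1070, 1140),
                              noise = TRUE, seed = NULL) {
  if (is.unsorted(times_min)) stop("times must be sorted ascending")
  if (!is.null(seed)) set.seed(seed)
  idx <- nearest_grid_index(grid, channels_cm_1)
  out <- matrix(NA_real_, length(times_min), length(idx))
  for (k in seq_along(times_min)) {
    s <- acquire_spectrum(map, position_um, times_min[k], grid, config,
                          noise = noise)
    out[k, ] <- s$values[idx]
  }
  res <- data.frame(time_min = times_min, out)
  names(res)[-1] <- sprintf("wn_%.2f", grid$points[idx])
  res
}
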