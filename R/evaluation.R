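#' Mean absolute relative deviation (MARD)
#'
#' `mean(|pred - ref| / ref) * 100`, the standard relative accuracy figure
#' for glucose monitors, with the spread of the per-pair absolute relative
#' deviations. The spread is reported as the population standard deviation
#' (divisor `n`) by default.
#'
#' @param y_pred predicted glucose (mg/dl).
#' @param y_ref reference glucose (mg/dl), strictly positive.
#' @param sd_type `"population"` (divisor n) or `"sample"` (divisor n-1).
#' @return list with `value` (%), `sd` (%), `n`.
#' @export
mard <- function(y_pred, y_ref, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(y_pred) != length(y_ref)) stop("length mismatch")
  if (any(y_ref <= 0)) stop("reference glucose must be strictly positive")
  ard <- abs(y_pred - y_ref) / y_ref * 100
  list(value = mean(ard), sd = spread(ard, sd_type), n = length(ard))
}

#' Mean absolute difference (MAD)
#'
#' `mean(|pred - ref|)` in mg/dl with the spread of the per-pair absolute
#' differences.
#'
#' @inheritParams mard
#' @return list with `value` (mg/dl), `sd` (mg/dl), `n`.
#' @export
mad_diff <- function(y_pred, y_ref, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(y_pred) != length(y_ref)) stop("length mismatch")
  ad <- abs(y_pred - y_ref)
  list(value = mean(ad), sd = spread(ad, sd_type), n = length(ad))
}

spread <- function(x, sd_type) {
  if (sd_type == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}

#' Clarke error-grid zone of a (reference, predicted) pair
#'
#' Classifies glucose prediction pairs into the clinical-accuracy zones of
#' the Clarke error grid: A (within 20% of the reference, or both
#' hypoglycemic readings <= 70), B (benign error), C (overcorrection),
#' D (dangerous failure to detect), E (erroneous treatment). The piecewise
#' boundaries are evaluated in the precedence order A, E, C, D, with B as
#' the remainder; boundaries are inclusive.
#'
#' @param ref reference glucose (mg/dl), vectorized.
#' @param pred predicted glucose (mg/dl), vectorized.
#' @return character vector of zones in `{"A","B","C","D","E"}`.
#' @export
clarke_zone <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("length mismatch")
  if (any(ref <= 0) || any(pred <= 0)) {
    stop("glucose values must be positive")
  }
  zone <- rep(NA_character_, length(ref))
  a <- (pred <= 70 & ref <= 70) | (pred >= 0.8 * ref & pred <= 1.2 * ref)
  e <- (ref >= 180 & pred <= 70) | (ref <= 70 & pred >= 180)
  cc <- (ref >= 130 & ref <= 180 & pred <= 1.4 * ref - 182) |
    (ref >= 70 & ref <= 290 & pred >= ref + 110)
  d <- (ref >= 240 & pred >= 70 & pred <= 180) |
    (ref <= 70 & pred >= 70 & pred <= 180)
  zone[is.na(zone) & a] <- "A"
  zone[is.na(zone) & e] <- "E"
  zone[is.na(zone) & cc] <- "C"
  zone[is.na(zone) & d] <- "D"
  zone[is.na(zone)] <- "B"
  zone
}

#' Clarke error-grid zone tallies
#'
#' @param y_ref,y_pred paired glucose values (mg/dl), non-empty.
#' @return list with integer `counts` and numeric `fractions`, both named
#'   A--E.
#' @export
clarke_summary <- function(y_ref, y_pred) {
  if (length(y_ref) == 0) stop("empty pair list")
  z <- factor(clarke_zone(y_ref, y_pred), levels = c("A", "B", "C", "D", "E"))
  counts <- table(z)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       fractions = stats::setNames(as.numeric(counts) / length(y_ref),
                                   names(counts)))
}

#' Assemble a clinical-accuracy evaluation report
#'
#' Bundles MARD, MAD, the RMSE figures and the Clarke zone tallies of a
#' cross-validated calibration into one report.
#'
#' @param y_cv cross-validated glucose predictions (mg/dl).
#' @param y_ref reference glucose (mg/dl).
#' @param rmsec,rmsecv calibration / cross-validation RMSE (mg/dl) at the
#'   chosen component count.
#' @param sd_type spread convention, see [mard()].
#' @return an `evaluation_report` list: `mard`, `mard_sd`, `mad`,
#'   `mad_sd`, `rmsec`, `rmsecv`, `zone_counts`, `zone_fractions`,
#'   `n_pairs`.
#' @export
evaluate_experiment <- function(y_cv, y_ref, rmsec = NA_real_,
                                rmsecv = NA_real_,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(y_cv) == length(y_ref))
  m <- mard(y_cv, y_ref, sd_type)
  d <- mad_diff(y_cv, y_ref, sd_type)
  cz <- clarke_summary(y_ref, y_cv)
  structure(list(mard = m$value, mard_sd = m$sd,
                 mad = d$value, mad_sd = d$sd,
                 rmsec = rmsec, rmsecv = rmsecv,
                 zone_counts = cz$counts, zone_fractions = cz$fractions,
                 n_pairs = length(y_ref)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Clinical accuracy over", x$n_pairs, "pairs\n")
  cat(sprintf("  MARD  %.2f %% (sd %.2f)\n", x$mard, x$mard_sd))
  cat(sprintf("  MAD   %.2f mg/dl (sd %.2f)\n", x$mad, x$mad_sd))
  if (is.finite(x$rmsec))  cat(sprintf("  RMSEC   %.2f mg/dl\n", x$rmsec))
  if (is.finite(x$rmsecv)) cat(sprintf("  RMSE-CV %.2f mg/dl\n", x$rmsecv))
  cat("  Clarke zones:",
      paste(sprintf("%s=%d (%.0f%%)", names(x$zone_counts), x$zone_counts,
                    100 * x$zone_fractions), collapse = ", "), "\n")
  invisible(x)
}
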