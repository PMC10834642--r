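# External-standard calibration: linear curve fitting, inversion, LOD/LOQ.

new_calibration_curve <- function(analyte, slope, intercept, r_squared,
                                  linear_range, lod = NA_real_,
                                  loq = NA_real_, n = NA_integer_) {
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r_squared, linear_range = linear_range,
                 lod = lod, loq = loq, n = n),
            class = "calibration_curve")
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on concentration (area on the
#' y-axis, concentration on the x-axis), the external-standard-method
#' convention. The reported R-squared is the squared Pearson correlation of
#' concentration and area, and the curve's linear range is the span of the
#' supplied concentrations.
#'
#' @param points Data frame with columns `concentration` (ug/mL) and
#'   `area`, at least 3 distinct concentrations.
#' @param analyte Analyte label carried on the curve.
#' @return A `calibration_curve`: `slope`, `intercept`, `r_squared`,
#'   `linear_range`, unset `lod`/`loq`.
#' @export
#' @examples
#' pts <- data.frame(concentration = c(50, 100, 200, 400),
#'                   area = 2132.2 * c(50, 100, 200, 400) - 5982.5)
#' fit_calibration(pts, "saikosaponin_d")
fit_calibration <- function(points, analyte = "analyte") {
  if (!is.data.frame(points) ||
      !all(c("concentration", "area") %in% names(points)))
    stop("points needs columns 'concentration' and 'area'", call. = FALSE)
  x <- points$concentration
  y <- points$area
  if (length(unique(x)) < 3)
    stop("calibration needs at least 3 distinct concentrations",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("zero concentration variance: cannot fit", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate calibration: all areas equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("fitted slope is not positive: not a usable calibration curve",
         call. = FALSE)
  new_calibration_curve(
    analyte = analyte,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = stats::cor(x, y)^2,
    linear_range = c(min(x), max(x)),
    n = length(x)
  )
}

#' Invert a calibration curve to a concentration
#'
#' Computes `(area - intercept) / slope`. Quantification outside the
#' curve's linear range is legitimate near the LOQ, so an out-of-range
#' result raises a warning, not an error.
#'
#' @param curve A `calibration_curve`.
#' @param area Peak area(s).
#' @param warn_out_of_range Emit a warning for results outside the linear
#'   range (default TRUE).
#' @return Concentration(s), ug/mL.
#' @export
predict_concentration <- function(curve, area, warn_out_of_range = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("curve slope must be positive", call. = FALSE)
  conc <- (area - curve$intercept) / curve$slope
  if (warn_out_of_range) {
    # small relative tolerance so round-off at the range ends never flags
    eps <- 1e-8 * diff(curve$linear_range)
    out <- conc < curve$linear_range[1] - eps |
           conc > curve$linear_range[2] + eps
    if (any(out))
      warning(sum(out), " concentration(s) for ", curve$analyte,
              " fall outside the linear range [",
              curve$linear_range[1], ", ", curve$linear_range[2], "] ug/mL",
              call. = FALSE)
  }
  conc
}

#' Detection and quantification limits from signal-to-noise
#'
#' LOD and LOQ are the concentrations whose peak height reaches 3 and 10
#' times the baseline noise standard deviation, respectively:
#' `lod = 3 * noise / height_slope`, `loq = 10 * noise / height_slope`,
#' where `height_slope` is the peak-height response per ug/mL.
#'
#' @param curve A `calibration_curve` to annotate, or `NULL` to return the
#'   bare pair.
#' @param height_slope Peak height per (ug/mL); > 0.
#' @param baseline_noise_sd Baseline noise sd in height units; > 0.
#' @return The curve with `lod`/`loq` set, or (if `curve` is `NULL`) a
#'   named numeric `c(lod, loq)` in ug/mL.
#' @export
#' @examples
#' estimate_lod_loq(NULL, height_slope = 10, baseline_noise_sd = 1)
estimate_lod_loq <- function(curve = NULL, height_slope, baseline_noise_sd) {
  stopifnot_scalar_pos(height_slope, "height_slope")
  stopifnot_scalar_pos(baseline_noise_sd, "baseline_noise_sd")
  lod <- 3 * baseline_noise_sd / height_slope
  loq <- 10 * baseline_noise_sd / height_slope
  if (is.null(curve)) return(c(lod = lod, loq = loq))
  stopifnot(inherits(curve, "calibration_curve"))
  curve$lod <- lod
  curve$loq <- loq
  curve
}

#' Summarise calibration curves as a table
#'
#' @param curves A list of `calibration_curve`s.
#' @return A tibble mirroring the usual published curve summary: analyte,
#'   slope, intercept, R-squared, linear range, LOD, LOQ.
#' @export
curve_summary <- function(curves) {
  dplyr::bind_rows(lapply(curves, function(cv) tibble::tibble(
    analyte = cv$analyte, slope = cv$slope, intercept = cv$intercept,
    r_squared = cv$r_squared, range_low = cv$linear_range[1],
    range_high = cv$linear_range[2], lod = cv$lod, loq = cv$loq
  )))
}

#' @export
print.calibration_curve <- function(x, digits = 6, ...) {
  cat(sprintf("<calibration_curve> %s: area = %.4g * C %+.4g (R^2 = %.4f)\n",
              x$analyte, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  linear range [%g, %g] ug/mL", x$linear_range[1],
              x$linear_range[2]))
  if (!is.na(x$lod)) cat(sprintf("; LOD %.3g, LOQ %.3g ug/mL", x$lod, x$loq))
  cat("\n")
  invisible(x)
}
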