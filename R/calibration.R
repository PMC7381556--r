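# Linear calibrations behind the assay: fluorescence vs algal biomass
# (F = l * W, through the origin by default) and absorbance vs dry mass
# (intercept allowed). Calibration is diagnostic: the clearance-rate
# estimator works on fluorescence ratios and never needs the curve unless
# results are requested in biomass units.

#' Fit a linear standard curve
#'
#' Least-squares fit of response on predictor, optionally through the origin.
#' For fluorescence vs biomass the model is F = l W, where l is the slope of
#' the regression; absorbance vs dry mass normally keeps an intercept.
#'
#' @param points Data frame / tibble with numeric columns `x` (predictor:
#'   biomass in mg dw L^-1, or absorbance) and `y` (response: RFU, or dry
#'   mass in mg L^-1).
#' @param through_origin Force the intercept to zero (default `TRUE`, the
#'   fluorescence-biomass model).
#' @return A `standard_curve` object: `slope_l`, `intercept`, `r_squared`,
#'   `n_points`, `through_origin`, `residuals`, and the underlying `lm` fit.
#' @export
#' @examples
#' pts <- data.frame(x = seq(0.2, 1.2, by = 0.2), y = 250 * seq(0.2, 1.2, by = 0.2))
#' fit_standard_curve(pts)$slope_l  # 250
fit_standard_curve <- function(points, through_origin = TRUE) {
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% colnames(points))) {
    abort_grazekit("calibration points need columns x and y")
  }
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_grazekit("calibration points must be finite")
  }
  if (any(x < 0)) abort_grazekit("calibration predictor must be nonnegative")
  if (length(x) < 2) abort_grazekit("need at least 2 calibration points")
  if (diff(range(x)) == 0) abort_grazekit("calibration predictor is constant")
  fit <- if (through_origin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(
    slope_l = unname(cf[["x"]]),
    intercept = if (through_origin) 0 else unname(cf[["(Intercept)"]]),
    r_squared = suppressWarnings(summary(fit)$r.squared),  # exact fits warn
    n_points = length(x),
    through_origin = through_origin,
    residuals = unname(stats::residuals(fit)),
    fit = fit
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: y = %.6g * x%s\n", x$slope_l,
              if (x$through_origin) " (through origin)"
              else sprintf(" + %.6g", x$intercept)))
  cat(sprintf("  n = %d points, R^2 = %.4f\n", x$n_points, x$r_squared))
  invisible(x)
}

#' Check a standard curve for adequate linearity
#'
#' @param curve A [fit_standard_curve()] result.
#' @param min_r2 Minimum acceptable R^2 (inclusive; default 0.95).
#' @return A list report: `pass`, `r_squared`, `min_r2`, and a residual
#'   summary (min / median / max / RMSE).
#' @export
check_linearity <- function(curve, min_r2 = 0.95) {
  stopifnot(inherits(curve, "standard_curve"))
  res <- curve$residuals
  list(pass = curve$r_squared >= min_r2,
       r_squared = curve$r_squared,
       min_r2 = min_r2,
       residual_summary = c(min = min(res), median = stats::median(res),
                            max = max(res), rmse = sqrt(mean(res^2))))
}

#' Convert fluorescence to algal biomass through a standard curve
#'
#' Inverts the calibration: W = (F - intercept) / l.
#'
#' @param F Fluorescence (RFU), vectorized.
#' @param curve A [fit_standard_curve()] result with positive slope.
#' @return Biomass in the curve's predictor units (mg dw L^-1).
#' @export
fluorescence_to_biomass <- function(F, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope_l <= 0) {
    abort_grazekit("standard curve slope must be positive to invert")
  }
  (F - curve$intercept) / curve$slope_l
}

#' Read a calibration CSV
#'
#' Columns `x`, `y` and a `kind` column distinguishing the two calibrations
#' (`fluor_biomass` or `abs_drymass`).
#'
#' @param file Path to the CSV.
#' @param kind Which calibration to extract.
#' @return Tibble of calibration points.
#' @export
read_calibration <- function(file, kind = c("fluor_biomass", "abs_drymass")) {
  kind <- match.arg(kind)
  df <- tibble::as_tibble(read_csv_strict(file))
  if (!all(c("x", "y", "kind") %in% colnames(df))) {
    abort_grazekit("calibration file needs columns x, y, kind",
                   class = "grazekit_parse_error")
  }
  df <- df[df$kind == kind, ]
  if (nrow(df) == 0) {
    abort_grazekit(sprintf("calibration file has no rows of kind '%s'", kind),
                   class = "grazekit_parse_error")
  }
  tibble::tibble(x = as.numeric(df$x), y = as.numeric(df$y))
}
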