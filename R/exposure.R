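# Assays run in the presence of a fluorescent-background stressor (pathogen
# propagules, microplastics, ...) and conversion of clearance rates to
# exposure quantities. Animal-free control tubes that CONTAIN the stressor
# replace the pure-algae controls, so any additive background fluorescence of
# the stressor is common to F(0) and F(t) and largely cancels; with blank
# subtraction of the measured background it cancels exactly.

#' Estimate clearance rates with stressor-bearing controls
#'
#' Identical pipeline to [estimate_all()] except that F(0) comes from wells
#' with role `stressor_control` (animal-free tubes containing algae plus the
#' stressor). Pure-algae `control` wells, if present, are ignored for F(0).
#' Every plate hosting samples must carry stressor controls.
#'
#' @inheritParams estimate_all
#' @return A `feeding_rate_fit`, as for [estimate_all()].
#' @export
estimate_with_stressor <- function(wells, config = assay_config(bootstrap_B = 0),
                                   keep_all = FALSE) {
  estimate_all(wells, config = config, control_role = "stressor_control",
               keep_all = keep_all)
}

#' Particle exposure rate from a clearance rate
#'
#' An animal clearing f mL of medium per hour at ambient particle
#' concentration Z encounters E = f * Z particles per hour.
#'
#' @param f Clearance rate (mL hr^-1), >= 0. Vectorized.
#' @param Z Particle concentration (particles mL^-1), >= 0.
#' @return Exposure rate (particles hr^-1).
#' @export
exposure_rate <- function(f, Z) {
  if (any(f < 0) || any(Z < 0)) {
    abort_grazekit("exposure_rate needs nonnegative f and Z")
  }
  f * Z
}

#' Cumulative particle dose over an assay
#'
#' Two dose models: `constant_Z` holds the ambient concentration fixed
#' (D = f Z0 t, e.g. continuously replenished particles); `depleting_Z`
#' (default) lets the animal deplete the tube's particles like its food,
#' D = Z0 V (1 - exp(-f t / V)), bounded by the Z0 V particles present.
#'
#' @param f Clearance rate (mL hr^-1), >= 0. Vectorized.
#' @param Z0 Initial particle concentration (particles mL^-1).
#' @param V Tube volume (mL), > 0.
#' @param t Exposure duration (hr), > 0.
#' @param model `"depleting_Z"` (default) or `"constant_Z"`.
#' @return Cumulative dose (particles).
#' @export
cumulative_dose <- function(f, Z0, V, t, model = c("depleting_Z", "constant_Z")) {
  if (is.character(model) && length(model) == 1 &&
      !model %in% c("depleting_Z", "constant_Z")) {
    abort_grazekit(sprintf("unknown dose model '%s' (use depleting_Z or constant_Z)", model))
  }
  model <- match.arg(model)
  if (any(f < 0) || any(Z0 < 0)) abort_grazekit("cumulative_dose needs nonnegative f and Z0")
  if (any(V <= 0) || any(t <= 0)) abort_grazekit("V and t must be positive")
  switch(model,
         constant_Z = f * Z0 * t,
         depleting_Z = Z0 * V * (1 - exp(-f * t / V)))
}

#' Attach exposure quantities to feeding-rate estimates
#'
#' @param fit A `feeding_rate_fit` (typically from [estimate_with_stressor()]).
#' @param Z Particle concentration (particles mL^-1).
#' @param model Dose model, see [cumulative_dose()].
#' @return The retained estimate tibble with `exposure_rate_per_hr` and
#'   `cumulative_dose` columns (rates in mL hr^-1 are used regardless of the
#'   configured output units; negative-rate samples are already excluded).
#' @export
exposure_table <- function(fit, Z, model = c("depleting_Z", "constant_Z")) {
  stopifnot(inherits(fit, "feeding_rate_fit"))
  model <- match.arg(model)
  est <- fit$retained
  V <- fit$config$default_volume_mL
  t <- fit$config$default_hours
  est$particle_concentration_Z <- Z
  est$exposure_rate_per_hr <- exposure_rate(est$f_mL_per_hr, Z)
  est$cumulative_dose <- cumulative_dose(est$f_mL_per_hr, Z, V, t, model = model)
  est$dose_model <- model
  est
}
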