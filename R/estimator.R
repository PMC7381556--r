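# Clearance-rate estimation from exponential resource depletion.
#
# The assay model: an individual clearing f (mL hr^-1) of medium from a tube
# of volume V depletes algal fluorescence as dF/dt = -(f/V) F, so
# F(t) = F(0) exp(-f t / V) and f = (V/t) ln(F(0)/F(t)). F(0) is the mean
# fluorescence of the consumer-free control wells on the SAME plate
# (matched-pairs blocking: plate-level multiplicative effects cancel in the
# within-plate ratio), F(t) the mean of the sample's technical-replicate
# wells. Canonical unit is mL hr^-1 ind^-1; conversion happens at output.

#' Summarize consumer-free controls per plate
#'
#' Arithmetic mean / sd / n of control-well fluorescence, computed within each
#' plate only — control values are never pooled across plates.
#'
#' @param wells Annotated well tibble (see [join_layout()]).
#' @param plate_id Optional single plate to summarize; default all plates
#'   that carry control wells.
#' @param control_role Which role supplies F(0): `"control"` (pure-algae,
#'   default) or `"stressor_control"` (see [estimate_with_stressor()]).
#' @return Tibble: `plate_id`, `F0_mean`, `F0_sd`, `n_controls`.
#' @export
summarize_controls <- function(wells, plate_id = NULL, control_role = "control") {
  if (!is.null(plate_id)) {
    wells <- wells[wells$plate_id %in% plate_id, ]
    present <- unique(wells$plate_id)
    if (length(present) == 0) abort_grazekit(sprintf("no wells for plate %s", plate_id))
  }
  ctl <- wells[wells$role == control_role, ]
  plates_needed <- if (is.null(plate_id)) unique(wells$plate_id) else plate_id
  missing <- setdiff(plates_needed, unique(ctl$plate_id))
  if (length(missing) > 0) {
    abort_grazekit(sprintf("plate(s) without %s wells: %s (feeding rates need plate-specific controls)",
                           control_role, paste(missing, collapse = ", ")),
                   class = "grazekit_control_error")
  }
  out <- dplyr::summarise(dplyr::group_by(ctl, .data$plate_id),
                          F0_mean = mean(.data$fluorescence),
                          F0_sd = stats::sd(.data$fluorescence),
                          n_controls = dplyr::n(), .groups = "drop")
  out$F0_sd[out$n_controls == 1] <- NA_real_
  if (any(out$n_controls == 1)) {
    rlang::warn(sprintf("single control well on plate(s): %s",
                        paste(out$plate_id[out$n_controls == 1], collapse = ", ")))
  }
  if (any(out$F0_mean <= 0)) {
    abort_grazekit(sprintf("nonpositive control mean on plate(s): %s",
                           paste(out$plate_id[out$F0_mean <= 0], collapse = ", ")),
                   class = "grazekit_control_error")
  }
  out
}

#' Aggregate a sample's technical replicates
#'
#' The two (or more) wells read from one animal's medium are averaged before
#' the rate computation: F(t) is the mean fluorescence across the sample's
#' wells. The technical-replicate coefficient of variation (sd/mean; 0 when
#' n = 1) is recorded and samples above the warning threshold are flagged
#' `high_tech_cv`.
#'
#' @param wells Annotated well tibble.
#' @param sample_id Optional subset of samples; default all.
#' @param config [assay_config()] supplying the CV threshold.
#' @return Tibble: `sample_id`, `plate_id`, `Ft_mean`, `tech_rep_cv`,
#'   `n_reps`, `high_tech_cv`.
#' @export
aggregate_technical_replicates <- function(wells, sample_id = NULL,
                                           config = assay_config(bootstrap_B = 0)) {
  samp <- wells[wells$role == "sample", ]
  if (!is.null(sample_id)) samp <- samp[samp$sample_id %in% sample_id, ]
  if (nrow(samp) == 0) {
    return(tibble::tibble(sample_id = character(), plate_id = character(),
                          Ft_mean = numeric(), tech_rep_cv = numeric(),
                          n_reps = integer(), high_tech_cv = logical()))
  }
  n_plates <- dplyr::summarise(dplyr::group_by(samp, .data$sample_id),
                               k = dplyr::n_distinct(.data$plate_id), .groups = "drop")
  split_ids <- n_plates$sample_id[n_plates$k > 1]
  if (length(split_ids) > 0) {
    abort_grazekit(sprintf("sample(s) split across plates (control pairing undefined): %s",
                           paste(split_ids, collapse = ", ")),
                   class = "grazekit_design_error")
  }
  out <- dplyr::summarise(dplyr::group_by(samp, .data$sample_id, .data$plate_id),
                          Ft_mean = mean(.data$fluorescence),
                          tech_rep_cv = ifelse(dplyr::n() == 1, 0,
                                               stats::sd(.data$fluorescence) / mean(.data$fluorescence)),
                          n_reps = dplyr::n(), .groups = "drop")
  if (any(out$n_reps == 1)) {
    rlang::warn(sprintf("%d sample(s) with a single technical replicate", sum(out$n_reps == 1)))
  }
  out$high_tech_cv <- out$tech_rep_cv > config$tech_rep_cv_warn
  out
}

#' Clearance rate from the within-plate fluorescence ratio
#'
#' f = (V / t) * ln(F0 / Ft), the closed-form inverse of exponential
#' depletion dF/dt = -(f/V) F. Vectorized. Negative rates (Ft > F0) are
#' returned as-is; they are flagged and excluded downstream, never clamped.
#'
#' @param F0_mean Plate-specific control mean fluorescence (RFU), > 0.
#' @param Ft_mean Sample mean fluorescence at assay end (RFU), > 0.
#' @param V Tube volume (mL), > 0.
#' @param t Assay duration (hr), > 0.
#' @return Clearance rate in mL hr^-1 ind^-1.
#' @export
#' @examples
#' compute_feeding_rate(1000, 500, V = 10, t = 7)  # (10/7) * ln(2)
compute_feeding_rate <- function(F0_mean, Ft_mean, V, t) {
  if (any(!is.finite(F0_mean)) || any(F0_mean <= 0)) {
    abort_grazekit("F0_mean must be finite and positive")
  }
  if (any(!is.finite(Ft_mean)) || any(Ft_mean <= 0)) {
    abort_grazekit("Ft_mean must be finite and positive")
  }
  if (any(V <= 0) || any(t <= 0)) abort_grazekit("V and t must be positive")
  (V / t) * log(F0_mean / Ft_mean)
}

#' Convert clearance rates between unit systems
#'
#' @param f Rate(s) in `from` units.
#' @param to Target units: `"mL_per_hr"` or `"L_per_day"`.
#' @param from Units of `f` (default the canonical `"mL_per_hr"`).
#' @return Converted rate(s); 1 mL hr^-1 = 0.024 L day^-1.
#' @export
convert_units <- function(f, to, from = "mL_per_hr") {
  factor_of <- function(u) {
    switch(u,
           mL_per_hr = 1,
           L_per_day = 24 / 1000,
           abort_grazekit(sprintf("unknown unit token '%s' (use %s)", u,
                                  paste(UNIT_TOKENS, collapse = " or "))))
  }
  f * factor_of(to) / factor_of(from)
}

#' Apply the exclusion rules
#'
#' Negative rates (technical errors), animals that died during the assay, and
#' animals later identified as male are excluded. Every exclusion is logged
#' with its sample id and reason(s); nothing is dropped silently. A high
#' technical-replicate CV flags but does not exclude.
#'
#' @param estimates Estimate tibble with `f_mL_per_hr` and `status` columns.
#' @param keep_all Explicit override: keep flagged samples (they stay
#'   flagged). Default `FALSE`.
#' @return List: `estimates` (with `qc_flags` and `excluded` columns),
#'   `retained` (subset), `exclusion_log` (tibble `sample_id`, `reasons`).
#' @export
apply_qc <- function(estimates, keep_all = FALSE) {
  status <- parse_status(estimates$status)
  flags <- mapply(function(f, st) {
    fl <- character()
    if (is.finite(f) && f < 0) fl <- c(fl, "negative_rate")
    if ("died" %in% st) fl <- c(fl, "died")
    if ("male" %in% st) fl <- c(fl, "male")
    fl
  }, estimates$f_mL_per_hr, status, SIMPLIFY = FALSE)
  if ("high_tech_cv" %in% colnames(estimates)) {
    flags <- mapply(function(fl, hi) if (isTRUE(hi)) c(fl, "high_tech_cv") else fl,
                    flags, estimates$high_tech_cv, SIMPLIFY = FALSE)
  }
  excluding <- vapply(flags, function(fl) any(fl %in% EXCLUDING_FLAGS), logical(1))
  estimates$qc_flags <- vapply(flags, function(fl) paste(fl, collapse = ";"), character(1))
  estimates$excluded <- excluding & !keep_all
  log <- tibble::tibble(
    sample_id = estimates$sample_id[excluding],
    reasons = vapply(flags[excluding],
                     function(fl) paste(intersect(fl, EXCLUDING_FLAGS), collapse = ";"),
                     character(1))
  )
  list(estimates = estimates,
       retained = estimates[!estimates$excluded, ],
       exclusion_log = log)
}

#' Percentile bootstrap CI for one sample's clearance rate
#'
#' Control wells and the sample's technical-replicate wells are resampled
#' with replacement, independently, B times; the rate is recomputed from each
#' resample's means and the 2.5/97.5 percentiles reported. Deterministic
#' given the seed.
#'
#' @param control_values Control-well fluorescences of the sample's plate.
#' @param rep_values The sample's technical-replicate fluorescences.
#' @param V,t Volume (mL) and duration (hr).
#' @param B Number of resamples (>= 1).
#' @param seed Integer seed.
#' @return Named numeric `c(ci_low, ci_high)` in mL hr^-1.
#' @export
bootstrap_ci <- function(control_values, rep_values, V, t, B, seed) {
  stopifnot(B >= 1, length(control_values) >= 1, length(rep_values) >= 1)
  withr::with_seed(seed, {
    f_star <- bootstrap_draws(control_values, rep_values, V, t, B)
    q <- stats::quantile(f_star, c(0.025, 0.975), names = FALSE, type = 7)
  })
  c(ci_low = q[1], ci_high = q[2])
}

# B bootstrap replicates of f; caller manages the RNG state
bootstrap_draws <- function(control_values, rep_values, V, t, B) {
  nc <- length(control_values); nr <- length(rep_values)
  F0_star <- colMeans(matrix(sample(control_values, nc * B, replace = TRUE), nrow = nc))
  Ft_star <- colMeans(matrix(sample(rep_values, nr * B, replace = TRUE), nrow = nr))
  (V / t) * log(F0_star / Ft_star)
}

#' Estimate clearance rates for every sample in an annotated well table
#'
#' The full per-sample pipeline: per-plate control summaries, technical-
#' replicate aggregation, the closed-form rate, optional blank subtraction,
#' optional bootstrap CIs, QC exclusion, and unit conversion. Each sample is
#' paired with the controls of its own plate; a sample split across plates is
#' an error because that pairing would be undefined.
#'
#' @param wells Annotated well tibble from [join_layout()].
#' @param config [assay_config()].
#' @param control_role Role supplying F(0) (default `"control"`).
#' @param keep_all Passed to [apply_qc()].
#' @return List of class `feeding_rate_fit`: `estimates` (all samples, with
#'   `excluded` flags), `retained`, `exclusion_log`, `controls`, `config`.
#' @export
estimate_all <- function(wells, config = assay_config(bootstrap_B = 0),
                         control_role = "control", keep_all = FALSE) {
  stopifnot(inherits(config, "assay_config"))
  if (isTRUE(config$blank_subtract)) wells <- subtract_blanks(wells)

  samp_plates <- unique(wells$plate_id[wells$role == "sample"])
  empty <- tibble::tibble(sample_id = character(), genotype = character(),
                          block = character(), plate_id = character(),
                          f_value = numeric(), units = character(),
                          ci_low = numeric(), ci_high = numeric(),
                          qc_flags = character(), excluded = logical())
  if (length(samp_plates) == 0) {
    return(structure(list(estimates = empty, retained = empty,
                          exclusion_log = tibble::tibble(sample_id = character(),
                                                         reasons = character()),
                          controls = NULL, config = config),
                     class = "feeding_rate_fit"))
  }

  controls <- summarize_controls(wells, plate_id = samp_plates,
                                 control_role = control_role)
  samples <- aggregate_technical_replicates(wells, config = config)
  if (any(samples$Ft_mean <= 0)) {
    abort_grazekit(sprintf("nonpositive sample mean fluorescence for: %s",
                           paste(samples$sample_id[samples$Ft_mean <= 0], collapse = ", ")))
  }
  est <- dplyr::left_join(samples, controls, by = "plate_id")

  meta_cols <- wells[wells$role == "sample",
                     c("sample_id", "genotype", "block", "status", "volume_mL", "hours")]
  meta_cols <- dplyr::distinct(meta_cols)
  est <- dplyr::left_join(est, meta_cols, by = "sample_id")
  est$V <- ifelse(is.na(est$volume_mL), config$default_volume_mL, est$volume_mL)
  est$t <- ifelse(is.na(est$hours), config$default_hours, est$hours)

  est$f_mL_per_hr <- compute_feeding_rate(est$F0_mean, est$Ft_mean, est$V, est$t)

  est$ci_low <- NA_real_; est$ci_high <- NA_real_
  if (config$bootstrap_B > 0) {
    seeds <- derive_seeds(config$rng_seed, nrow(est))
    ctl_vals <- split(wells$fluorescence[wells$role == control_role],
                      wells$plate_id[wells$role == control_role])
    rep_vals <- split(wells$fluorescence[wells$role == "sample"],
                      wells$sample_id[wells$role == "sample"])
    for (i in seq_len(nrow(est))) {
      ci <- bootstrap_ci(ctl_vals[[est$plate_id[i]]], rep_vals[[est$sample_id[i]]],
                         est$V[i], est$t[i], config$bootstrap_B, seeds[i])
      est$ci_low[i] <- ci[1]; est$ci_high[i] <- ci[2]
    }
  }

  qc <- apply_qc(est, keep_all = keep_all)
  est <- qc$estimates

  # convert to output units last; internal computations stay in mL/hr
  est$f_value <- convert_units(est$f_mL_per_hr, to = config$output_units)
  if (config$bootstrap_B > 0) {
    est$ci_low <- convert_units(est$ci_low, to = config$output_units)
    est$ci_high <- convert_units(est$ci_high, to = config$output_units)
  }
  est$units <- config$output_units

  keep <- c("sample_id", "genotype", "block", "plate_id", "f_value", "units",
            "ci_low", "ci_high", "qc_flags", "excluded",
            "f_mL_per_hr", "Ft_mean", "F0_mean", "tech_rep_cv", "n_reps", "status")
  est <- est[, keep]
  structure(list(estimates = est, retained = est[!est$excluded, ],
                 exclusion_log = qc$exclusion_log,
                 controls = controls, config = config),
            class = "feeding_rate_fit")
}

#' @export
print.feeding_rate_fit <- function(x, ...) {
  n <- nrow(x$estimates)
  cat(sprintf("Feeding-rate estimates: %d sample(s), %d retained, %d excluded\n",
              n, nrow(x$retained), n - nrow(x$retained)))
  if (n > 0) {
    f <- x$retained$f_value
    cat(sprintf("  f [%s]: mean %.4f, range [%.4f, %.4f]\n",
                x$estimates$units[1], mean(f), min(f), max(f)))
  }
  if (nrow(x$exclusion_log) > 0) {
    cat(sprintf("  exclusions: %s\n",
                paste(sprintf("%s (%s)", x$exclusion_log$sample_id,
                              x$exclusion_log$reasons), collapse = ", ")))
  }
  invisible(x)
}

#' Write estimates and the exclusion log to CSV
#' @param fit A [estimate_all()] result.
#' @param estimates_file,log_file Output paths (`log_file` optional).
#' @export
write_estimates <- function(fit, estimates_file, log_file = NULL) {
  stopifnot(inherits(fit, "feeding_rate_fit"))
  utils::write.csv(fit$estimates, estimates_file, row.names = FALSE)
  if (!is.null(log_file)) {
    utils::write.csv(fit$exclusion_log, log_file, row.names = FALSE)
  }
  invisible(estimates_file)
}

# per-plate blank (algae-free medium) mean subtracted from every well
subtract_blanks <- function(wells) {
  blanks <- wells[wells$role == "blank", ]
  if (nrow(blanks) == 0) {
    rlang::warn("blank_subtract requested but no blank wells present; skipping")
    return(wells)
  }
  bl <- dplyr::summarise(dplyr::group_by(blanks, .data$plate_id),
                         blank_mean = mean(.data$fluorescence), .groups = "drop")
  wells <- dplyr::left_join(wells, bl, by = "plate_id")
  adj <- !is.na(wells$blank_mean)
  wells$fluorescence[adj] <- pmax(wells$fluorescence[adj] - wells$blank_mean[adj], 0)
  wells$blank_mean <- NULL
  wells
}
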