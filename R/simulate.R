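# Synthetic grazing-assay generator with known truth, plus parameter-recovery
# and error-rate experiments built on it.
#
# Forward model per well: a sample well reads
#   F0_true * exp(-f t / V) * plate_factor * (1 + cv * eps),
# a control well F0_true * plate_factor * (1 + cv * eps), with eps standard
# normal and plate_factor lognormal (multiplicative plate/gain effects -- the
# regime the matched-pairs plate design is built to cancel). Artifacts are
# injected at stated rates: deaths and males set metadata status flags;
# "spurious spikes" multiply one sample well upward to induce a negative
# estimated rate (the signature of a technical error).

#' Parameters for a synthetic grazing assay
#'
#' Defaults mirror the standard study design: 7 genotypes x 30 animals, two
#' technical replicates, 6 consumer-free controls per 96-well plate
#' (45 samples x 2 wells + 6 controls fills a plate exactly), two temporal
#' blocks, 10 mL tubes, 7 hr assays. True genotype clearance rates default to
#' an even spread over 0.6--1.2 mL hr^-1, a typical Daphnia range.
#'
#' @param genotype_true_f Named numeric: true clearance rate (mL hr^-1) per
#'   genotype.
#' @param n_per_genotype Animals per genotype.
#' @param tech_reps Technical-replicate wells per animal.
#' @param controls_per_plate Consumer-free control wells per plate (>= 1).
#' @param n_blocks Temporal blocks; animals are assigned round-robin.
#' @param F0_true True consumer-free fluorescence (RFU).
#' @param well_noise_cv Well-level multiplicative noise CV (fraction).
#' @param plate_effect_sd SD of the log plate factor (0 = no plate effects).
#' @param artifact_rates Named fractions: `death`, `male`, `spurious_spike`.
#' @param V_mL,t_hr Tube volume and assay duration.
#' @param control_role Role written for control wells (`"control"` or
#'   `"stressor_control"`).
#' @param stressor_background Additive background fluorescence (RFU) applied
#'   to every tube, emulating a fluorescent stressor; 0 disables.
#' @param seed Integer seed (mandatory).
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(genotype_true_f = stats::setNames(seq(0.6, 1.2, length.out = 7),
                                                                paste0("G", 1:7)),
                              n_per_genotype = 30,
                              tech_reps = 2,
                              controls_per_plate = 6,
                              n_blocks = 2,
                              F0_true = 1000,
                              well_noise_cv = 0.05,
                              plate_effect_sd = 0.1,
                              artifact_rates = c(death = 0, male = 0, spurious_spike = 0),
                              V_mL = 10, t_hr = 7,
                              control_role = c("control", "stressor_control"),
                              stressor_background = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    abort_grazekit("simulation seed is mandatory", class = "grazekit_config_error")
  }
  control_role <- match.arg(control_role)
  ar <- c(death = 0, male = 0, spurious_spike = 0)
  ar[names(artifact_rates)] <- artifact_rates
  stopifnot(all(ar >= 0 & ar <= 1), F0_true > 0, controls_per_plate >= 1,
            n_per_genotype >= 1, tech_reps >= 1, n_blocks >= 1,
            well_noise_cv >= 0, plate_effect_sd >= 0, V_mL > 0, t_hr > 0,
            stressor_background >= 0)
  if (is.null(names(genotype_true_f))) {
    names(genotype_true_f) <- paste0("G", seq_along(genotype_true_f))
  }
  structure(list(genotype_true_f = genotype_true_f,
                 n_per_genotype = as.integer(n_per_genotype),
                 tech_reps = as.integer(tech_reps),
                 controls_per_plate = as.integer(controls_per_plate),
                 n_blocks = as.integer(n_blocks),
                 F0_true = F0_true,
                 well_noise_cv = well_noise_cv,
                 plate_effect_sd = plate_effect_sd,
                 artifact_rates = ar,
                 V_mL = V_mL, t_hr = t_hr,
                 control_role = control_role,
                 stressor_background = stressor_background,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a complete grazing assay
#'
#' Generates plate reads, a layout, sample metadata and a truth table that
#' parse through the package's own I/O unmodified. Fully reproducible from
#' the seed.
#'
#' @param params A [simulation_params()] object.
#' @return A `simulated_dataset` list: `wells` (read table, values only),
#'   `layout`, `meta`, `truth` (sample_id, genotype, block, true_f,
#'   true_status, spiked), `params`.
#' @export
simulate_assay <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  wells_per_sample <- p$tech_reps
  capacity <- 96 - p$controls_per_plate
  samples_per_plate <- capacity %/% wells_per_sample
  if (samples_per_plate < 1) {
    abort_grazekit("wells demanded per sample exceed plate capacity",
                   class = "grazekit_design_error")
  }

  geno <- names(p$genotype_true_f)
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(length(geno) * p$n_per_genotype)),
    genotype = rep(geno, each = p$n_per_genotype),
    block = paste0("B", rep_len(seq_len(p$n_blocks), length(geno) * p$n_per_genotype))
  )
  samples$true_f <- p$genotype_true_f[samples$genotype]

  withr::with_seed(p$seed, {
    # plates nested in blocks; tube-to-plate assignment randomized within each
    # block, as on the bench: no genotype is confounded with a plate, and the
    # plate-shared control-mean error enters genotype contrasts the way the
    # ANOVA's randomization assumption expects
    perm <- unlist(lapply(split(seq_len(nrow(samples)), samples$block),
                          function(ix) ix[sample.int(length(ix))]),
                   use.names = FALSE)
    samples <- samples[perm, ]
    plate_seq <- unlist(lapply(split(seq_len(nrow(samples)), samples$block), function(ix) {
      ceiling(seq_along(ix) / samples_per_plate)
    }), use.names = FALSE)
    samples$plate_id <- paste0("P_", samples$block, "_", sprintf("%02d", plate_seq))

    n <- nrow(samples)
    samples$true_status <- rep("ok", n)
    died <- stats::runif(n) < p$artifact_rates[["death"]]
    male <- stats::runif(n) < p$artifact_rates[["male"]]
    samples$true_status[died] <- "died"
    samples$true_status[male] <- ifelse(died[male], "died;male", "male")
    samples$spiked <- stats::runif(n) < p$artifact_rates[["spurious_spike"]]

    plates <- unique(samples$plate_id)
    plate_factor <- stats::setNames(
      exp(stats::rnorm(length(plates), 0, p$plate_effect_sd)), plates)

    # wells, plate by plate: controls first, then sample replicates row-major
    make_plate <- function(pl) {
      ps <- samples[samples$plate_id == pl, ]
      n_wells <- p$controls_per_plate + nrow(ps) * wells_per_sample
      pos <- seq_len(n_wells)
      row <- PLATE_ROWS[(pos - 1) %/% 12 + 1]
      col <- (pos - 1) %% 12 + 1
      role <- c(rep(p$control_role, p$controls_per_plate),
                rep("sample", nrow(ps) * wells_per_sample))
      sid <- c(rep(NA_character_, p$controls_per_plate),
               rep(ps$sample_id, each = wells_per_sample))
      f_true <- c(rep(0, p$controls_per_plate), rep(ps$true_f, each = wells_per_sample))
      mean_signal <- p$F0_true * exp(-f_true * p$t_hr / p$V_mL) + p$stressor_background
      noise <- 1 + p$well_noise_cv * stats::rnorm(n_wells)
      fl <- pmax(mean_signal * plate_factor[[pl]] * noise, 0)
      # spike: one well of each affected sample pushed well above F(0)
      spiked_ids <- ps$sample_id[ps$spiked]
      if (length(spiked_ids) > 0) {
        first_well <- match(spiked_ids, sid)
        fl[first_well] <- fl[first_well] *
          (3 * p$F0_true / (p$F0_true * exp(-ps$true_f[ps$spiked] * p$t_hr / p$V_mL)))
      }
      tibble::tibble(plate_id = pl, well = well_string(row, col), row = row,
                     column = as.integer(col), fluorescence = fl,
                     role = role, sample_id = sid)
    }
    plate_tabs <- lapply(plates, make_plate)
  })

  all_wells <- dplyr::bind_rows(plate_tabs)
  layout <- all_wells[, c("plate_id", "well", "role", "sample_id")]
  reads <- all_wells[, c("plate_id", "well", "row", "column", "fluorescence")]
  reads$role <- "empty"; reads$sample_id <- NA_character_; reads$gain <- NA_integer_
  meta <- tibble::tibble(sample_id = samples$sample_id, genotype = samples$genotype,
                         block = samples$block, status = samples$true_status,
                         volume_mL = p$V_mL, hours = p$t_hr)
  meta <- meta[order(meta$sample_id), ]
  truth <- samples[order(samples$sample_id),
                   c("sample_id", "genotype", "block", "plate_id", "true_f",
                     "true_status", "spiked")]
  structure(list(wells = reads, layout = layout, meta = meta, truth = truth,
                 params = p),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated grazing assay: %d samples, %d plates, %d wells (seed %d)\n",
              nrow(x$truth), length(unique(x$wells$plate_id)), nrow(x$wells),
              x$params$seed))
  invisible(x)
}

#' Write a simulated dataset as the CSV dialects the parsers read
#'
#' One grid CSV per plate (`reads_<plate>.csv`), plus `layout.csv`,
#' `meta.csv`, `truth.csv` and `params.yaml`. Wells the simulation did not
#' use are written as zero-fluorescence empty wells so each grid is complete.
#'
#' @param sim A [simulate_assay()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pl in unique(sim$wells$plate_id)) {
    w <- sim$wells[sim$wells$plate_id == pl, ]
    present <- w$well
    all96 <- expand.grid(row = PLATE_ROWS, column = PLATE_COLS,
                         stringsAsFactors = FALSE)
    missing <- !(well_string(all96$row, all96$column) %in% present)
    if (any(missing)) {
      pad <- tibble::tibble(plate_id = pl,
                            well = well_string(all96$row[missing], all96$column[missing]),
                            row = all96$row[missing],
                            column = as.integer(all96$column[missing]),
                            fluorescence = 0, role = "empty",
                            sample_id = NA_character_, gain = NA_integer_)
      w <- dplyr::bind_rows(w, pad)
    }
    write_plate_grid(w, file.path(dir, paste0("reads_", pl, ".csv")))
  }
  utils::write.csv(sim$layout, file.path(dir, "layout.csv"), row.names = FALSE)
  utils::write.csv(sim$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = sim$params$seed,
                        V_mL = sim$params$V_mL, t_hr = sim$params$t_hr,
                        F0_true = sim$params$F0_true,
                        well_noise_cv = sim$params$well_noise_cv,
                        plate_effect_sd = sim$params$plate_effect_sd),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Annotated well table of a simulated dataset
#'
#' Convenience wrapper: joins the simulated layout and metadata onto the
#' reads exactly as a user would with [join_layout()].
#'
#' @param sim A [simulate_assay()] result.
#' @return Annotated well tibble ready for [estimate_all()].
#' @export
sim_wells <- function(sim) {
  stopifnot(inherits(sim, "simulated_dataset"))
  join_layout(sim$wells, sim$layout, sim$meta)
}

#' Parameter-recovery report
#'
#' Compares estimates against the generating truth, per genotype: mean bias
#' (f_hat - f_true), mean absolute relative bias, RMSE, and (when bootstrap
#' CIs are present) the fraction of CIs covering the true rate. QC-excluded
#' samples are not scored.
#'
#' @param truth Truth tibble (`sample_id`, `genotype`, `true_f`), e.g.
#'   `sim$truth`.
#' @param estimates A `feeding_rate_fit` or its retained estimate tibble
#'   (rates in mL hr^-1 taken from `f_mL_per_hr`).
#' @return List: `per_genotype` tibble (`genotype`, `n`, `bias`,
#'   `mean_abs_rel_bias`, `rmse`, `coverage`), `overall` one-row tibble.
#' @export
recovery_report <- function(truth, estimates) {
  if (inherits(estimates, "feeding_rate_fit")) {
    ci_units <- estimates$config$output_units
    est <- estimates$retained
    if (ci_units != "mL_per_hr") {  # score in canonical units
      est$ci_low <- convert_units(est$ci_low, to = "mL_per_hr", from = ci_units)
      est$ci_high <- convert_units(est$ci_high, to = "mL_per_hr", from = ci_units)
    }
  } else {
    est <- tibble::as_tibble(estimates)
    if ("excluded" %in% colnames(est)) est <- est[!est$excluded, ]
  }
  if (!"f_mL_per_hr" %in% colnames(est)) {
    abort_grazekit("estimates need an f_mL_per_hr column")
  }
  joined <- dplyr::inner_join(tibble::as_tibble(truth)[, c("sample_id", "genotype", "true_f")],
                              est[, intersect(c("sample_id", "f_mL_per_hr", "ci_low", "ci_high"),
                                              colnames(est))],
                              by = "sample_id")
  if (nrow(joined) == 0) {
    abort_grazekit("truth and estimates share no sample_ids")
  }
  have_ci <- all(c("ci_low", "ci_high") %in% colnames(joined)) &&
    any(is.finite(joined$ci_low))
  per_g <- dplyr::summarise(
    dplyr::group_by(joined, .data$genotype),
    n = dplyr::n(),
    bias = mean(.data$f_mL_per_hr - .data$true_f),
    mean_abs_rel_bias = abs(mean(.data$f_mL_per_hr - .data$true_f)) / mean(.data$true_f),
    rmse = sqrt(mean((.data$f_mL_per_hr - .data$true_f)^2)),
    coverage = if (have_ci) {
      mean(.data$ci_low <= .data$true_f & .data$true_f <= .data$ci_high)
    } else NA_real_,
    .groups = "drop")
  overall <- tibble::tibble(
    n = nrow(joined),
    bias = mean(joined$f_mL_per_hr - joined$true_f),
    mean_abs_rel_bias = mean(per_g$mean_abs_rel_bias),
    rmse = sqrt(mean((joined$f_mL_per_hr - joined$true_f)^2)),
    coverage = if (have_ci) {
      mean(joined$ci_low <= joined$true_f & joined$true_f <= joined$ci_high)
    } else NA_real_)
  list(per_genotype = per_g, overall = overall)
}

#' Monte-Carlo error rate of the genotype test
#'
#' Repeatedly simulates an assay, runs the estimation pipeline and the
#' blocked Type III ANOVA, and reports how often the genotype main effect is
#' rejected at `alpha`. With equal true rates in `params` this measures the
#' type-I error; with unequal rates, power.
#'
#' @param params A [simulation_params()] (its `seed` seeds the experiment;
#'   each simulation gets a derived child seed).
#' @param n_sims Number of simulated assays (>= 1).
#' @param alpha Rejection level (default 0.05).
#' @return List: `rejection_rate`, `n_sims`, `alpha`, `ci` (exact binomial
#'   95% CI), `p_values`.
#' @export
error_rate_experiment <- function(params, n_sims, alpha = 0.05) {
  stopifnot(inherits(params, "simulation_params"), n_sims >= 1)
  seeds <- derive_seeds(params$seed, n_sims)
  config <- assay_config(default_volume_mL = params$V_mL, default_hours = params$t_hr,
                         bootstrap_B = 0)
  pvals <- vapply(seq_len(n_sims), function(i) {
    p_i <- params; p_i$seed <- seeds[i]
    sim <- simulate_assay(p_i)
    fit <- suppressWarnings(estimate_all(sim_wells(sim), config))
    an <- fit_blocked_anova(fit)
    an$effects$p_value[an$effects$term == "genotype"]
  }, numeric(1))
  rate <- mean(pvals < alpha)
  bt <- stats::binom.test(sum(pvals < alpha), n_sims)
  list(rejection_rate = rate, n_sims = n_sims, alpha = alpha,
       ci = unname(bt$conf.int), p_values = pvals)
}
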