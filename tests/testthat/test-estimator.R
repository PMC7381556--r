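test_that("control summaries are plate-specific arithmetic", {
  wells <- toy_wells(controls = c(980, 1020, 1000), samples = list(S1 = c(500, 520)))
  ctl <- summarize_controls(wells)
  expect_equal(ctl$F0_mean, 1000)
  expect_equal(ctl$F0_sd, 20)
  expect_equal(ctl$n_controls, 3L)

  no_ctl <- toy_wells(controls = numeric(), samples = list(S1 = c(500, 520)))
  expect_error(summarize_controls(no_ctl), "without control")

  one <- toy_wells(controls = 1000, samples = list(S1 = c(500, 520)))
  expect_warning(ctl1 <- summarize_controls(one), "single control")
  expect_equal(ctl1$F0_mean, 1000)
  expect_equal(ctl1$n_controls, 1L)
})

test_that("technical replicates aggregate by mean with a CV flag", {
  wells <- toy_wells(controls = 1000,
                     samples = list(S1 = c(500, 520), S2 = c(500, 500),
                                    S3 = c(400, 600)))
  agg <- suppressWarnings(aggregate_technical_replicates(wells))
  agg <- agg[order(agg$sample_id), ]
  expect_equal(agg$Ft_mean, c(510, 500, 500))
  expect_equal(agg$tech_rep_cv[1], sd(c(500, 520)) / 510)
  expect_equal(agg$tech_rep_cv[2], 0)
  expect_equal(agg$tech_rep_cv[3], sd(c(400, 600)) / 500)  # ~0.2828
  expect_equal(agg$high_tech_cv, c(FALSE, FALSE, TRUE))
})

test_that("the closed-form rate matches hand values and the sign contract", {
  expect_equal(compute_feeding_rate(1000, 1000, 10, 7), 0)
  expect_equal(compute_feeding_rate(1000, 500, 10, 7), (10 / 7) * log(2))
  expect_lt(compute_feeding_rate(1000, 1100, 10, 7), 0)
  expect_error(compute_feeding_rate(0, 500, 10, 7), "positive")
  expect_error(compute_feeding_rate(1000, 0, 10, 7), "positive")
  expect_error(compute_feeding_rate(1000, 500, -1, 7), "positive")

  # monotonicity: f strictly decreases as Ft increases
  Ft <- seq(200, 1500, by = 50)
  f <- compute_feeding_rate(1000, Ft, 10, 7)
  expect_true(all(diff(f) < 0))
  expect_true(all(f[Ft < 1000] > 0) && all(f[Ft > 1000] < 0))
})

test_that("closed form agrees with the ODE + root-finding oracle", {
  withr::with_seed(401, {
    n <- 50
    F0 <- runif(n, 500, 2000)
    ratio <- runif(n, 0.3, 1.4)  # includes negative-rate cases
    V <- runif(n, 5, 15)
    t <- runif(n, 2, 24)
  })
  Ft <- F0 * ratio
  f_closed <- compute_feeding_rate(F0, Ft, V, t)
  f_oracle <- mapply(ode_feeding_rate, F0, Ft, V, t)
  expect_lt(max(abs(f_closed - f_oracle) / pmax(abs(f_oracle), 1e-6)), 1e-8)
})

test_that("unit conversion is exact algebra with an exact round trip", {
  expect_equal(convert_units(1, "L_per_day"), 0.024)
  expect_equal(convert_units(0, "L_per_day"), 0)
  f <- c(0.3, 0.99, 1.5)
  expect_equal(convert_units(convert_units(f, "L_per_day"), "mL_per_hr",
                             from = "L_per_day"), f, tolerance = 1e-15)
  expect_error(convert_units(1, "gallons_per_fortnight"), "unknown unit")
})

test_that("QC excludes negative rates, deaths and males, and logs each", {
  est <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:10),
    f_mL_per_hr = c(-0.1, -0.2, rep(0.9, 8)),
    status = c("ok", "ok", "died", "male", rep("ok", 6)))
  qc <- apply_qc(est)
  expect_equal(nrow(qc$retained), 6)
  expect_equal(nrow(qc$exclusion_log), 4)
  expect_setequal(qc$exclusion_log$sample_id, c("S01", "S02", "S03", "S04"))

  clean <- apply_qc(tibble::tibble(sample_id = "S1", f_mL_per_hr = 1, status = "ok"))
  expect_equal(nrow(clean$retained), 1)
  expect_equal(nrow(clean$exclusion_log), 0)

  both <- apply_qc(tibble::tibble(sample_id = "S1", f_mL_per_hr = -1, status = "male"))
  expect_equal(nrow(both$exclusion_log), 1)
  expect_equal(both$exclusion_log$reasons, "negative_rate;male")

  kept <- apply_qc(est, keep_all = TRUE)
  expect_equal(nrow(kept$retained), 10)
  expect_true(all(grepl("negative_rate", kept$estimates$qc_flags[1:2])))
})

test_that("bootstrap CIs are seeded, degenerate on zero variance, and bracket f", {
  f_hat <- compute_feeding_rate(1000, 500, 10, 7)
  degen <- bootstrap_ci(rep(1000, 3), c(500, 500), 10, 7, B = 200, seed = 5)
  expect_equal(unname(degen), c(f_hat, f_hat))

  ci1 <- bootstrap_ci(c(990, 1010, 1000), c(495, 505), 10, 7, B = 2000, seed = 5)
  ci2 <- bootstrap_ci(c(990, 1010, 1000), c(495, 505), 10, 7, B = 2000, seed = 5)
  expect_identical(ci1, ci2)
  f_pt <- compute_feeding_rate(1000, 500, 10, 7)
  expect_lt(ci1[["ci_low"]], f_pt)
  expect_gt(ci1[["ci_high"]], f_pt)

  # doubling every well count shrinks the width roughly like 1/sqrt(2),
  # as the delta-method variance of the log ratio-of-means predicts
  ctl <- c(990, 1010, 1000, 995, 1005, 1002)
  reps <- c(495, 505, 492, 508)
  w1 <- diff(bootstrap_ci(ctl, reps, 10, 7, B = 4000, seed = 6))
  w2 <- diff(bootstrap_ci(rep(ctl, 2), rep(reps, 2), 10, 7, B = 4000, seed = 6))
  expect_gt(w2 / w1, 0.55)
  expect_lt(w2 / w1, 0.9)
})

test_that("estimate_all pairs each sample with its own plate's controls", {
  p1 <- toy_wells(controls = c(1000, 1000, 1000), samples = list(S1 = c(500, 500)))
  est1 <- estimate_all(p1)$estimates
  expect_equal(est1$f_value, (10 / 7) * log(2), tolerance = 1e-12)
  expect_equal(est1$units, "mL_per_hr")

  p2 <- toy_wells(controls = c(800, 800), samples = list(S2 = c(500, 500)),
                  plate_id = "P2")
  both <- estimate_all(bind_plates(p1, p2))$estimates
  f_by_id <- setNames(both$f_mL_per_hr, both$sample_id)
  expect_equal(f_by_id[["S1"]], (10 / 7) * log(1000 / 500))
  expect_equal(f_by_id[["S2"]], (10 / 7) * log(800 / 500))
  expect_gt(f_by_id[["S1"]], f_by_id[["S2"]])
})

test_that("estimate_all handles empty input, split samples, and V/t overrides", {
  none <- toy_wells(controls = c(1000, 1000), samples = list())
  fit <- estimate_all(none)
  expect_equal(nrow(fit$estimates), 0)

  split_sample <- bind_plates(
    toy_wells(controls = 1000, samples = list(S1 = 500)),
    toy_wells(controls = 1000, samples = list(S1 = 510), plate_id = "P2"))
  split_sample$n_tech_reps[split_sample$role == "sample"] <- 2L
  expect_error(suppressWarnings(estimate_all(split_sample)), "split across plates")

  vt <- toy_wells(controls = c(1000, 1000), samples = list(S1 = c(500, 500)),
                  volume_mL = 20, hours = 10)
  expect_equal(estimate_all(vt)$estimates$f_value, 2 * log(2))
})

test_that("estimates are invariant to rescaling a plate's wells", {
  sim <- simulate_assay(simulation_params(seed = 11,
                                          n_per_genotype = 6))
  wells <- sim_wells(sim)
  base <- estimate_all(wells)$estimates
  for (c_scale in c(0.25, 3.7)) {
    scaled <- wells
    pl <- unique(scaled$plate_id)[1]
    scaled$fluorescence[scaled$plate_id == pl] <-
      scaled$fluorescence[scaled$plate_id == pl] * c_scale
    redone <- estimate_all(scaled)$estimates
    expect_equal(redone$f_value, base$f_value, tolerance = 1e-12)
  }
})

test_that("blank subtraction is off by default and exact when on", {
  wells <- toy_wells(controls = c(1050, 1050), samples = list(S1 = c(550, 550)),
                     blanks = c(50, 50))
  plain <- estimate_all(wells)$estimates
  expect_equal(plain$f_value, (10 / 7) * log(1050 / 550))
  cfg <- assay_config(bootstrap_B = 0, blank_subtract = TRUE)
  blanked <- estimate_all(wells, cfg)$estimates
  expect_equal(blanked$f_value, (10 / 7) * log(2), tolerance = 1e-12)
})

test_that("bootstrap CIs flow through estimate_all deterministically", {
  wells <- toy_wells(controls = c(990, 1010, 1000), samples = list(S1 = c(495, 505)))
  cfg <- assay_config(bootstrap_B = 500, rng_seed = 9)
  e1 <- estimate_all(wells, cfg)$estimates
  e2 <- estimate_all(wells, cfg)$estimates
  expect_identical(e1$ci_low, e2$ci_low)
  expect_true(e1$ci_low <= e1$f_value && e1$f_value <= e1$ci_high)

  lday <- assay_config(bootstrap_B = 500, rng_seed = 9, output_units = "L_per_day")
  e3 <- estimate_all(wells, lday)$estimates
  expect_equal(e3$f_value, e1$f_value * 0.024)
  expect_equal(e3$ci_low, e1$ci_low * 0.024)
})
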