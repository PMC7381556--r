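test_that("identical genotype means give a zero genotype statistic", {
  est <- make_estimates(c(G1 = 1, G2 = 1, G3 = 1), n = 6, block_effect = 0.2)
  fit <- fit_blocked_anova(est)
  gstat <- fit$effects$statistic[fit$effects$term == "genotype"]
  expect_equal(gstat, 0, tolerance = 1e-20)
  expect_equal(fit$effects$chisq[fit$effects$term == "genotype"], 0,
               tolerance = 1e-20)
})

test_that("Type III equals the sequential decomposition on balanced data", {
  est <- make_estimates(c(G1 = 0.8, G2 = 1.0, G3 = 1.2), n = 8, sd = 0.1,
                        block_effect = 0.15, seed = 501)
  fit <- fit_blocked_anova(est)
  # independent oracle: sequential (Type I) ANOVA on the same model
  seq_tab <- stats::anova(stats::lm(f_value ~ genotype * block, data = fit$data))
  for (term in c("genotype", "block", "genotype:block")) {
    expect_equal(fit$effects$statistic[fit$effects$term == term],
                 seq_tab[term, "F value"], tolerance = 1e-10)
  }
})

test_that("Type III statistics are invariant to factor-level order", {
  est <- make_estimates(c(G1 = 0.8, G2 = 1.0, G3 = 1.3), n = 7, sd = 0.12,
                        block_effect = 0.1, seed = 502)
  est <- est[-(1:4), ]  # make it unbalanced, where naive marginal SS breaks
  f_ref <- fit_blocked_anova(est)$effects
  for (perm_seed in 1:3) {
    shuffled <- est
    lev <- withr::with_seed(perm_seed, sample(unique(est$genotype)))
    shuffled$genotype <- factor(shuffled$genotype, levels = lev)
    f_perm <- fit_blocked_anova(shuffled)$effects
    expect_equal(f_perm$statistic[f_perm$term == "genotype"],
                 f_ref$statistic[f_ref$term == "genotype"], tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected with named errors", {
  est <- make_estimates(c(G1 = 1, G2 = 1.2), n = 4, sd = 0.05, seed = 503)
  solo <- est[est$genotype == "G1", ]
  expect_error(fit_blocked_anova(solo), "at least 2 genotypes")
  est$excluded <- est$genotype == "G2"
  expect_error(fit_blocked_anova(est), "G2")
})

test_that("Shapiro-Wilk wrapper behaves under H0, skew, and degeneracy", {
  pvals <- vapply(1:100, function(i) {
    r <- withr::with_seed(600 + i, rnorm(200))
    test_normality(r)$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)

  skewed <- withr::with_seed(604, exp(rnorm(200)))
  expect_lt(test_normality(skewed)$p_value, 0.01)

  degen <- test_normality(rep(1, 50))
  expect_false(degen$pass)
  expect_true(is.na(degen$W))
  expect_error(test_normality(c(1, 2)), "at least 3")
})

test_that("interaction is dropped only when non-significant, else refused", {
  no_int <- make_estimates(c(G1 = 0.8, G2 = 1.1, G3 = 1.2), n = 10, sd = 0.1,
                           block_effect = 0.1, seed = 505)
  fit <- fit_blocked_anova(no_int)
  main <- drop_interaction_and_refit(fit)
  expect_false(main$interaction)
  expect_match(main$refit_note, "averaged across blocks")
  expect_false("genotype:block" %in% main$effects$term)

  strong_int <- make_estimates(
    c(G1 = 0.8, G2 = 1.1), n = 12, sd = 0.05, seed = 506,
    interaction = list(G1 = c(0, 0.5), G2 = c(0, -0.5)))
  fit_i <- fit_blocked_anova(strong_int)
  expect_error(drop_interaction_and_refit(fit_i), "override")
  forced <- drop_interaction_and_refit(fit_i, override = TRUE)
  expect_false(forced$interaction)

  single_block <- make_estimates(c(G1 = 0.9, G2 = 1.1), n = 8, sd = 0.05,
                                 blocks = "B1", seed = 507)
  fit_s <- fit_blocked_anova(single_block)
  expect_match(fit_s$note, "single block")
  refit_s <- drop_interaction_and_refit(fit_s)
  expect_match(refit_s$refit_note, "single block")
})

test_that("Tukey-Kramer produces G(G-1)/2 comparisons with valid intervals", {
  est <- make_estimates(stats::setNames(seq(0.6, 1.2, length.out = 7),
                                        paste0("G", 1:7)),
                        n = 10, sd = 0.08, block_effect = 0.1, seed = 508)
  main <- fit_blocked_anova(est, interaction = FALSE)
  tk <- tukey_genotype(main)
  expect_equal(nrow(tk$comparisons), 21)
  expect_true(all(tk$comparisons$ci_low <= tk$comparisons$difference))
  expect_true(all(tk$comparisons$difference <= tk$comparisons$ci_high))
  expect_true(all(tk$comparisons$adj_p >= 0 & tk$comparisons$adj_p <= 1))
  expect_error(tukey_genotype(fit_blocked_anova(est)), "main-effects")
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise p-values", {
  est <- make_estimates(c(G1 = 0.9, G2 = 1.0, G3 = 1.05, G4 = 1.2), n = 8,
                        sd = 0.1, block_effect = 0.1, seed = 509)
  main <- fit_blocked_anova(est, interaction = FALSE)
  tk <- tukey_genotype(main)
  unadj <- 2 * stats::pt(abs(tk$comparisons$difference) / tk$comparisons$se,
                         df = main$fit$df.residual, lower.tail = FALSE)
  expect_true(all(tk$comparisons$adj_p >= unadj - 1e-12))
})

test_that("Tukey-Kramer matches TukeyHSD exactly on a balanced one-way design", {
  est <- make_estimates(c(G1 = 0.8, G2 = 1.0, G3 = 1.15, G4 = 1.3), n = 9,
                        sd = 0.1, blocks = "B1", seed = 510)
  main <- fit_blocked_anova(est)  # single block -> f ~ genotype
  tk <- tukey_genotype(main)
  hsd <- stats::TukeyHSD(stats::aov(f_value ~ genotype, data = main$data))$genotype
  key <- paste(tk$comparisons$genotype_b, tk$comparisons$genotype_a, sep = "-")
  expect_equal(unname(-tk$comparisons$difference), unname(hsd[key, "diff"]),
               tolerance = 1e-10)
  expect_equal(unname(-tk$comparisons$ci_high), unname(hsd[key, "lwr"]),
               tolerance = 1e-10)
  expect_equal(unname(tk$comparisons$adj_p), unname(hsd[key, "p adj"]),
               tolerance = 1e-6)
})

test_that("Tukey-Kramer agrees with multcomp on an unbalanced blocked design", {
  est <- make_estimates(c(G1 = 0.85, G2 = 1.0, G3 = 1.2), n = 12, sd = 0.1,
                        block_effect = 0.12, seed = 511)
  est <- est[-c(1, 2, 3, 20, 40), ]
  main <- fit_blocked_anova(est, interaction = FALSE)
  tk <- tukey_genotype(main)
  glht_fit <- multcomp::glht(main$fit,
                             linfct = multcomp::mcp(genotype = "Tukey"))
  sm <- withr::with_seed(512, summary(glht_fit))
  ci <- withr::with_seed(512, stats::confint(glht_fit))
  expect_equal(unname(-tk$comparisons$difference),
               unname(coef(glht_fit)), tolerance = 1e-10)
  # multivariate-t vs studentized-range: close but not identical
  expect_equal(unname(tk$comparisons$adj_p), as.numeric(sm$test$pvalues),
               tolerance = 0.02)
  expect_equal(unname(-tk$comparisons$difference - (-tk$comparisons$ci_high)),
               unname(ci$confint[, "upr"] - ci$confint[, "Estimate"]),
               tolerance = 0.05)
})

test_that("well-separated genotypes are always detected; identical ones never", {
  # two means 10 pooled SDs apart, n = 30 each: the interval must exclude 0
  hits <- vapply(1:100, function(i) {
    est <- make_estimates(c(G1 = 1.0, G2 = 2.0), n = 15, sd = 0.1,
                          block_effect = 0.05, seed = 700 + i)
    tk <- tukey_genotype(fit_blocked_anova(est, interaction = FALSE))
    tk$comparisons$ci_low > 0 | tk$comparisons$ci_high < 0
  }, logical(1))
  expect_true(all(hits))

  # zero noise, identical means: difference 0, CI [0, 0], adj_p = 1
  est0 <- tibble::tibble(sample_id = as.character(1:12),
                         genotype = rep(c("G1", "G2"), each = 6),
                         block = rep(c("B1", "B2"), 6), f_value = 1)
  tk0 <- tukey_genotype(fit_blocked_anova(est0, interaction = FALSE))
  expect_equal(tk0$comparisons$difference, 0)
  expect_equal(tk0$comparisons$adj_p, 1)
  expect_true(tk0$comparisons$ci_low <= 0 && tk0$comparisons$ci_high >= 0)
})

test_that("compact letter display separates distinct means and shares letters", {
  est <- make_estimates(c(A = 0.5, B = 0.52, C = 2.0), n = 10, sd = 0.2,
                        block_effect = 0, seed = 513)
  tk <- tukey_genotype(fit_blocked_anova(est, interaction = FALSE))
  expect_equal(tk$letters[["A"]], tk$letters[["B"]])  # indistinguishable pair
  expect_false(tk$letters[["C"]] == tk$letters[["A"]])
})

test_that("the comparison report round-trips through CSV", {
  est <- make_estimates(c(G1 = 0.8, G2 = 1.2), n = 6, sd = 0.05, seed = 514)
  main <- fit_blocked_anova(est, interaction = FALSE)
  tk <- tukey_genotype(main)
  nm <- test_normality(main)
  dir <- withr::local_tempdir()
  write_comparison_report(main, tk, nm, dir)
  expect_true(all(file.exists(file.path(dir, c("effects.csv", "pairwise.csv",
                                               "normality.csv")))))
  eff <- utils::read.csv(file.path(dir, "effects.csv"))
  expect_equal(nrow(eff), nrow(main$effects))
})
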