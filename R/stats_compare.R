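# Inference on retained clearance rates: blocked ANOVA with Type III
# (marginal) sums of squares, residual normality diagnostics, and all-pairs
# genotype comparisons with Tukey-Kramer simultaneous confidence intervals.
#
# Type III tests are only meaningful under sum-to-zero contrasts, so those
# are forced internally; user-supplied contrasts are not honoured. Each term
# is reported both as an F statistic and as a Wald chi-square
# (chisq = F * df_num), since both conventions circulate for this design.

#' Fit a blocked ANOVA to retained feeding rates
#'
#' Fits `f ~ genotype * block` (or `f ~ genotype + block` with
#' `interaction = FALSE`) by least squares with sum-to-zero contrasts and
#' reports marginal (Type III) tests for every term. With a single block
#' level the block terms are dropped and noted.
#'
#' @param estimates A `feeding_rate_fit` from [estimate_all()], or an
#'   estimate tibble with columns `f_value`, `genotype`, `block` (rows with
#'   `excluded = TRUE` are dropped if present).
#' @param interaction Include the genotype x block interaction (default `TRUE`).
#' @return A `feeding_anova` object: `effects` tibble (term, df, den_df,
#'   F, p_value, chisq, chisq_p), `residuals`, `fit` (the `lm`), `data`,
#'   `interaction`, `note`.
#' @export
fit_blocked_anova <- function(estimates, interaction = TRUE) {
  dat <- anova_data(estimates)
  note <- NULL
  if (nlevels(dat$block) < 2) {
    note <- "single block: block and interaction terms inestimable, fitted f ~ genotype"
    form <- f_value ~ genotype
    interaction <- FALSE
  } else if (interaction) {
    form <- f_value ~ genotype * block
  } else {
    form <- f_value ~ genotype + block
  }
  contr <- list(genotype = "contr.sum")
  if (nlevels(dat$block) >= 2) contr$block <- "contr.sum"
  fit <- stats::lm(form, data = dat, contrasts = contr)
  if (any(is.na(stats::coef(fit)))) {
    abort_grazekit("singular design: some model terms are not estimable",
                   class = "grazekit_design_error")
  }
  a3 <- tryCatch(car::Anova(fit, type = 3),
                 error = function(e) {
                   if (grepl("residual sum of squares is 0", conditionMessage(e))) {
                     type3_zero_residual(fit)
                   } else stop(e)
                 })
  terms <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  den_df <- a3["Residuals", "Df"]
  eff <- tibble::tibble(
    term = terms,
    df = a3[terms, "Df"],
    den_df = den_df,
    statistic = a3[terms, "F value"],
    p_value = a3[terms, "Pr(>F)"],
    chisq = a3[terms, "F value"] * a3[terms, "Df"],
    chisq_p = stats::pchisq(a3[terms, "F value"] * a3[terms, "Df"],
                            df = a3[terms, "Df"], lower.tail = FALSE)
  )
  structure(list(effects = eff, residuals = unname(stats::residuals(fit)),
                 fit = fit, data = dat, interaction = interaction, note = note),
            class = "feeding_anova")
}

# Type III (marginal Wald) table when the model fits the data exactly and
# the residual SS is numerically 0: each term's SS is b' (X'X)^-1[term]^-1 b,
# the statistic is 0 for a zero-SS term and Inf otherwise.
type3_zero_residual <- function(fit) {
  asgn <- attr(stats::model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  b <- stats::coef(fit)
  xtxinv <- suppressWarnings(summary(fit)$cov.unscaled)  # perfect fits warn
  ss <- vapply(seq_along(labs), function(k) {
    idx <- which(asgn == k)
    drop(t(b[idx]) %*% solve(xtxinv[idx, idx, drop = FALSE]) %*% b[idx])
  }, numeric(1))
  df <- vapply(seq_along(labs), function(k) sum(asgn == k), numeric(1))
  tol <- 1e-10 * max(abs(stats::fitted(fit)), 1)^2
  fstat <- ifelse(ss <= tol, 0, Inf)
  out <- data.frame(`Sum Sq` = c(ss, 0), Df = c(df, stats::df.residual(fit)),
                    `F value` = c(fstat, NA), `Pr(>F)` = c(ifelse(ss <= tol, 1, 0), NA),
                    row.names = c(labs, "Residuals"), check.names = FALSE)
  out
}

anova_data <- function(estimates) {
  if (inherits(estimates, "feeding_rate_fit")) estimates <- estimates$estimates
  dat <- tibble::as_tibble(estimates)
  need <- c("f_value", "genotype", "block")
  miss <- setdiff(need, colnames(dat))
  if (length(miss) > 0) {
    abort_grazekit(sprintf("estimates need column(s): %s", paste(miss, collapse = ", ")))
  }
  all_geno <- unique(as.character(dat$genotype))
  if ("excluded" %in% colnames(dat)) dat <- dat[!dat$excluded, ]
  ok <- stats::complete.cases(dat[, need])
  dropped <- setdiff(all_geno, unique(as.character(dat$genotype[ok & is.finite(dat$f_value)])))
  dat <- dat[ok, ]
  if (length(dropped) > 0) {
    abort_grazekit(sprintf("genotype(s) with zero retained observations: %s",
                           paste(dropped, collapse = ", ")),
                   class = "grazekit_design_error")
  }
  dat$genotype <- droplevels(factor(dat$genotype))
  dat$block <- droplevels(factor(dat$block))
  if (nlevels(dat$genotype) < 2) {
    abort_grazekit("need at least 2 genotypes", class = "grazekit_design_error")
  }
  dat
}

#' @export
print.feeding_anova <- function(x, ...) {
  cat("Blocked ANOVA on feeding rates (Type III, sum-to-zero contrasts)\n")
  print(as.data.frame(x$effects), digits = 4, row.names = FALSE)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Shapiro-Wilk normality check of model residuals
#'
#' @param residuals Numeric residual vector (or a `feeding_anova`).
#' @return List: `W`, `p_value`, `n`, `pass` (`p >= 0.05`), `note`.
#'   Degenerate (constant) residuals report `pass = FALSE` with `W = NA`.
#' @export
test_normality <- function(residuals) {
  if (inherits(residuals, "feeding_anova")) residuals <- residuals$residuals
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 3) abort_grazekit("Shapiro-Wilk needs at least 3 residuals")
  if (stats::sd(residuals) == 0) {
    return(list(W = NA_real_, p_value = NA_real_, n = n, pass = FALSE,
                note = "degenerate (constant) residuals: W undefined"))
  }
  sw <- stats::shapiro.test(residuals)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n,
       pass = sw$p.value >= 0.05, note = NULL)
}

#' Drop a non-significant interaction and refit main effects
#'
#' Mirrors the standard reporting path: when the genotype x block interaction
#' is not significant, refit `f ~ genotype + block` so genotype effects are
#' averaged across blocks. Refuses to drop a significant interaction unless
#' explicitly overridden.
#'
#' @param fit A [fit_blocked_anova()] result with an interaction term.
#' @param threshold Interaction p-value above which dropping is allowed
#'   (default 0.05).
#' @param override Drop regardless of the interaction p-value.
#' @return A main-effects `feeding_anova`, with `interaction_p` and
#'   `refit_note` recorded.
#' @export
drop_interaction_and_refit <- function(fit, threshold = 0.05, override = FALSE) {
  stopifnot(inherits(fit, "feeding_anova"))
  if (!is.null(fit$note)) {  # single-block fit: nothing to drop
    fit$refit_note <- fit$note
    return(fit)
  }
  if (!fit$interaction) {
    fit$refit_note <- "no interaction term in the original fit"
    return(fit)
  }
  ip <- fit$effects$p_value[fit$effects$term == "genotype:block"]
  if (ip < threshold && !override) {
    abort_grazekit(sprintf(
      "interaction p = %.4g < %.3g: dropping it would average over a real genotype x block interaction (use override = TRUE to force)",
      ip, threshold), class = "grazekit_design_error")
  }
  refit <- fit_blocked_anova(fit$data, interaction = FALSE)
  refit$interaction_p <- ip
  refit$refit_note <- sprintf("interaction dropped (p = %.4g %s %.3g); genotype effects averaged across blocks",
                              ip, if (ip >= threshold) ">=" else "<", threshold)
  refit
}

#' Tukey-Kramer all-pairs genotype comparisons
#'
#' Block-adjusted genotype means (averaged over block levels) are compared
#' for every genotype pair with studentized-range critical values, giving
#' simultaneous 95% confidence intervals and adjusted p-values that are valid
#' under the unequal group sizes left after QC (Tukey-Kramer).
#'
#' @param fit A main-effects `feeding_anova` (no interaction term; see
#'   [drop_interaction_and_refit()]).
#' @param conf_level Simultaneous confidence level (default 0.95).
#' @return A `tukey_comparisons` object: tibble with `genotype_a`,
#'   `genotype_b`, `difference`, `se`, `ci_low`, `ci_high`, `adj_p`; plus
#'   `means` (adjusted genotype means) and `letters` (compact letter display).
#' @export
tukey_genotype <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "feeding_anova"))
  if (fit$interaction) {
    abort_grazekit("Tukey comparisons need a main-effects fit; drop the interaction first",
                   class = "grazekit_design_error")
  }
  lmfit <- fit$fit
  dat <- fit$data
  G <- nlevels(dat$genotype)
  if (G < 2) abort_grazekit("need at least 2 genotypes", class = "grazekit_design_error")
  geno <- levels(dat$genotype)
  blocks <- levels(dat$block)

  # adjusted mean for genotype g: average model prediction over block levels
  grid <- expand.grid(genotype = factor(geno, levels = geno),
                      block = factor(blocks, levels = blocks))
  X <- stats::model.matrix(stats::delete.response(stats::terms(lmfit)), grid,
                           contrasts.arg = lmfit$contrasts)
  L <- t(vapply(geno, function(g) colMeans(X[grid$genotype == g, , drop = FALSE]),
                numeric(ncol(X))))
  beta <- stats::coef(lmfit)
  V <- suppressWarnings(stats::vcov(lmfit))  # perfect fits warn in summary.lm
  means <- drop(L %*% beta)
  df <- stats::df.residual(lmfit)

  pairs <- utils::combn(G, 2)
  comp <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    l <- L[i, ] - L[j, ]
    diff <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% V %*% l))
    tol <- 1e-10 * max(abs(means), 1)  # zero-residual fits leave ~1e-16 dust
    if (se < tol) {
      if (abs(diff) < tol) diff <- 0
      adj_p <- if (diff == 0) 1 else 0
      half <- 0
    } else {
      q_obs <- sqrt(2) * abs(diff) / se
      adj_p <- stats::ptukey(q_obs, nmeans = G, df = df, lower.tail = FALSE)
      half <- stats::qtukey(conf_level, nmeans = G, df = df) / sqrt(2) * se
    }
    tibble::tibble(genotype_a = geno[i], genotype_b = geno[j],
                   difference = diff, se = se,
                   ci_low = diff - half, ci_high = diff + half, adj_p = adj_p)
  })
  comparisons <- dplyr::bind_rows(comp)
  structure(list(comparisons = comparisons,
                 means = stats::setNames(means, geno),
                 letters = cld_letters(geno, means, comparisons),
                 conf_level = conf_level, df = df, n_genotypes = G),
            class = "tukey_comparisons")
}

#' @export
print.tukey_comparisons <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons: %d genotypes, %d pairs, %g%% simultaneous CIs\n",
              x$n_genotypes, nrow(x$comparisons), 100 * x$conf_level))
  print(as.data.frame(x$comparisons), digits = 4, row.names = FALSE)
  cat("compact letter display:",
      paste(sprintf("%s=%s", names(x$letters), x$letters), collapse = " "), "\n")
  invisible(x)
}

# compact letter display: genotypes sharing a letter are not significantly
# different. Means are sorted; each letter covers a maximal run of genotypes
# whose pairwise adjusted p-values all exceed alpha.
cld_letters <- function(geno, means, comparisons, alpha = 0.05) {
  ord <- order(means, decreasing = TRUE)
  g_sorted <- geno[ord]
  G <- length(geno)
  p_of <- function(a, b) {
    hit <- (comparisons$genotype_a == a & comparisons$genotype_b == b) |
      (comparisons$genotype_a == b & comparisons$genotype_b == a)
    comparisons$adj_p[hit]
  }
  runs <- list()
  for (i in seq_len(G)) {
    j <- i
    while (j < G && all(vapply(i:j, function(k) p_of(g_sorted[k], g_sorted[j + 1]) > alpha,
                               logical(1)))) {
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- i:j
  }
  # keep only maximal runs
  keep <- vapply(seq_along(runs), function(k) {
    !any(vapply(seq_along(runs), function(m) {
      m != k && all(runs[[k]] %in% runs[[m]])
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letters_out <- stats::setNames(rep("", G), g_sorted)
  for (k in seq_along(runs)) {
    lab <- letters[(k - 1) %% 26 + 1]
    for (i in runs[[k]]) {
      letters_out[i] <- paste0(letters_out[i], lab)
    }
  }
  letters_out[geno]
}

#' Write the comparison report
#'
#' Effect table, pairwise table and normality result as CSVs.
#'
#' @param anova_fit A `feeding_anova`.
#' @param tukey A `tukey_comparisons` (optional).
#' @param normality A [test_normality()] result (optional).
#' @param dir Output directory.
#' @export
write_comparison_report <- function(anova_fit, tukey = NULL, normality = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(anova_fit$effects, file.path(dir, "effects.csv"), row.names = FALSE)
  if (!is.null(tukey)) {
    pw <- tukey$comparisons
    pw$letters_a <- tukey$letters[pw$genotype_a]
    pw$letters_b <- tukey$letters[pw$genotype_b]
    utils::write.csv(pw, file.path(dir, "pairwise.csv"), row.names = FALSE)
  }
  if (!is.null(normality)) {
    utils::write.csv(tibble::tibble(W = normality$W, p_value = normality$p_value,
                                    n = normality$n, pass = normality$pass),
                     file.path(dir, "normality.csv"), row.names = FALSE)
  }
  invisible(dir)
}
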