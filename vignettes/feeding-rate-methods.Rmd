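---
title: "Estimating feeding rates from 96-well plate fluorometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating feeding rates from 96-well plate fluorometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazekit)
```

## The assay and its model

Small aquatic grazers — *Daphnia*, snails, tadpole larvae — feed by sweeping a
volume of medium clear of suspended algae. The assay grazekit supports places
one animal in a tube of volume $V$ (default 10 mL) containing algal food for a
duration $t$ (default 7 hr), then reads the chlorophyll-*a* fluorescence of the
remaining medium on a black 96-well microplate, two wells ("technical
replicates") per animal. Tubes with algae but no animal — consumer-free
controls — ride along on every plate.

If the animal clears medium at rate $f$ (mL hr$^{-1}$), algal biomass $W$, and
hence fluorescence $F$ (fluorescence is linear in biomass, $F = lW$, checked
against a standard curve), declines exponentially:

$$\frac{dF}{dt} = -\frac{f}{V}F
\quad\Longrightarrow\quad
F(t) = F(0)\,e^{-f t / V}
\quad\Longrightarrow\quad
f = \frac{V}{t}\,\ln\frac{F(0)}{F(t)}.$$

$F(t)$ is the mean of the animal's technical-replicate wells; $F(0)$ is the
mean of the consumer-free control wells **on the same plate**. That pairing is
the load-bearing design choice: modern fluorometers drift between reads, and
gain or plate-level effects act multiplicatively on the signal. Because $f$
depends on fluorescence only through the within-plate ratio $F(0)/F(t)$, any
multiplicative plate effect cancels exactly. The package never averages
controls across plates, and refuses to estimate a sample whose wells span more
than one plate (the pairing would be undefined).

Because the estimator uses only ratios, the standard curve is diagnostic: it
certifies linearity (`fit_standard_curve()`, `check_linearity()`) and converts
to biomass units on request (`fluorescence_to_biomass()`), but calibration
error never enters the rates themselves.

### Controls read at assay end

The consumer-free controls are collected and read alongside the samples at the
end of the assay, and their end-of-assay read stands in for $F(0)$. Reading
controls and samples in the same session makes common-mode drift between
plating and reading cancel; if controls were instead read at assay start, any
between-read drift would enter every estimate on the plate. The well table
carries plate and role metadata, so a user whose protocol reads controls at
$t_0$ can still analyse their data — the package does not guess which protocol
produced a file.

## Quality control

Three exclusion rules are applied by `apply_qc()` (inside `estimate_all()`),
mirroring standard practice for this assay:

* **negative rates** ($F(t) > F(0)$): a clearance rate cannot be negative, so
  these indicate technical errors (a spurious fluorescence spike, a mis-pipetted
  well). They are excluded, never truncated to zero.
* **deaths** during the assay, and
* **males** identified after the fact (feeding differs systematically by sex).

Every exclusion is logged with its sample id and reason; nothing is dropped
silently, and `keep_all = TRUE` is an explicit override that keeps flagged
animals (still flagged). A high technical-replicate CV (default threshold
0.15) flags a sample for inspection but does not exclude it — disagreement
between duplicate wells of the same medium signals pipetting or read trouble,
not a property of the animal.

## Uncertainty

The assay reports a point rate per animal; within-animal uncertainty comes
from a percentile bootstrap (`bootstrap_ci()`): control wells and the sample's
technical-replicate wells are resampled with replacement, independently, and
the rate is recomputed per resample ($B = 2000$ by default, seeded). This is
the simplest defensible interval for a log ratio-of-means statistic.

Its known limitation should be understood: with only two technical replicates
the bootstrap plug-in variance of the replicate mean has expectation
$\sigma^2/4$ against a true sampling variance of $\sigma^2/2$ (and $5/6$ of
the control part at six controls), so intervals run narrow — roughly
$1.5\sigma$ instead of $1.96\sigma$ half-widths — and cover the true rate in
roughly 70–85% of cases rather than 95% in our simulations. This is the
classic small-$n$ percentile-bootstrap undercoverage; it is a property of the
assay's replicate structure, not of the implementation, and it is why
between-animal inference (below) never uses these intervals. They are reported
for triage — flagging animals whose duplicate wells disagree — not for formal
coverage.

## Inference across genotypes and blocks

Assays large enough to compare genotypes run in temporal blocks.
`fit_blocked_anova()` fits $f \sim \text{genotype} \times \text{block}$ by
least squares and reports marginal (Type III) tests, which remain meaningful
under the unbalanced group sizes QC leaves behind. Type III tests are only
valid under sum-to-zero contrasts, so those are forced internally and user
contrasts are not honoured; the genotype test is invariant to factor-level
ordering, which the test suite asserts by permutation. Each term is reported
both as an $F$ statistic and as a Wald chi-square ($\chi^2 = F \cdot
\text{df}$), since both conventions circulate for this design. Residual
normality is checked with Shapiro–Wilk (`test_normality()`).

When the genotype-by-block interaction is not significant (threshold 0.05,
overridable), `drop_interaction_and_refit()` refits main effects so genotype
means are averaged across blocks — the standard reporting path for a nested
design; it refuses to average over a significant interaction unless forced.

All-pairs genotype comparisons use the Tukey–Kramer procedure
(`tukey_genotype()`): block-adjusted genotype means, simultaneous confidence
intervals and adjusted p-values from the studentized range distribution, which
handles unequal group sizes. We chose the studentized-range construction over
the single-step multivariate-$t$ generalization because it is exactly
reproducible from standard special functions; for designs like this one the
two agree closely (the suite cross-checks against `multcomp` to within 0.02 in
adjusted p), and on balanced one-way designs our implementation matches
`TukeyHSD` to $10^{-10}$. A compact letter display is derived for plotting.

## The stressor extension

To measure feeding in the presence of a fluorescent contaminant or pathogen,
the controls change, not the estimator: animal-free tubes that *contain* the
stressor replace the pure-algae controls (`estimate_with_stressor()`), so the
stressor's background fluorescence is common to $F(0)$ and $F(t)$. The module
assumes the background is additive and common to all tubes on a plate; an
additive offset distorts the ratio slightly, and enabling blank subtraction
(`blank_subtract = TRUE`, default off — plain assays do not blank-correct)
removes it exactly when blank wells measuring the background are present.

Clearance rates convert to exposure quantities: encounter rate $E = fZ$ for
ambient particle concentration $Z$ (`exposure_rate()`), and cumulative dose
over the assay (`cumulative_dose()`) under either a constant-concentration
model ($D = fZ_0t$, for continuously replenished particles) or — the default,
consistent with the assay's own depletion model — a depleting-particle model
$D = Z_0V(1 - e^{-ft/V})$, bounded by the $Z_0V$ particles present. The
depleting dose is always below the constant-$Z$ dose and saturates as
$t \to \infty$.

## The synthetic assay generator

`simulate_assay()` exists so every stage above is testable with known truth.
Its forward model is the assay model run forwards: a sample well reads
$F_0\,e^{-f t/V}\cdot u_p\cdot(1 + \mathrm{cv}\,\varepsilon)$ and a control
well $F_0\cdot u_p\cdot(1 + \mathrm{cv}\,\varepsilon)$, with $\varepsilon$
standard normal and $u_p$ a lognormal plate factor. Noise is multiplicative
because fluorometer noise scales with signal, and plate effects are scale
effects — the regime the matched-pairs design is built for. Artifacts are
injected at set rates: deaths and males set metadata flags, and "spurious
spikes" multiply one sample well far above $F(0)$ to induce a negative rate,
the signature the QC rules look for.

Defaults mirror the study design the package was validated against, chosen
once:

| parameter | default | why |
|---|---|---|
| genotypes × animals | 7 × 30 | the design scale of the motivating study |
| technical reps | 2 | standard duplicate wells |
| controls per plate | 6 | 45 samples × 2 wells + 6 controls fills a 96-well plate exactly |
| blocks | 2 | temporal blocks, animals assigned round-robin |
| $V$, $t$ | 10 mL, 7 hr | protocol constants |
| $F_0$ | 1000 RFU | mid-range for gain 112–120 |
| well CV | 5% | plausible read-to-read scatter for a plate fluorometer |
| plate-effect sd | 0.1 (log scale) | ±10% plate-to-plate scale drift |
| true $f$ | 0.6–1.2 mL hr$^{-1}$ | typical *Daphnia* clearance range |

Tube-to-plate assignment is randomized within block. This matters twice over:
it keeps any genotype from being confounded with a plate (the plate-shared
control-mean error, about $(V/t)\,\mathrm{cv}/\sqrt{6} \approx 0.03$ mL
hr$^{-1}$, would otherwise land wholesale on one genotype's mean), and it is
the assumption under which the ANOVA's error rate is calibrated — with
deterministic balanced placement the genotype test becomes conservative,
because plate noise inflates the residual while cancelling from genotype
contrasts.

What the generator does **not** emulate: algal growth during the assay (the
protocol runs dark), chlorophyll:carbon drift, temperature effects, well
position (edge) effects, and between-animal variation in true rate within a
genotype — measurement noise is the only within-genotype variance. Passing
recovery tests therefore certify the estimator and inference chain, not the
biology of any particular lab's animals; the noise CV in particular is a
placeholder the user should calibrate to their own instrument.

`recovery_report()` scores estimates against truth (per-genotype bias, RMSE,
CI coverage), and `error_rate_experiment()` wraps the whole
simulate–estimate–test chain to measure the genotype test's rejection rate
under a null or alternative. At the default design, 1000 null simulations put
the type-I error within the exact binomial band around the nominal 0.05.

## Numerical choices and degenerate inputs

* Rates are computed and stored in mL hr$^{-1}$ ind$^{-1}$; conversion
  (1 mL hr$^{-1}$ = 0.024 L day$^{-1}$) happens only at output.
* A perfectly fitting model (zero residual variance, e.g. noiseless synthetic
  data) breaks the standard Type III machinery; the package substitutes a
  Wald construction in which a zero-SS term reports statistic 0 and a
  non-zero-SS term reports infinity, and Tukey comparisons snap differences
  below $10^{-10}\times$ scale to exactly zero so degenerate intervals behave
  ($[0,0]$, adjusted p of 1).
* A plate with a single control well is allowed with a warning (its sd is
  undefined); a plate with none is a hard error.
* `parse_plate_grid()` and `parse_long_table()` fail loudly, naming the plate
  and well of the first offending cell; nothing is coerced silently.
* Bootstrap resampling and simulation draw all randomness from explicit
  seeds; identical seeds give byte-identical simulated files.
* The linearity threshold for standard curves defaults to $R^2 \ge 0.95$
  (inclusive), configurable — "strong linearity" is a judgement the user
  should make against their own instrument.

## Problem sizes used in validation

The packaged checks run the oracle comparison at 1000 random parameter draws
(closed form vs ODE integration with root-finding, agreement to $10^{-8}$
relative), parameter recovery at the full 7 × 30 design with $B = 1000$
bootstrap resamples, and 1000-replicate Monte-Carlo experiments for the
type-I error and the Tukey family-wise coverage. These sizes give Monte-Carlo
bands tight enough to be informative (±1.4 percentage points on a 5% rate)
while keeping a full validation run to a few minutes.
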