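---
title: "Deriving serum-plasma transformation factors for Olink NPX data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving serum-plasma transformation factors for Olink NPX data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxfactors)
```

## The problem

Olink's proximity extension assay reports protein abundance as NPX, a
relative log2 unit. Serum and plasma from the same blood draw give
systematically different NPX values for many proteins, because coagulation
consumes or releases proteins and anticoagulants alter the matrix. Studies
therefore avoid mixing media, which strands large banked datasets. When
matched serum and plasma aliquots from the same subjects are available, the
relationship can be estimated per protein and used to convert one medium's
values onto the other's scale.

## Model and assumptions

For protein $p$ with matched measurements $(s_{ip}, y_{ip})$ on subjects
$i = 1 \dots n$, we fit ordinary least squares

$$ y_{ip} = \beta_{0p} + \beta_{1p}\, s_{ip} + \varepsilon_{ip}, \qquad
   \varepsilon_{ip} \sim N(0, \sigma_p^2), $$

with plasma as the response and serum as the predictor, so $\beta_{1p}$
converts serum NPX to the plasma scale. The orientation is a modelling
choice (either direction is defensible); to convert the other way a catalog
can be built from the swapped matrices, and `apply_transform()` checks the
matrix medium against the catalog's direction so the two cannot be mixed up
silently. Key assumptions:

- the serum-plasma relationship is linear on the NPX (log2) scale;
- residuals are homoscedastic within a protein; the slope's confidence
  interval uses the classical $t$ quantile with $n-2$ degrees of freedom;
- the intercept absorbs cohort-specific offsets and is deliberately **not**
  applied during conversion — only the slope is portable across cohorts.

Because NPX is log2-scale, multiplying NPX by a slope corresponds to a
power-law relation between the linear-scale concentrations. No linear-scale
mode is offered; all arithmetic stays in NPX units.

## The tier scheme

A handful of aberrant samples (hemolysis, a mislabelled aliquot, an assay
failure) can destroy an otherwise clean linear relationship. Instead of
robust regression, the method uses an interpretable fallback driven by
Cook's distance

$$ D_i = \frac{e_i^2}{2 s^2} \cdot \frac{h_{ii}}{(1-h_{ii})^2}, $$

the influence of observation $i$ on the fitted line ($e_i$ residual,
$h_{ii}$ leverage, $s^2 = \mathrm{SSE}/(n-2)$, 2 estimated parameters):

1. **Tier 1**: fit all complete pairs; accept if $R^2 \ge 0.5$.
2. **Tier 2**: remove the $\lceil 0.10\,n \rceil$ samples with the largest
   Tier-1 Cook's distances, refit, accept if $R^2 \ge 0.5$.
3. **Tier 3**: remove the $\lceil 0.15\,n \rceil$ top-ranked samples (a
   superset of the Tier-2 removals, still ranked by the Tier-1 fit), refit,
   accept if $R^2 \ge 0.5$; otherwise the protein is non-modelable.

Choices worth stating explicitly:

- **Removal counts** default to fractions of $n$ (2 and 3 samples at
  $n = 19$); a fixed-count mode (`tier_scheme(removal = "fixed")`) always
  removes 2 and 3, which matters for larger cohorts where the two readings
  diverge (at $n = 40$ the fraction mode removes 4 and 6).
- **Ranking basis**: all removals are ranked by the Tier-1 fit, so the tier
  sets are nested and deterministic. `ranking_basis = "per_tier"` instead
  re-ranks the Tier-3 additions on the Tier-2 fit; with influential points
  masking one another the two modes can disagree.
- **Ties** in Cook's distance are broken by input order, so results are
  bit-reproducible.
- The Pearson screen ($r \ge 0.5$, signed — anticorrelated proteins fail)
  describes how much of the panel behaves linearly but never decides which
  proteins are fitted: every protein runs through the tiers.
- Missing values are handled pairwise per protein; a protein's $n$ is its
  complete-pair count, and the scheme requires $n \ge 3 + k_3$.
- A zero-variance predictor makes the slope unidentifiable (degenerate,
  non-modelable); a zero-variance response returns slope 0 with $R^2$
  defined as 0 and a degeneracy flag.

## Gating and the sensitivity rationale

A modelable slope enters the catalog only if its 95% confidence half-width
$t_{0.975, n-2} \cdot \mathrm{SE}(\hat\beta_1)$ is at most 0.3 (inclusive).
The tolerance is justified empirically by the sensitivity module: scale all
proteins in a two-group study by a factor $c$, re-run the differential
expression analysis, and compare calls against the unscaled analysis.
Because every value of a protein is scaled, the $t$ statistic is unchanged
and only the effect gate moves: a protein with estimated effect $\hat e$ is
retained iff $|c\,\hat e|$ still clears the 1-NPX fold-change gate. Findings
therefore erode smoothly as $|c - 1|$ grows, and a half-width of 0.3 bounds
the plausible mis-scaling.

DEA choices: Welch's $t$-test by default (`test = "wilcoxon"` for the
rank-sum alternative), Benjamini-Hochberg adjustment across all scored
proteins, significance = adjusted $p \le 0.05$ **and** $|\Delta\mathrm{NPX}|
\ge 1$ (NPX is log2, so 1 unit is a 2-fold change). Both boundaries are
inclusive. A protein significant in both analyses but with a flipped sign
counts as both a false positive (the modified call is spurious) and a false
negative (the original finding is not retained), keeping retention =
TP/(TP+FN) well defined; retention is NA when the original analysis found
nothing.

## Cross-cohort validation and the final catalog

`refit_cohort()` re-runs the tier scheme on exactly the catalog proteins an
independent cohort measures; `slope_concordance()` calls a protein
concordant when both cohorts model it and $|\Delta \hat\beta_1| \le 0.3$
(inclusive; the accepted tier's slope is used on both sides). Proteins
modelable in only one cohort are reported with the other side's per-medium
variances, since low within-cohort variance is the usual reason a protein
fails to refit — a homogeneous cohort gives the regression nothing to work
with. `select_best_factor()` resolves proteins catalogued in several cohorts
by the highest $R^2$, ties going to the larger $n$ and then to the earlier
listed cohort; `run_pipeline_workflow()` chains fit, gate, concordance and
selection, keeping only proteins gated in at least two cohorts and not
discordant in any pair.

## What the synthetic generator emulates

`sim_config()` defaults define the package's reference study conditions,
chosen to mirror a small matched-aliquot discovery cohort:

| parameter | default | rationale |
|---|---|---|
| subjects | 19 | a realistic matched-aliquot cohort size |
| proteins | 200 | panel-scale without slowing tests |
| true slopes | U[0.6, 1.3] | the bulk of observed serum-plasma slopes |
| serum means | U[2, 10] NPX | typical mid-dynamic-range abundances |
| serum SD | 75%: U[0.8, 2.0]; 25%: U[0.03, 0.15] | heterogeneous biology plus a near-zero-variance stratum that should fail modelling |
| residual SD | U[0.2, 1.5] NPX | spans clearly modelable to hopeless fits |
| outliers | 10% of proteins, 2 samples, ±8 NPX | gross single-sample failures |

Plasma is generated as intercept + slope × serum + Gaussian noise on the
NPX scale (NPX is roughly log-normal on the linear scale, so Gaussian log2
residuals are the natural choice). Outliers displace the plasma response,
which is what Cook's distance on the plasma-on-serum regression detects.
`gen_paired_cohorts()` shares one truth between two cohorts of sizes $n$ and
$n_2$ with independent noise; `gen_two_group_study()` spikes a known subset
of proteins by ±1.2 NPX against within-group SD 0.3 at 20 per group, putting
true effects comfortably past the fold-change gate.

The generator does **not** emulate plate/batch effects, limit-of-detection
censoring, panel bridging artifacts, shared-subject correlation across
proteins, or heteroscedastic residuals. Passing tests therefore demonstrate
the correctness and calibration of the estimator and gates under clean
conditions, not robustness to those real-data phenomena; with real Olink
exports, QC-warned rows are kept but flagged (`attr(x, "qc_flags")`) and
any filtering is the analyst's decision.

## Numerical choices and test problem sizes

- Cook's distances are computed from the closed form above; the suite
  verifies equality with brute-force leave-one-out refits (200 random
  instances, $n \le 25$, agreement relative to each instance's largest
  distance) and with the reference implementation in `stats`.
- An exact fit leaves residuals of order $10^{-16}$; fits with
  $\mathrm{SSE}/\mathrm{SS}_{tot} < 10^{-20}$ are treated as perfect (all
  distances zero) so rounding noise is never ranked as influence.
- CI calibration is checked by simulation: 2,000 proteins at $n = 19$ with
  noise set for expected $R^2 = 0.8$; observed coverage of the 95% interval
  is required to fall in 95% ± 3%.
- Tier exclusivity is re-verified by recomputation on a 1,000-protein
  cohort; concordance simulations use 150 proteins at $n = 19$ vs
  $n_2 = 40$. These sizes keep the whole suite under a minute while leaving
  Monte-Carlo margins wide.
- Factor catalogs round-trip through TSV at full `write_tsv()` precision.

## Known limitations

- **Leverage masquerade**: two gross outliers landing together at one
  extreme of the serum range can imitate a steeper slope, leaving Tier-1
  $R^2$ above threshold with a biased slope — the tier fallback never
  triggers because the fit looks adequate. Simulation puts this at roughly
  8% of random two-outlier placements regardless of displacement magnitude.
  It is intrinsic to any scheme that arbitrates on $R^2$ alone; inspecting
  `plot_variance_diagnostics()` and the per-protein Cook's distances is the
  practical defence.
- Slopes are estimated by unweighted OLS; errors-in-variables (serum is
  also measured with noise) attenuate slopes toward zero, and no correction
  is applied — consistent with treating the slope as an empirical
  conversion, not a biological constant.
- The concordance rule $|\Delta| \le 0.3$ is an absolute criterion: it is
  conservative for slopes near zero and lenient for large slopes.
- Catalogued factors transfer only as far as the cohorts they were fitted
  and validated in resemble the target data; batch effects between datasets
  still require bridging samples after transformation.
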