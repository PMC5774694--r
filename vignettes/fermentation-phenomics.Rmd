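---
title: "Methods: from vial weighings to strain robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from vial weighings to strain robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermphen)
```

`fermphen` analyzes small-vial wine fermentations tracked by weight loss.
This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical decisions, what the synthetic
generator does and does not emulate, and the known limitations.

## Must chemistry

Two closed-form quantities anchor everything downstream.

**Theoretical CO2 maximum.** Complete fermentation of hexose releases CO2
in fixed stoichiometric proportion; we use `tCO2max = 0.482 · [sugar]`
with sugar in g/L. All kinetic thresholds are fractions of `tCO2max`, so
it is always computed from the must composition, never estimated from the
observed curve — a stuck fermentation must be visible as a curve that
fails to reach its must's ceiling.

**Molecular SO2.** Only the undissociated (molecular) fraction of free SO2
is antimicrobial. Full sulfite speciation involves two equilibria plus
temperature and ethanol corrections; over the narrow range of wine musts
(pH 3.2–3.6, 24 °C, trace ethanol) a single Henderson–Hasselbalch form
with one *effective* constant absorbs all of that:

$$\mathrm{SO_2^{mol}} = \frac{\mathrm{SO_2^{free}}}{1 + 10^{\,pH - pK_a^{eff}}}.$$

`pka_eff = 1.86` is the least-squares calibration of this one-parameter
model against the five laboratory-reported active-SO2 values of the
packaged must panel (`inst/extdata/grape_musts.csv`); it reproduces them
within about 0.01 mg/L, and the remaining residuals are the footprint of
the corrections the single-pKa form folds in. Values are reported at the
laboratory's 2-decimal precision (`digits = 2`; pass `NULL` to disable).

## Kinetics

A vial's cumulative CO2 release is
`co2(t) = (weight(t0) − weight(t)) / volume_L` (g/L). The series starts at
0 by construction: nothing is known about CO2 released before the first
weighing, so the lag phase is measured on the same clock as the weighings
(inoculation at `t = 0`, first weighing at or after it).

**Smoothing.** `smooth_co2()` fits a loess smoother — locally weighted
quadratic regression with tricube weights — and evaluates it on a regular
grid over `[0, last observation]`. Parameters:

| parameter | default | meaning |
|---|---|---|
| `span` | 0.45 | fraction of points per local neighbourhood |
| `grid_step` | 0.1 h | evaluation grid resolution |
| `lag_threshold` | 2 g/L | CO2 level defining the lag phase |

The default span matches routine practice for 2–3 weighings/day over a
2–3 week fermentation (roughly 30–50 points). Numerical decisions worth
knowing:

* the local quadratic needs at least 5 points per neighbourhood to be
  well-conditioned, so the effective span is floored at `5/n`;
* the evaluated curve is clipped at 0 and monotonized by running maximum
  before any threshold is read — balance drift can make the raw fit dip
  locally, while cumulative release cannot decrease;
* left of the first observation the curve is extended flat at the fitted
  value rather than extrapolating the polynomial backwards, which keeps
  parameter extraction equivariant under time shifts of the record;
* threshold crossings are linearly interpolated between grid points, so
  extraction error on an exactly known curve is below `2 · grid_step`.

With a *fixed* span fraction, the smoothing window scales with the number
of observations: at very dense sampling (10+ weighings/day) the default
window covers a large part of the curve and introduces bias of order
0.5–1 h in threshold times. When smoothing dense data, scale the span
down so the window stays comparable (the package's own dense-sampling
tests use `span = 0.2` at 12 weighings/day). At the routine density the
default is appropriate, and the residual bias is well below the
replicate-to-replicate spread.

**The six traits.** `lp` (h): first crossing of 2 g/L. `t35`, `t50`,
`t80` (h): crossings of 35/50/80 % of `tCO2max`, minus `lp` — the lag
convention cancels in differences, so
`v50_80 = (0.30 · tCO2max / 0.482)/(t80 − t50) = 0.30·[sugar]/(t80 − t50)`
is an average hexose consumption rate in g/L/h. `co2max` (g/L) is read
from the end of the monotonized smoothed curve, not from the noisy raw
maximum. A curve that never reaches 80 % of `tCO2max` is a stuck
fermentation: the unreached thresholds are `NA` and the fit carries a
`STUCK` flag (`NO_LAG_REACHED` if even 2 g/L is never released).
Completion in the assay sense (< 1.5 g/L residual sugar) is an input from
the sugar assay, not inferred from the curve.

## The experiment simulator

`simulate_experiment()` exists so that every downstream stage can be
tested against known truth. Its generative choices:

* **Curve family:** a delayed logistic — zero until onset, then a logistic
  rescaled to start at exactly 0 and plateau at `co2max`. This is the
  simplest family with the observed lag + sigmoid shape; the analysis
  pipeline never assumes it, and `true_kinetic_params()` inverts it in
  closed form for recovery tests.
* **Sampling:** weighing gaps jittered uniformly ±40 % around
  `24/frequency` h (default 2.5/day), over a horizon reaching 95 % of the
  plateau plus a day's margin; Gaussian balance noise (default sd 2 mg,
  i.e. 0.4 g/L at 5 mL) on every weight.
* **Effect structure:** each trait — the kinetic-generative parameters
  (`onset`, `t_infl`, `rate`, `co2max_deficit`) and the end-point
  metabolites — is built additively as grand mean + strain + must +
  micro-oxygenation + strain:must + strain:mox + Gaussian residual, i.e.
  exactly the model the G×E stage estimates. Effects are centered within
  each factor for identifiability. `co2max` is parameterized as a deficit
  below the must's `tCO2max` so stoichiometry holds for any must panel.
* **Defaults** (`default_effect_model()`): the reference factorial is 4
  strains × 2 musts × 2 oxygenation levels × 10 replicates = 160 vials.
  Magnitudes are enological: lag ~6 h, inflection ~48 h, rate ~0.085 /h,
  glycerol 6.5 ± 0.15 g/L with a ~15 % micro-oxygenation increase, acetic
  acid reduced by oxygenation, malic acid dominated by the must.
  Interactions are present but small against main effects.
* **Seeding:** one master seed; per-vial seeds derived deterministically
  from it, so any subset of vials reproduces identically.

What the generator does **not** emulate: diauxic or multi-phase kinetics,
nitrogen-driven rate dynamics, stuck fermentations (unless parameterized
by hand), assay-specific metabolite error structure, outlier weighings, or
ester chemistry. Passing recovery tests therefore demonstrate correctness
of the estimators under clean sigmoidal kinetics with balance noise — not
robustness to every pathology of real screens.

## G×E statistics

`fit_lm1()` reports each term's percentage of the total sum of squares
using sequential (Type I) SS. The designs this model targets are balanced
factorials, where sequential SS are order-invariant and equal the
classical mean decomposition (both asserted against a brute-force cell
mean oracle in the tests); unbalanced input triggers a warning rather
than an error.

Significance is assessed by permutation: response values are permuted
across all vials, all term F statistics are recomputed, and
`p = (1 + #{F* ≥ F}) / (n_perm + 1)`. Implementation note: the design
matrix is fixed under permutation, so all permuted fits reuse one QR
factorization (`qr.qty` on blocks of permuted responses) — this is exact,
not an approximation, and makes 5000 permutations (the default;
`n_perm = 999` is fine for exploration) cheap. A seed is mandatory.
Post-hoc contrasts use Tukey's HSD on the ordinary least-squares fit —
the conventional pairing with permutation omnibus tests — summarized as a
compact letter display built by insert-and-absorb, letters assigned from
the highest group mean. Two-sample questions use the Wilcoxon–Mann–Whitney
test; completely tied samples return p = 1 (no signal) rather than an
error.

Replicate quality control: `cv_table()` computes CV % per strain ×
condition × trait, averages over strains, and sums per-trait averages
into the "cumulated CV" used to compare protocol variants. No
multiple-testing correction is applied anywhere in this stage by design;
percentages and permutation p-values are reported per trait.

## Multivariate phenomics

The must (medium) effect dominates raw phenotypes, so strain-level
questions are asked on the per-must normalized layer
(`normalize_by_must()`: within-must z-scores, sample sd). This
deliberately erases strain×must interactions — which is why robustness is
computed on the *raw* layer instead.

* `correlation_matrix()`: Spearman rho with `cor.test` significance at
  0.95 confidence; constant traits are flagged, not fatal.
* `pca_phenotypes()`: PCA on centered, unit-variance traits; loadings are
  trait–axis correlations (the correlation circle); axis variances are
  the correlation-matrix eigenvalues (asserted against `eigen()` in the
  tests). The natural observation layer for a strain survey is
  per-(strain, must) replicate means — 175 observations for 35 strains ×
  5 musts — since replicate-level PCA mostly re-measures assay noise.
* `strain_dispersion()`: per must and trait class (kinetic vs metabolic),
  the mean pairwise Euclidean distance between strains in standardized
  trait space — a direct measure of how well an environment discriminates
  a panel.
* `rank_clustermap()`: per-trait ascending ranks 1..n (average ranks on
  ties) so every trait weighs equally, then complete-linkage hierarchical
  clustering on Euclidean distances of the rank matrix. Strongly
  correlated traits would double-weight one axis, so pairs above
  `redundancy_rho = 0.8` warn; for kinetics a typical subset is
  `co2max`, `lp`, `v50_80`, which are mutually weakly correlated. Display
  rounding never feeds back into clustering.
* `robustness_analysis()`: per strain × trait, the sample variance of the
  per-must mean values (raw layer). Per trait, the `floor(0.25·n)` most
  variable strains form the fluctuating group — 8 of 35, leaving 27
  robust; the quartile is computed independently per trait, so the strain
  lists differ between traits. `floor` rather than `round` keeps the
  group within the stated quarter (round(8.75) would give 9). Group-mean
  contrasts per must use Tukey letters across must × group cells, with a
  per-must Wilcoxon test alongside; the variance matrix is also returned
  column-scaled for heatmap display. Variance membership uses raw (not
  column-scaled) variances; ties at the quartile boundary are broken by
  first occurrence.

## Pipeline and formats

The interchange dialect is long/tidy CSV (UTF-8, `.` decimal, header row):
weighing logs (`vial_id, strain, must, shaking, volume_mL, replicate,
time_h, weight_g`), must tables matching the packaged
`grape_musts.csv` schema, and vial-level trait tables. Spreadsheet data
should be exported to CSV in these shapes. Hours since inoculation are
the single time convention; volumes are mL in files. `run_pipeline()`
executes kinetics → trait assembly → G×E → phenomics, skipping stages
whose design requirements are unmet (logged), refusing stochastic stages
without a seed, and writing every artifact as CSV plus a run log.
Deterministic stages are bit-reproducible for a fixed config.

## Problem sizes and validation scope

The test suite validates: chemistry against the five-must laboratory
panel; extraction against closed-form logistic inversions
(`2 · grid_step` tolerance) and noisy recovery on a 104-vial simulated
batch (median t50 error ≈ 1 h, median CO2max error ≈ 0.4 g/L at default
noise); permutation type-I error pooled over 200 null traits × 5 terms at
`n_perm = 499` (≈ 0.05); Spearman null rejection over 1000 panels of 35
observations (≈ 0.05); sequential SS against the mean-decomposition
oracle to 1e-9 on 20 random balanced designs; the 8/27 robustness split
and ≥ 95 % detection of a planted strain×must interaction over 100 seeds;
and a full 35-strain × 5-must survey (350 vials) end-to-end, which runs
in a few seconds on one CPU.

## Known limitations

* The single-pKa SO2 model is calibrated for wine-must conditions; do not
  use it far from pH 3–4 or at high ethanol.
* Sequential SS with unbalanced data depend on term order; the package
  warns but does not re-estimate by other SS types.
* The loess span is a fraction of points, not a time window: adjust it
  when the sampling density departs strongly from 2–3/day.
* The quartile split is a ranking device, not a test: membership near the
  boundary is noise-sensitive, which is why group contrasts carry their
  own significance assessment.
* Normalized-layer analyses hide G×E interactions by construction; use
  the raw layer (as the robustness stage does) when interactions are the
  question.
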