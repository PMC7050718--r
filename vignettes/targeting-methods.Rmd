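---
title: "Methods: quantifying the targeting consequences of expanded MUAC-only programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the targeting consequences of expanded MUAC-only programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute malnutrition in children 6–59 months is diagnosed by two anthropometric
indicators that only partially agree: the weight-for-height z-score (WHZ),
which scales the child's weight against the reference median for their height
and sex, and the mid-upper arm circumference (MUAC), an absolute cut-off
applied regardless of body size. Programs following current WHO guidance use
both (plus nutritional oedema, which defines severe disease on its own). A
simplified "expanded MUAC-only" design admits on MUAC < 125 mm or oedema
alone, tiers severity at MUAC 115 mm, and never measures WHZ. `muactarget`
quantifies what that choice does to targeting: which severe (SAM) and
moderate (MAM) cases are missed, down-tiered or followed without knowledge of
their weight-for-height deficit, and how the population receiving
ready-to-use therapeutic food (RUTF) changes.

## WHZ computation

WHZ uses the LMS method: given sex- and height-indexed coefficients
(Box-Cox power $L$, median $M$, coefficient of variation $S$),

$$z = \frac{(W/M)^L - 1}{L\,S}, \qquad
  z = \frac{\log(W/M)}{S} \ \text{when } L = 0 .$$

Coefficients are linearly interpolated in $L$, $M$ and $S$ between adjacent
height grid rows. Reference grids are dense (0.1–0.5 cm), so the
interpolation scheme is second-order; linearity was chosen for transparency
and exact reproducibility. Heights outside the grid are never extrapolated.

Beyond ±3 SD the package applies the *restricted adjustment* used by the
standard WHO computation: with $SD_k = M(1 + L S k)^{1/L}$,

$$z_{\text{adj}} = 3 + \frac{W - SD_{3}}{SD_{3} - SD_{2}} \quad (z > 3),
\qquad
z_{\text{adj}} = -3 + \frac{W - SD_{-3}}{SD_{-2} - SD_{-3}} \quad (z < -3).$$

This replaces the increasingly distribution-sensitive tail of the Box-Cox
scale with a linear extension anchored on the ±2/±3 SD curves. It is
continuous at ±3 and agrees exactly with the raw formula on $[-3, 3]$; both
properties are asserted in the test suite to $10^{-9}$ (round-trip through
`invert_whz()`) and $10^{-5}$ (two-sided continuity at the anchors). The
adjustment is on by default (`restricted = TRUE`) and can be disabled.

`invert_whz()` is the exact inverse (analytic on $[-3,3]$, piecewise-linear
beyond); it exists so the survey simulator can emit weight/height pairs that
reproduce a prescribed WHZ, and it makes the z-score path testable as a
round-trip identity rather than against opaque reference values.

## Cleaning rules

`clean_records()` assigns one exclusion reason per child with fixed
precedence: `missing_field` (age, sex, weight, height or MUAC absent; oedema
too under the default strict policy), then `age_out_of_range`
($6.0 \le \text{age} < 60.0$ months; the upper bound is exclusive, which is
how "6.0–59.99 months" is read here), then `whz_flag` for computed WHZ
outside fixed ±5 z-scores around zero. Nothing is dropped: every input row
is returned with its reason, and the pipeline asserts input = retained +
excluded on every run.

Three deliberate policy choices, each switchable:

- **Flag dialect.** The default is the fixed ±5 band around zero. A
  survey-mean ±3 dialect (as used by SMART-style plausibility checks) is
  available via `flag_dialect = "smart_mean"` but off by default.
- **Missing oedema.** Excluded as a missing field by default (the strict
  reading of "children with missing data ... were excluded");
  `missing_oedema_policy = "assume_no"` treats it as absent oedema.
- **Out-of-grid heights.** The exclusion taxonomy has no dedicated reason for
  a present but un-referenced height, and cleaning must not error on a data
  problem. Such heights (biologically implausible for this age range on any
  full reference grid) are flagged as `whz_flag` with undefined WHZ — the
  one case where a `whz_flag` child carries no z-score.

No measurement-position (recumbent/standing) correction is applied: the
analysis this package implements does not use one, and silent ±0.7 cm shifts
would be invisible to the user.

## Case definitions and the targeting taxonomy

Case booleans follow the WHO cut-offs with half-open intervals exactly as
printed: SAM by MUAC is MUAC < 115 mm or oedema; MAM by MUAC is
115 ≤ MUAC < 125 mm without oedema; SAM by WHZ is WHZ < −3; MAM by WHZ is
−3 ≤ WHZ < −2. A child meeting both a SAM and a MAM criterion counts as SAM
only (`mam_all` requires not-SAM). This precedence is what makes SAM and MAM
disjoint, the six targeting categories a partition of GAM, and the program
case-mix percentages sum to 100 — the accounting the aggregated metrics
require.

Two boundary conventions deserve note because the printed category
definitions are ambiguous at exactly 125 mm (written both as "MUAC > 125"
for the excluded sets and "MUAC < 125" for enrolment): the package
consistently treats MUAC = 125 mm as *not enrolled* (exclusion condition
MUAC ≥ 125), matching the half-open moderate interval. Likewise WHZ exactly
−3 is MAM-range and exactly −2 is not a case. An oedematous child with
WHZ < −3 is `IGNORED_RISK_SAM` regardless of MUAC.

The assignment is verified against a brute-force truth table transcribed
clause by clause from the category definitions, on an exhaustive grid of
~7,000 (WHZ, MUAC, oedema) combinations including all boundary values — the
truth table lives in the test helpers and is intentionally written in a
different style (per-child conditionals) from the vectorized implementation.

## Count-first aggregation and metrics

All pooling sums child counts (per survey → country → region → overall);
proportions and ratios are computed only from summed counts, never averaged
across groups, so each survey contributes in proportion to its caseload.
`reconstruct_counts()` inverts a published summary row (total N × chained
printed percentages) into a fractional count table so that published
aggregates can flow through the identical code path; fractional counts are
accepted there by design, while raw-survey tallies are integers.

Metrics with zero denominators (no SAM cases, no MAM cases, empty program)
are reported as absent (`NA`), never as zero. Reports round percentages to
one decimal and the allocation ratio to two — the precision customary in
survey summary tables — while JSON mirrors keep full precision.

The package ships the regional rows of a published 550-survey compilation
(~400,000 children) and `reconstruct_overall_row()` reproduces that
compilation's overall row from them. Quantities that are single chained
proportions match at printed precision; the RUTF allocation ratio and
program case-mix divide two reconstructed counts, so the one-decimal
rounding of the inputs propagates to about one unit in the ratio's last
printed digit. The acceptance tests encode exactly these tolerances, derived
from the input precision, not from observed differences.

## The survey simulator

Real child-level survey data of this kind are restricted, so the package
includes a generative stand-in (clearly labelled synthetic) built to exercise
every pipeline stage:

- **Design.** Two-stage: equal-size clusters, each with one Gaussian shift
  (SD `cluster_sd`, default 0.2 z) added to both latent means — a shared
  environmental effect that induces within-cluster correlation.
- **Joint deficit model.** (WHZ, latent MUAC deviation) is bivariate normal
  with correlation `rho`. MUAC in mm is a linear model,
  $\beta_0 + \beta_{age}\,\text{age} + \beta_{male}\,\mathbb{1}[\text{male}]
  + \sigma_{MUAC} Z$, floored at 80 mm. The linear age/sex terms are the
  mechanism behind the field-observed demographic pattern: younger children
  and girls have smaller arms, so an absolute MUAC cut-off selects them
  preferentially. MUAC-for-age standards are deliberately not used — the
  policy under study applies absolute cut-offs.
- **Oedema** is Bernoulli and independent of anthropometry (a dependence
  knob would add parameters the available aggregates cannot identify).
- **Missingness** erases each recorded field independently with
  `p_missing`; the simulation-truth WHZ column is never erased.
- **Emission.** With a reference table configured, height follows a fixed
  stylized age–height line (68 + 0.72·age cm, inside the synthetic grid for
  all ages 6–60 months) and weight is `invert_whz(whz, height)`, so cleaning
  recovers the simulated WHZ to $10^{-6}$.

The default preset targets the pooled profile of the published compilation:
SAM ≈ 3.7%, category split ≈ 25/24/15/36, RUTF ratio ≈ 2.45
(`mu_whz = -0.65`, `sigma_whz = 1.18`, `rho = 0.75`,
`muac_beta0 = 129.5` mm, `muac_beta_age = 0.35` mm/month,
`muac_beta_male = 3` mm, `muac_sigma = 11.5` mm, `p_oedema = 0.003`). A
single Gaussian WHZ latent cannot simultaneously hold SAM at 3.7% and MAM as
low as 12.3% with a field-like category split — the published MAM:SAM ratio
of ~3.3 implies a heavier-than-Gaussian lower tail — so the preset settles at
MAM ≈ 13%. The preset is illustrative, not a calibrated estimate of any real
population: the compilation publishes no per-survey joint (WHZ, MUAC)
distribution to fit.

### What passing simulation tests do and do not show

The simulator reproduces the *structural* features the analysis depends on —
partial deficit overlap, age/sex-dependent MUAC, rare oedema, clustering,
missingness — so green tests demonstrate that the pipeline's accounting,
classification and aggregation are correct on data with those features. They
do not validate the preset against any real population: real surveys have
non-Gaussian anthropometry, age heaping, digit preference, unequal cluster
sizes and informative missingness, none of which are modelled.

## The analytic category oracle

For a fixed age and sex (and `p_missing = 0`, `cluster_sd = 0`) the category
probabilities implied by the simulator are exact bivariate-normal rectangle
probabilities: the WHZ thresholds (−3, −2) and the MUAC thresholds (115,
125 mm, mapped to the latent scale through the linear model) cut the plane
into nine cells, routed to categories by the same classification rules and
mixed with the independent oedema probability. Rectangle probabilities come
from `mvtnorm::pmvnorm` (absolute tolerance $10^{-10}$); perfectly
(anti)correlated deficits (|rho| > 0.9999) are handled by collapsing onto one
coordinate, where the rectangle becomes an interval intersection. The oracle
is validated structurally (probabilities sum to 1; universal oedema forces
the two admitted-SAM categories; independence factorizes cells into products
of univariate tails) and then serves as the expected value in Monte-Carlo
parameter-recovery tests: a 50,000-child simulation (age/sex effects
switched off so one oracle covers all children) must match every category
probability within three binomial standard errors after running the *full*
pipeline, weight/height emission and cleaning included.

## Problem sizes and numerical tolerances

The test suite simulates up to 50,000 children per scenario (about 4 s for
the whole suite), sizes at which binomial standard errors separate the
structural effects under test (e.g. monotonicity of exclusion in `rho`
across {0, 0.3, 0.6, 0.9}) from noise while keeping the suite fast.
Round-trip identities are asserted at $10^{-9}$ (analytic inverses),
$10^{-6}$ (simulation emission through cleaning) and $10^{-12}$
(hand-computed closed forms). All randomness flows from explicit seeds fixed
in the tests.

## Known limitations

- The WHO 2006 coefficient files are not bundled; analyses of real data
  require the user-supplied official tables. The synthetic grid is smooth
  and WHO-like but not the standard.
- Only WHZ is computed; height-for-age, weight-for-age and MUAC-for-age are
  out of scope, as are SMART plausibility checks beyond the stated flags.
- Children excluded by the ±5 flag are dropped from **all** tallies,
  including MUAC-based ones — whether the original analytic choice kept them
  for MUAC counts is not determinable from the published aggregates.
- Aggregated proportions carry no confidence intervals; the design effect of
  cluster sampling is simulated but not propagated into variance estimates.
- Published-row reconstruction inherits the printed one-decimal rounding;
  per-country rows with few cases reconstruct less faithfully than the
  pooled row.
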