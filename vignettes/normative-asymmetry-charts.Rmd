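---
title: "Normative lifespan charts of white matter asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative lifespan charts of white matter asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most white matter pathways come in left/right pairs, and many of their
microstructural properties (FA, MD, AD, RD) and macrostructural properties
(volume, mean streamline length) differ systematically between hemispheres.
`wmasym` builds *normative charts* of this asymmetry across the lifespan:
age-resolved centile curves describing the typical population range of the
lateralization index at any age, the way pediatric growth charts describe
height or weight. At the sample sizes where such charts become reliable
(tens of thousands of scans pooled over dozens of cohorts), binary
null-hypothesis testing of "is there asymmetry?" is uninformative — nearly
any asymmetry is significant — so the package is built around estimation of
the full age-specific distribution rather than testing.

# The lateralization index

For a feature measured in both hemispheres, asymmetry is quantified as

$$\mathrm{LI} = \frac{R - L}{R + L},$$

which is bounded in $(-1, 1)$ for positive inputs, zero at perfect symmetry,
positive for rightward dominance, antisymmetric under hemisphere exchange,
and invariant to any global scaling that affects both hemispheres equally
(a property that removes much of the between-scanner variation in absolute
units). `laterality_index()` rejects non-positive or non-finite inputs
rather than clamping them: the index is undefined there, and the features it
is applied to are positive by construction. `build_laterality_table()`
applies the same policy when assembling observation tables, dropping and
counting degenerate rows.

# The normative model

The LI of subject $i$ is modeled as Gaussian with age-varying location and
scale (a GAMLSS-type location-scale model with a normal family):

$$\mathrm{LI}_i \sim N(\mu_i, \sigma_i^2),$$
$$\mu_i = f_\mu(\mathrm{age}_i) + \beta_{\mu,\mathrm{sex}}\,[\mathrm{male}_i] + u_{\mu,c(i)},$$
$$\log \sigma_i = f_\sigma(\mathrm{age}_i) + \beta_{\sigma,\mathrm{sex}}\,[\mathrm{male}_i] + u_{\sigma,c(i)},$$

where $c(i)$ is subject $i$'s study cohort. The log link keeps $\sigma$
positive and lets the spread itself change over life (age-dependent
heteroscedasticity), which is essential: asymmetry variability in infancy
and old age differs markedly from mid-life.

**Age smooths.** $f_\mu$ and $f_\sigma$ are fractional polynomials (FP):
linear combinations of powers of shifted age drawn from
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, at most three terms, with power 0
meaning $\log(a)$ and repeated powers contributing
$a^p \log(a)^{j-1}$ for the $j$-th repeat (the Royston–Altman convention).
This family is small (8 + 36 + 120 = 164 specifications up to order 3),
fully enumerable, and covers monotone growth, peaks, and early-life
saturation shapes well. Because ages start at 0 and FP transforms need a
positive argument, all ages are shifted by `age_offset` (default **1 year**)
before the transforms; the offset is stored in the model and the fitted
curves are invariant to the (age, offset) reparameterization, which is
checked by a test.

**Sex.** One additive indicator per predictor, `male` vs. the `female`
reference (an explicit convention; the coding is documented rather than
assumed). Charts are produced per sex; "population" summaries average the
two sexes with equal weight — for $\mu$ this is exact, for $\sigma$ the two
sex-specific SDs are averaged (a pragmatic convention: the equal-weight
mixture of two normals is not normal, and at the small sex effects typical
here the difference is negligible).

**Cohorts.** Multi-cohort dMRI data carry scanner/protocol offsets. Cohort
enters both predictors as per-cohort offsets with a Gaussian ridge penalty
(variance $\tau^2$ per predictor), the penalized-likelihood equivalent of
the random intercepts used in large normative-chart studies. The penalty
variances are estimated inside the fitting loop by their EM update, whose
fixed point maximizes the Laplace marginal likelihood; a grid search would
optimize the same criterion at several times the cost, which matters inside
a 164-candidate BIC search. When the marginal-likelihood optimum for
$\tau^2$ sits at the zero boundary the EM iteration approaches it only
sublinearly, so after `tau_updates` (default 30) outer iterations the
penalty variances are frozen and the coefficient iteration runs to
convergence; without the freeze, fits with few cohorts and tiny true
offsets would drift for hundreds of iterations without meeting the
tolerance. An unpenalized sum-to-zero fixed-effects fallback
(`cohort = "fixed"`) and a no-cohort mode are provided. Population charts
set the offsets to zero.

# Fitting and model selection

`fit_location_scale()` maximizes the Gaussian log-likelihood by alternating
an exact penalized weighted-least-squares update of the $\mu$-side
coefficients with Fisher-scoring steps (with step halving) on the
$\log\sigma$-side. Convergence requires the log-likelihood change to fall
below `tol` (default 1e-8) *and* the penalized gradient norm to fall below
1e-3 in the internally rescaled basis; non-convergence triggers up to
`n_restarts` jittered restarts and is flagged, never silently returned. FP
basis columns are rescaled to unit root-mean-square internally — $a^3$ spans
six orders of magnitude over a lifespan grid — and coefficients are
transformed back, which is purely a conditioning device with no effect on
the model. On datasets with a single cohort and intercept-only smooths the
fit reproduces the closed-form Gaussian MLEs to 1e-8, and on small general
datasets it matches multi-start `nlminb` log-likelihoods to 1e-6; both are
enforced by tests.

`select_model()` chooses the FP specifications by BIC,
$-2\ell + k\log n$, with $k$ counting every estimated location/scale
coefficient: intercepts, FP terms, sex terms, and cohort offsets (all $C$
per predictor under ridge, $C-1$ under the fixed-effects fallback).
Counting each shrunken offset as a full parameter is a deliberate,
conservative simplification — an effective-degrees-of-freedom count would
be smaller and is noted as an alternative — and since every candidate in a
search carries the same offset structure, the choice shifts all BIC values
equally and does not affect the ranking. The default search is **staged**:
the $\mu$ smooth is selected over all 164 candidates with the $\log\sigma$
smooth held at a linear age term, then the $\sigma$ smooth is selected with
the winning $\mu$ smooth frozen (329 fits); an exhaustive
`strategy = "full_grid"` ($164^2$ fits) exists for small problems. Ties
break toward fewer parameters, then enumeration order. Every candidate's
BIC and convergence flag is recorded in a selection report. FP families
overlap heavily, so recovery is asserted on the fitted median *curve*
(RMSE against truth), never on exact spec identity.

# Charts, prevalence, and lifespan dynamics

Under the normal family the $p$-th centile at age $a$ is
$\mu(a) + \sigma(a)\,z_{p/100}$; `centile_curves()` evaluates the default
levels (2.5, 25, 50, 75, 97.5) on a dense grid — default **500 equally
spaced points** over the fitted age range, beyond which evaluation is
flagged as extrapolation. The 50th curve is exactly $\mu$. The model-based
share of right-lateralized individuals is
$100\,\Phi(\mu(a)/\sigma(a))$ (`prevalence_right()`); an empirical
raw-proportion counterpart (`prevalence_right_empirical()`) exists because
either reading of "percentage of individuals" is defensible — the
model-based version is the default and the one used in snapshot tables.

Lifespan analytics operate on the median curve:

* `median_derivative()` — finite differences (central inside, one-sided at
  the ends).
* `detect_reversals()` — sign changes of the median with
  linearly-interpolated crossing ages; `min_excursion` (default **0**:
  report every sign change) suppresses crossings whose flanking excursions
  both stay below the threshold, a guard against numerical
  micro-oscillation around zero rather than a scientific filter.
* `epoch_slopes()` — the mean first-difference slope of $|\mathrm{median}|$
  within six predefined epochs (early childhood 2–5, childhood 5–12,
  adolescence 12–20, early adulthood 20–40, midlife 40–60, older adulthood
  60–100 years; ages below 2 belong to no epoch). $|\cdot|$ is
  non-differentiable at a crossing; the finite-difference mean is used
  verbatim, so an epoch containing a reversal mixes attenuation and
  rebuilding phases — that mixing is part of the summary's definition, not
  an artifact to be split away.
* `snapshot_summary()` — median LI and % right-lateralized at the epoch
  median ages 3, 9, 17, 30, 50, 80.

Handedness contrasts fit independent models per stratum (right/left;
ambidextrous and unknown excluded, undersized strata skipped with a record)
and summarize separation as Cohen's d at integer ages 1–80,
$d(a) = (\mu_R - \mu_L)/\sqrt{(\sigma_R^2 + \sigma_L^2)/2}$ — the balanced
pooled-SD form, chosen and documented because "pooled variability" admits
several readings. Signed and absolute age-averages are both reported, the
absolute mean being the scale on which handedness effects are judged small.

# The synthetic-data generator

Per-subject consortium data are not redistributable, so every stage is
exercised against `make_cohort_design()` + `trajectory_truth()` +
`simulate_li_observations()` / `simulate_bilateral_measures()`, which
emulate the *structure* of aggregated lifespan data: staggered, overlapping
cohort age windows whose union covers the requested range; uniform ages
within windows; independent sex (default 50% female) and handedness
(default 9.3% left, 1% ambidextrous) assignment; a normal LI whose mean and
log-SD follow known FP trajectories with sex effects and cohort offsets
drawn $N(0, \tau^2)$; and positive bilateral pairs
$R = B(a)(1+\mathrm{LI})$, $L = B(a)(1-\mathrm{LI})$ that reproduce the
drawn LI exactly. Truth specifications must satisfy
$|\mu| + 3\sigma < 1$ over the design range so the untruncated normal fit
remains appropriate; out-of-range draws are redrawn and counted, and a
budget overrun aborts. What the generator does *not* emulate: non-Gaussian
LI shapes, longitudinal repeats, within-cohort age-sex confounding,
scanner drift within cohort, and spatially correlated errors across tracts
and features — so green tests certify the estimation machinery, not the
behavior of the model class on real consortium data.

All randomness flows from one master seed through `derive_seed(seed,
label)`, a counter-based splitting hash, so each stage is independently
reproducible and bit-identical under a fixed seed (the whole pipeline is
byte-deterministic, which a test asserts by hashing outputs).

# Problem sizes used by the tests and scripts

The checks are sized for a single CPU: parameter recovery and centile
coverage use 10 cohorts × 500 subjects (n = 5,000) with the full 164-spec
staged search; the planted-reversal recovery runs the same size end to end;
the handedness null calibration runs 100 replicates of two 2,000-subject
strata over 4 cohorts with a compact candidate family (powers {0, 1},
order ≤ 2), because the stratified subsets in practice are far smaller and
more weakly constrained than the primary models and a 164-candidate search
per stratum per replicate adds nothing to the calibration being checked.
The demonstration workflow under `analysis/` uses 8 cohorts × 500 subjects
and four tract-feature combinations with distinct planted dynamics (stable
leftward, near-symmetric, mid-life reversal, attenuating rightward).

# Numerical choices and edge cases

* `age_offset` default 1 year; recorded per model; reparameterization
  invariance tested.
* Fit tolerance 1e-8 on the log-likelihood, max 200 outer iterations, up to
  10 Fisher-scoring inner steps with halving; $\log\sigma$ clamped to
  $[\log 10^{-8}, \log 10^{3}]$ during iteration to survive wild
  intermediate steps.
* $\tau^2$ floored at 1e-6 and frozen after 30 EM updates (boundary
  handling, above).
* Intercept-only smooths (`fp_spec(numeric(0))`) are valid degenerate
  specifications, used as closed-form oracles and baselines.
* Chart levels must be strictly increasing in (0, 100); centile
  monotonicity across levels is then automatic under $\sigma > 0$ and is
  asserted on every chart test.
* CSV floats are written at 9 significant digits for stable round-trips;
  NPY arrays are float64 little-endian v1.0, one age column plus one column
  per centile level in ascending order, with the layout documented in each
  chart's JSON sidecar rather than assumed.

# Known limitations

The family is fixed to the normal distribution: skewed or heavy-tailed LI
distributions (plausible for ratio indices near boundaries) would need
BCCG/SHASH-type families that are out of scope. Cohort offsets are
compensatory location/scale shifts only; they cannot absorb cohort-specific
age trends. The BIC parameter count treats shrunken offsets as full
parameters (conservative). Epoch slopes and reversal ages are point
summaries without uncertainty bands. The generator's uniform-age,
independent-covariate design is more benign than real consortium
demographics.
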