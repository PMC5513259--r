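---
title: "Deriving ecosystem photosynthetic capacity and linking it to leaf traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving ecosystem photosynthetic capacity and linking it to leaf traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Eddy-covariance towers measure net ecosystem CO~2~ exchange every half
hour; flux partitioning turns it into gross primary productivity (GPP).
These fluxes swing with weather, so they cannot be compared directly
with plant traits that are sampled once per season. The way around this
is an *ecosystem functional property* (EFP): a slowly varying quantity,
standardized for meteorology, extracted from the flux record. `efpcap`
implements one such property — ecosystem photosynthetic capacity — and
the machinery to relate it to community-weighted leaf traits across
sites.

## The model

Within a 5-day moving window, half-hourly GPP is regressed on incoming
radiation `Q` (PAR, or APAR = FAPAR × PAR when canopy structure should
be factored in) with the nonrectangular hyperbola

$$\mathrm{GPP}(Q) \;=\; \frac{\alpha Q + A_{max} -
\sqrt{(\alpha Q + A_{max})^2 - 4\,\theta\,\alpha Q A_{max}}}{2\theta},$$

the smaller root of $\theta\,G^2 - (\alpha Q + A_{max})G + \alpha Q
A_{max} = 0$. Here $\alpha$ is the initial (quantum-yield) slope in
µmol CO~2~ per µmol photons, $A_{max}$ the plateau in µmol CO~2~
m^-2^ s^-1^, and $\theta \in [0,1]$ the curvature. $\theta = 0$ is
evaluated through its analytic limit, the rectangular (Michaelis-Menten)
hyperbola $\alpha Q A_{max}/(\alpha Q + A_{max})$; $\theta = 1$ is the
Blackman limit $\min(\alpha Q, A_{max})$. Both limits are tested, and
the implementation is checked against an independent quadratic-root
oracle.

From every converged window fit, three capacity quantities are derived
(each in a PAR and an APAR variant, six estimators in all):

* `amax` — the fitted plateau;
* `gpp_sat` — GPP at saturating light, Q~sat~ = 2110 µmol m^-2^ s^-1^
  for PAR (the PAR equivalent of Rg = 1000 W m^-2^ under the 2.11
  conversion) and 2000 µmol m^-2^ s^-1^ for APAR;
* `gpp_cum` — the integral of the fitted curve from 0 to Q~sat~,
  by adaptive quadrature (relative tolerance 1e-6), with a composite
  Simpson fallback for near-Blackman fits where the adaptive rule
  reports roundoff. Both paths are oracle-tested against a 10^4^-node
  trapezoid rule.

A day enters the downstream analysis only when the window fit's
R^2^ exceeds 0.6 — this simultaneously screens poor fits and confines
the series to the active growing season.

## Quality control ahead of fitting

* PAR is derived as 2.11 × Rg (µmol J^-1^).
* Only measured (not gap-filled) half-hours with Rg strictly above
  10 W m^-2^ are fitted.
* A site-year is dropped when, over April 1–September 30 (always 183
  calendar days), more than 25% of days have more than 80% of their 48
  half-hours gapped. All three thresholds are read as strict
  inequalities ("more than"), and days with no records at all count
  their missing slots as gaps — the conservative, reproducible reading.
  The day basis is all 183 calendar days, not only days with data.
* Dry-site or disturbance exclusions are an explicit configuration
  list, never inferred from the data.

## FAPAR handling

16-day satellite FAPAR for the tower pixel is gap-filled from
neighbouring pixels whose series have distance correlation strictly
above 0.75 with the central one (the dependence measure is switchable
to Pearson; distance correlation is the default because the same
statistic serves the trait-linking diagnostics, and one shared,
oracle-tested implementation beats two conventions). Donor values pass
through an affine bias correction — central regressed on donor over
their shared dates — because a neighbouring pixel can track phenology
faithfully yet sit at a different FAPAR level; a raw-substitution
switch exists and every filled step records its donor. Gaps that no
donor covers fall back to a deliberately simple filler: the same-slot
climatology across years, then linear interpolation. This fallback is a
documented simplification, not a reimplementation of published
spatiotemporal gap-fillers. The gapless series is smoothed to daily
resolution with a cubic smoothing spline (smoothing parameter by
generalized cross-validation) and clamped to [0, 1]. Annual "maximum"
LAI is the 90th percentile of the year's 16-day retrievals.

## Annual extraction and estimator choice

Daily retained values are summarised per year by the maximum or a
percentile. One percentile convention is used everywhere in the
package: linear interpolation between order statistics at rank
$h = (n-1)p + 1$ (the default convention of `quantile()`, type 7); an
independent sort-and-interpolate oracle backs it in the tests.
Interannual variability is the coefficient of variation, sample
standard deviation (n−1 denominator; the convention is documented
because the upstream definition is silent on it) over the mean of the
annual values. Estimators are compared across sites with at least 5
years of data; the extraction minimising the mean CV is flagged. On
heavy-tailed synthetic daily series the 90th percentile is
systematically less variable between years than the maximum — the
property that motivates preferring it — and the plateau parameter
`amax` is the least robust of the estimators because radiation rarely
reaches it, so small slope changes at high light move it a lot. Both
properties are asserted statistically (over hundreds of seeded
replicates), not per instance.

## Community traits

Species trait tables (N, P, C per dry mass in mg g^-1^, SLA in
mm^2^ mg^-1^ — the only dimensionally consistent reading of
"mm/mg" — and δ^13^C) are aggregated to site level as
community-weighted means, $\mathrm{CWM} = \sum_i a_i x_i$ with relative
abundances $a_i$ summing to one. Missing species values are dropped
with abundance renormalisation; an unweighted species mean is available
to gauge the sensitivity to abundance information. Derived traits:
C/N = C~mass~/N~mass~ (g/g) and per-area nutrient contents
N~area~ = N~mass~/SLA (mg g^-1^ ÷ mm^2^ mg^-1^ = g m^-2^ exactly,
no conversion factor). Provided per-area values take precedence over
derived ones, with a warning when they disagree by more than 5%.

## Linking capacity to traits

Three synchronisation scenarios are compared: multi-year mean capacity
against database traits, multi-year mean against in-situ traits, and
sampling-year capacity against in-situ traits. Each relationship is
summarised by OLS slope and intercept with standard errors, R^2^ and
adjusted R^2^, distance correlation (computed between observations and
fitted values; for a simple regression this equals the trait-capacity
distance correlation by affine invariance), and leave-one-out
cross-validated modeling efficiency
$EF = 1 - \sum(y-\hat y)^2/\sum(y-\bar y)^2$ and
RRMSE = 100·RMSE/mean(y). ANCOVA across scenarios fits
`y ~ x + group + x:group` and reads the sequential F-tests: the
interaction term tests slope homogeneity, the group term intercept
differences adjusted for the covariate. A permutation test checks
whether sampling-year synchronisation genuinely improves the fit: each
site is assigned a uniformly random available year, B times, and the
empirical p-value uses the +1 correction so it is never exactly zero.

Stepwise selection explores transformed predictors: for each base
trait `v` the candidates `v`, `v^2`, `sqrt(v)`, `log(v)` plus all
ordered ratios of base variables (ratios of transforms would make the
candidate set combinatorial; restricting ratios to base variables keeps
it finite). Search is bidirectional from the intercept-only model under
$AIC = n\ln(RSS/n) + 2k$, with $k$ the coefficient count including the
intercept (additive constants dropped — only differences matter), a
term cap of $n/5$, strict-improvement moves, earlier-candidate
tie-breaking and a rank guard against collinear entries. Forward-only
and backward-only modes are available; bidirectional is the default
because the direction is otherwise a silent arbitrary choice.

Two behaviours of this search are worth knowing. First, like any greedy
stepwise (including `step()`), it has no swap move: when two candidates
are nearly collinear — `cn` and `cn^2` over a 3-fold range, say — the
first add can lock in the wrong family member if other signal masks the
difference. The term-recovery experiment in the tests is therefore
designed in the well-conditioned regime: C/N ~ U(15, 45),
P~area~ ~ U(0.05, 0.2) g m^-2^, residual noise 0.02, n = 18, where the
generating C/N + P~area~^2^ model is identified in well over 90% of
seeds. Second, under pure noise the +2 penalty per parameter does not
make the empty model the norm — a single noise predictor clears it with
probability ≈ 0.17 at n = 50 — but selection stays sparse (mean
selected terms below 2 with 10 noise candidates), which the suite
asserts instead of an intercept-only majority.

## The synthetic-data generator

The generator exists so every stage has known ground truth.

* **Radiation**: a sinusoidal daytime arc whose day length
  (12·(1 ± `latitude_proxy`) hours) and amplitude follow the season;
  midsummer noon reaches `rg_max_summer` (default 800 W m^-2^)
  exactly when noise is off. Cloudiness is multiplicative clearness
  noise `exp(-noise_scale·|N(0,1)|)`, bounded in (0, 1]. No solar
  geometry or weather covariates are modelled.
* **Fluxes**: GPP is the nonrectangular hyperbola driven by a
  double-logistic seasonal trajectory of α(t) and A~max~(t)
  (defaults: peak α 0.04, peak A~max~ 28, θ 0.7, season day 120–280,
  steepness 0.15 d^-1^, off-season floor 5%), log-normal year effects
  on the plateau (sd 0.08), plus heteroscedastic Gaussian noise with
  sd = `noise_scale` × modelled flux (Laplace optional) — flux random
  error scales with flux magnitude, which is also why modelled GPP is
  exactly zero at night before and after noise. The default
  `noise_scale` of 0.1 is a free choice on our part; field estimates
  vary by site and instrument. Gaps are a mixture of singletons and
  geometric-length blocks hitting the target fraction exactly.
* **FAPAR**: the central pixel follows the phenology scaled into
  [0.1, 0.9]; correlated neighbours add Gaussian noise, and a
  configurable number of neighbours are independent AR(1) series to
  exercise the donor screen.
* **Traits**: site CWM N% is drawn uniform on [1, 3.2] and true
  capacity follows GPP~sat~ = 15.67 + 7.25·N% + N(0, 3) by default;
  species values are constructed so the abundance-weighted mean
  reproduces the site CWM exactly, P couples to N through a
  configurable N:P ratio, and a perturbed copy of the table emulates a
  trait-database lookup.

One integer seed drives separate sub-streams (radiation, noise, gaps,
FAPAR, traits, year effects), so regeneration is bit-identical and
stages can be regenerated independently.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: additive instrument noise at
night and in winter (our proportional-only noise keeps window R^2^ high
outside the growing season, so the R^2^ > 0.6 screen bites less than it
does on real fluxes), u*-filtering and storage-correction artefacts,
partitioning biases, footprint/pixel mismatch, disturbance and
management history, and temperature or VPD limitation of the light
response (the moving window absorbs those implicitly, as in the field
convention).

## Numerical choices

* Window fits minimise the residual sum of squares with box-constrained
  L-BFGS-B (α ∈ [1e-6, 0.5], A~max~ ∈ [0.1, 100] µmol m^-2^ s^-1^,
  θ ∈ [0, 1]; bounds are wide physical brackets, configurable), an
  analytic gradient, parameter scaling, and five curvature starts
  θ ∈ {0.1, …, 0.9} with α from a low-light slope heuristic and
  A~max~ from the window's 95th GPP percentile. Windows with fewer
  than 20 half-hours (configurable) return `converged = FALSE` rather
  than erroring; the highest radiation seen (`q_max`) is reported as a
  plateau-reliability diagnostic.
* Windows step one day at a time; each half-hour contributes to at most
  five windows.
* Noiseless synthetic windows are recovered to ~1e-5 relative; the
  suite asserts 0.1%.
* Ties, degenerate inputs, and empty sets return flagged missing values
  with reasons rather than exceptions wherever the pipeline must keep
  running (annual extraction, site capacity selection, donor search).

## Problem sizes used by the tests and acceptance script

Unit tests run single windows and small tables. The statistical
assertions use 200 seeded windows (parameter recovery), 200 synthetic
sites × 6 years (CV comparison), 1000 simulations (ANCOVA type-I
calibration), and 100 seeds (stepwise recovery). The end-to-end runs
use 8 sites × 2 years (stage coverage) and 3 sites × 5 years twice
(byte-identical determinism); the acceptance script runs 12 sites × 3
years twice. These sizes are our choices for a desk-scale study; every
contract they exercise is size-independent.

## Known limitations

* The FAPAR fallback filler is climatology + interpolation by design,
  auditable through provenance marks, and will be biased in years with
  anomalous phenology.
* `amax` extrapolates beyond the observed radiation range whenever
  `q_max` < Q~sat~; treat it as unreliable there (the comparison
  machinery exists precisely to prefer `gpp_sat`/`gpp_cum`).
* The ANCOVA group test is the sequential (Type I) F after the
  covariate, which is the standard slope/intercept reading for this
  balanced design but not a Type III analysis.
* Greedy stepwise selection inherits the identifiability limits
  discussed above; its output is a parsimonious description, not a
  causal claim.
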