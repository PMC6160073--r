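---
title: "Size scaling of patch departure: models, descriptors and the synthetic mesocosm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size scaling of patch departure: models, descriptors and the synthetic mesocosm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gudscale)
```

## The scientific problem

Optimal-foraging theory predicts that a forager abandons a resource patch
when its intake rate drops below what is worth its while — classically, the
marginal value of foraging elsewhere, and at the physiological floor, its
own metabolic requirement. Because metabolic rate scales allometrically
with body size, patch departure behaviour should be size-structured:
larger foragers, with higher absolute energy demands, should perceive
resource scarcity sooner, give up earlier (shorter giving-up time, GUT)
and leave more resource behind (higher giving-up density, GUD) than
smaller foragers.

`gudscale` implements the full analysis chain for testing this prediction
in radiotracer mesocosm trials with benthic grazers (three freshwater
gastropod species spanning ~35x in body mass), and an individual-based
synthetic generator of such trials so that every stage of the chain can be
validated end to end, including recovery of known generating parameters.

## Allometric model and equivalence design

Individual metabolic rate is modelled as the power law

$$I = a\,M^{b}, \qquad a = 0.69\ \mathrm{mJ\,day^{-1}\,(mg\ AFDW)^{-b}},\quad b = 0.79,$$

with $M$ the body size in mg ash-free dry weight. The defaults are the
single-power-law reduction of empirical respiration estimates for
surficial motile gastropods at 18 °C; both coefficients are configurable
(`metabolic_model()`), and a tissue energy density of 21.5 J mg$^{-1}$
AFDW is carried for energy/biomass conversions. A cohort of $n$
individuals demands $n\,I(M)$ overall — energy requirements add — so the
demand per unit biomass scales as $M^{b-1}$: with $b<1$, a fixed biomass
of small individuals out-demands the same biomass of large ones
(`theoretical_exponents()` returns the pair $(b,\,b-1)$).

Uncertainty in the mean size propagates to the rate by the first-order
delta method, $\Delta I = a\,b\,M^{b-1}\Delta M$ (`propagate_size_ci()`).
Only size uncertainty is propagated; uncertainty in $(a, b)$ themselves is
not, which is why the design table's rate CIs are narrower than CIs that
fold in respiration-model error.

The design engine (`design_table()`) expands species profiles into three
equivalence classes of cohorts: *numeric* (equal counts), *biomass*
(equal total AFDW) and *energy* (equal summed metabolic rate). Energy-
equivalent counts are computed from **unrounded** model rates,
$n = \mathrm{round}(4\,I(12.88)/I(M))$, which yields 6 *B. tentaculata*
and 66 *E. ventrosa* as energetic matches for four *G. truncatula*;
rounding the per-capita rates first (21/0.31) would distort the count
(68). Two printing conventions coexist in published design tables and both
are exposed: `overall_rate` is the exact product $n\,I(M)$, while
`overall_rate_printed` is $n$ times the rate rounded to two decimals.
Biomass-equivalent abundances are treated as design inputs rather than
recomputed from AFDW quotients, whose rounding basis in field designs is
rarely stated; `equivalent_count()` always reports the raw quotient next
to the rounded count.

## Tracer accounting

Scintillation counts pass through three steps, in order
(`process_charges()`):

1. blank and efficiency correction, $(\mathrm{raw} -
   \mathrm{blank})/\mathrm{eff}$, clamped at zero with a warning (blanks
   legitimately exceed near-background samples, so a negative corrected
   count is data, not an error);
2. decay correction to a common reference time,
   $\mathrm{DPM} \times 2^{t/t_{1/2}}$ with the ³²P half-life
   $t_{1/2} = 14.268$ d by default (configurable; the reference time
   defaults to each series' trial start);
3. conversion to curies at 1 DPM = 4.556 × 10⁻¹³ Ci, reported in nCi.

The inverse map (`charge_to_raw_dpm()`) synthesises realistic raw counter
readings from true charges, so simulated studies can exercise the whole
correction pipeline; the round trip is exact to floating-point precision.

## The four descriptors

Per treatment × series (`compute_descriptors()`):

* **GUT** — mean time on the patch over *leavers only*; individuals still
  present at the 96 h horizon are censored and excluded (the historical
  convention for this assay, not a survival-analysis treatment). A series
  where nobody leaves has an undefined GUT (`NA`) with counts retained.
* **Net accumulation rate** — final body charge over time on patch
  (nCi h⁻¹). Censored individuals demonstrably fed for the whole trial,
  so their denominator is the full horizon.
* **GUD** — mean residual charge of the grazed disks (nCi disk⁻¹).
* **Exploitation** — the *complement* of the grazed/control charge ratio,
  $1 - \bar{g}/\bar{c}$, i.e. the share of the labelled resource removed.
  The complement (rather than the bare ratio) is what behaves as "resource
  exploited"; the raw ratio is returned alongside, and negative values
  (grazed disks hotter than controls, possible under disk heterogeneity)
  are reported with a warning rather than suppressed.

Replication is at the series level: treatment summaries are means of the
four series means with $t$-based CIs on 3 degrees of freedom
(`aggregate_descriptors()`).

Departure times are recorded on the observation grid: checks every 30 min
through a 12 h day and once at the end of each 12 h night, with trials
starting at dawn (`observation_schedule()`, `discretize_departure()`).
Discretisation maps a true time to the next check (idempotent, never
decreasing), so a night-time departure is first noticed at dawn.

## Energy-equivalence interpolation

The energy-equivalence treatment is modelled, not observed: within each
replicate series, each descriptor is linearly interpolated across the
observed abundances to the energy-equivalent count
(`interpolate_descriptor()`, `energy_equivalence_table()`). The
interpolant is the piecewise-linear bracketing segment — the only linear
variant that passes exactly through observed endpoints; a global
least-squares line is available as `method = "global_linear"` for
sensitivity checks. Targets outside the observed abundance range are
linearly extrapolated from the nearest segment with a warning.
Interpolated rows carry `modelled = TRUE`: they are excluded from the
within-species abundance fits, and they are what makes the cross-species
energy-class fit possible at all.

## Scaling fits

Descriptors against size or abundance are fitted as power laws
$Y = aX^{b}$ by OLS on natural-log axes (`fit_power_law()`); the base of
logarithms only shifts intercepts, never exponents. CIs are $t$-based;
Pearson's $r$ with a Fisher-z CI accompanies each fit. Observations are
the series-level means (four per treatment), matching the replication
unit.

Fractional descriptors (exploitation) are linearised with the logit link,
$\log(y/(1-y))$ on $\log x$ (`fit_logit_fraction()`); exact 0/1 values
are nudged into the open interval by a configurable $\varepsilon$
(default 10⁻⁶). Goodness of fit is McFadden's pseudo-R²,
$1 - \ell_{\mathrm{fit}}/\ell_{\mathrm{null}}$, with both log-likelihoods
evaluated in the Bernoulli form
$\sum y\log p + (1-y)\log(1-p)$ at the inverse-logit fitted fractions,
the null model being the intercept-only logit fit. Two consequences of
choosing this definition (documented because the alternative,
quasi-likelihood, is equally defensible): with continuous fractions the
likelihood at $p = y$ is the negative entropy rather than zero, so even a
perfect fit has pseudo-R² < 1; and because the linearised fit is least
squares rather than maximum likelihood, the ratio is clamped below at 0
(an uninformative predictor gives exactly 0).

The treatment effect on residual disk charges is the one-way
fixed-effects $F$ test (`residual_charge_anova()`), with the ungrazed
final-control disks entering as their own group — a 7-treatment study
therefore has $df_{between} = 7$. No multiple-testing correction is
applied anywhere; each descriptor's test is reported raw.

## The synthetic mesocosm

`simulate_trial()` runs discrete-time ($\Delta t = 0.1$ h) dynamics of
$n$ conspecific foragers on a patch of 16 labelled disks:

* each forager ingests label at $c_i M_i^{\gamma} f(R)$ nCi h⁻¹, with
  $f(R) = R/R_0$ the remaining fraction of patch charge (linear
  functional response; a saturating Holling type II is available behind
  `functional_response = "holling2"`). A Holling response breaks the
  analytic simplicity of the conservation ledger, which is why linear is
  the default;
* ingested charge is removed from disks in proportion to their current
  charges, and a fraction `assimilation_efficiency` (0.70) accrues to the
  body — so each trial obeys the conservation identity
  $R_0 = R_{\mathrm{residual}} + \mathrm{bodies}/0.70$ exactly, the
  anchor of the property tests;
* departure follows a noisy quitting-harvest-rate rule: the forager
  abandons the patch once its intake rate falls below
  $q\,I(M_i)\,(1+\epsilon_i)$, a threshold proportional to its own
  metabolic rate. $\epsilon_i$ is a logistic perturbation drawn **once
  per forager** (scale 0.08): drawing fresh noise at every one of the
  ~960 checks would make the earliest of 960 draws decide departure and
  collapse GUT dispersion toward zero threshold exceedance. Because
  intake declines monotonically as the patch drains, the crossing is
  absorbing; after it, departure occurs with hazard 2 h⁻¹ by day and
  0.1 × that at night (gastropods are day-active), and the true time is
  then discretised onto the observation grid;
* individual sizes are drawn from the species' size distribution
  (normal, sd = CI half-width / 1.96, resampled if non-positive) and
  individual ingestion coefficients are lognormal with CV 0.2 —
  physiological heterogeneity without which per-forager rates within a
  trial would be nearly identical.

`generate_study()` runs the 7 observed treatments over 4 series, each
series with its own mean disk charge (lognormal around 31.2 nCi, CV 0.08
between series, CV 0.10 between disks — conditioning heterogeneity) and
its own start-control and final-control disk sets, and is byte-identical
under a fixed seed.

Default rate constants were chosen once so the generator lands in the
empirically realistic regime for this assay — ingestion coefficient
$c = 0.3$ nCi h⁻¹ mg$^{-\gamma}$ and quitting coefficient $q = 0.25$
nCi h⁻¹ per mJ day⁻¹ put per-forager net accumulation near
1.0/0.65/0.08 nCi h⁻¹ for the large/medium/small species, GUTs near one
day for the largest species, essentially no departures of the smallest
species at $n = 4$, and GUT dispersion of a few hours across replicates.
The ingestion exponent default is the theoretical $\gamma = 0.75$. These
are study conditions, not tuning knobs: the property and acceptance
tests run against them as fixed.

What the generator deliberately omits: spatial structure within the
patch, travel time between patches, inter-specific competition, satiation
and diel rhythm beyond the night hazard factor, and any feeding-mode
switching. Passing tests therefore demonstrate that the analysis chain
measures what the generating process encodes — not that real gastropods
obey the quitting rule.

## Parameter recovery and its identifiability design

The recovery probe (`fit_accumulation_scaling()`) fits the cross-species
power law of per-forager net accumulation rate on body size; on synthetic
data its slope estimates $\gamma$. The estimator is only consistent while
the functional response stays near its plateau: a forager's realised rate
is $0.70\,c\,M^{\gamma}\,\overline{f(R)}$ averaged over its stay, and
treatments that drain their patch to different depths contribute
different $\overline{f(R)}$, confounding the size effect (on the default
study the slope comes out near 0.78; on a balanced low-enrichment design,
near 0.69). The calibration design (`recovery_config()`) therefore uses
all three species at the same abundance (6 × 4 series = 24 foragers per
species) on patches enriched 50-fold, keeping $f(R) > 0.95$ throughout;
under it the fitted 95% CI covers 0.75 as it should. This is an
experimental-design choice — identifiability dictates the calibration
conditions — not a modification of the study conditions above, which are
unchanged wherever descriptors and their scalings are examined.

## Numerical choices and degenerate inputs

* $\Delta t = 0.1$ h balances discretisation error in the intake ODE
  against runtime; the observation grid (0.5 h), not $\Delta t$, limits
  recorded-time resolution anyway.
* Ingestion in a step is capped at the charge remaining on the disks
  (relevant only under extreme parameters).
* Negative corrected DPM clamps to 0 with a warning; exploitation may be
  negative and is flagged, not clamped.
* `equivalent_count()` rounds half away from zero via `round()`'s
  banker-free behaviour on the ratios that occur here; the raw ratio is
  always reported so the rounding is auditable.
* Degenerate descriptor inputs fail loudly and by stage name: no grazed
  disks, no final controls, zero time-on-patch, departure at or before
  entry, fewer than two distinct abundances for interpolation, fewer
  than three points or non-positive values for a power-law fit.
* `quitting_coef = 0` disables departures exactly (the threshold and its
  noise both vanish), giving the all-censored limit used in tests.

## Problem sizes

The shipped tests and scripts run the generator at the study's own scale
(7 treatments × 4 series, ~1,020 foragers, 576 disks — about 3 s) and
the calibration study at 72 foragers; the slope-coverage property uses
1,000 replicates of a 20-point fit. These sizes give the property tests
sampling error well below the effects they assert.

## Known limitations

* The delta-method CI understates the design table's rate uncertainty
  whenever respiration-model parameter error matters; published tables
  built on multi-predictor respiration models will show wider CIs than
  size-only propagation can reproduce.
* The logit-linearised fit is not the binomial GLM; its pseudo-R² is a
  descriptive, definition-dependent quantity (see above).
* With $b - \gamma = 0.04$, the quitting rule predicts only weakly
  size-dependent GUT at energy equivalence; the simulator reproduces the
  direction (largest species leaves first) but compresses the spread
  relative to what field data show, where perception and movement
  differences add to the pure energetics.
* Interpolated energy-equivalence values inherit the linearity
  assumption between adjacent abundances; with only two abundances for
  the mid-sized species the "interpolation" there is a two-point line.
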