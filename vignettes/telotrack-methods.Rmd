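---
title: "Methods: qPCR telomere quantification, rank tracking and the association ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR telomere quantification, rank tracking and the association ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotrack)
```

# The problem

Leukocyte telomere length (TL) in children is commonly measured by
quantitative PCR as a T/S ratio: the telomere-repeat signal (T) relative
to a single-copy gene (S). Cohort studies then relate early-life
exposures — here, parent-reported sedentary behaviour (SB) such as screen
time — to TL at a baseline visit and to how a child's TL *tracks*
relative to peers between visits. Two features make the analysis chain
non-trivial:

* qPCR quantities are only relative, drift from plate to plate, and must
  be calibrated before samples measured on different runs can be
  compared;
* when the follow-up assay uses different chemistry (e.g. different
  single-copy-gene primers), absolute baseline and follow-up values are
  not comparable, so longitudinal change has to be expressed through
  within-cohort *ranks* rather than differences of raw values.

`telotrack` implements that chain end to end — relative quantification
with reliability metrics, exposure construction, the rank-tracking
statistic, and a robust-regression association ladder — together with a
synthetic cohort generator with known ground truth, so every stage is
testable without access to any real cohort data.

# Relative quantification (CNRQ)

For each target the amplification efficiency $E$ (fold increase per
cycle) is estimated from a serial dilution of pooled DNA by least squares
of mean Cq on $\log_{10}$ input quantity:

$$E = 10^{-1/\text{slope}}, \qquad \text{efficiency\%} = (E - 1) \times 100.$$

Perfect doubling gives slope $-1/\log_{10} 2 \approx -3.3219$ and 100%.
Replicate wells (triplicates) are aggregated by arithmetic mean; no
replicate is ever rejected automatically, but groups with fewer than two
replicates or a spread above 0.5 cycles (configurable) carry non-blocking
QC flags.

Relative quantities use the delta-Cq form with target-specific
efficiency,

$$\mathrm{RQ} = E^{\,\bar{Cq}_{\text{ref}} - \bar{Cq}},$$

where the reference is the arithmetic mean Cq over all analysed study
samples of that target *within the run and cohort*. Normalising to an
all-sample mean rather than a designated calibrator sample avoids
inflating the error of every quantity with the measurement error of one
calibrator well. Computing the reference per run makes every relative
quantity invariant to additive per-run Cq shifts by construction; the
residual run-to-run differences in composition are then removed by the
inter-run calibrators (IRCs): with $\mathrm{NRQ} = \mathrm{RQ}_T /
\mathrm{RQ}_S$ and eight IRC aliquots re-measured on every run, the
per-run correction factor is

$$\mathrm{CF}_r = \Big(\prod_{i \in \text{IRC}}
  \frac{\mathrm{NRQ}_{ir}}{\widetilde{\mathrm{NRQ}}_{i\cdot}}\Big)^{1/n_\text{IRC}},
  \qquad \mathrm{CNRQ} = \mathrm{NRQ}/\mathrm{CF}_r,$$

where $\widetilde{\mathrm{NRQ}}_{i\cdot}$ is calibrator $i$'s geometric
mean across runs. The geometric mean of the CFs over runs is exactly 1,
and on noise-free input the CNRQ equals the true T/S ratio up to a single
multiplicative constant per cohort — both properties are asserted in the
test suite at numerical precision. An IRC missing from any run is flagged
and excluded so the construction stays balanced. Normalisation never
mixes cohorts; each cohort (and each visit, which is a separate assay
campaign) is quantified independently.

On a single plate with $E = 2$ for both targets the whole chain collapses
to the familiar $2^{-\Delta\Delta Cq}$ quantity taken relative to the
all-sample mean Cq, which the acceptance tests check to $10^{-12}$.

## Reliability

Repeatability is summarised by intraclass correlation coefficients from
one-way random-effects ANOVA (single measurement, absolute agreement):

$$\mathrm{ICC} = \frac{\mathrm{MSB} - \mathrm{MSW}}
  {\mathrm{MSB} + (k - 1)\,\mathrm{MSW}},$$

with F-based confidence limits and p-value, and the usual $k_0$
adjustment for unbalanced groups. Intra-assay ICCs are computed on
replicate-level relative quantities for T, S and the replicate-paired T/S
ratio; the inter-assay ICC treats each IRC as a subject re-measured on
every run (on the CNRQ scale). The one-way model was chosen because the
replicate structure has no crossed rater; negative estimates are reported
as computed rather than truncated, so a failed assay is visible.

# Exposure construction

Parent-reported weekday and weekend hours are combined as
$((\text{wd} \times 5) + (\text{we} \times 2))/7$ for screen time and for
other sedentary activities; total SB is their sum. Each variable is
categorised into tertiles at the empirical 1/3 and 2/3 quantiles
(linear-interpolation sample quantiles, `type = 7`), ties at a cut-point
going to the lower category. Questionnaire hours are coarse (0.1 h
granularity in the generator), so ties are common and tertile groups are
expected to be unequal in size; cut-points and group sizes are therefore
always reported alongside the labels. Because the quantile algorithm and
tie rule move the printed cut-points, both are explicit, fixed choices of
this package rather than hidden defaults. Tertiles are assigned on each
model's own complete-case analysis sample, not once globally, so the
groups always partition the children actually modelled.

# Rank tracking

Within each cohort, TL is ranked from longest (rank 1) to shortest at
both visits among the children measured at both; ties take average ranks.
The tracking statistic is

$$\Delta R = \frac{R_1 - R_2}{n - 1} \times 100,$$

bounded by $\pm 100$, negative when a child declines in the ranking
(relative shortening). With complete paired rankings and average ranks,
$\sum \Delta R = 0$ exactly — tracking is zero-sum by construction — and
$\Delta R$ is invariant to any monotone transform of the underlying
values, which is what makes it usable across assays with different
chemistry. A pooled Spearman correlation between the two rankings is
reported as a tracking QC statistic. An option to rank the baseline on
the full baseline sample (including children later lost to follow-up)
exists but is off by default, because it breaks the zero-mean
conservation property; the default keeps both rankings on the paired
sample.

# The association ladder

Associations are estimated by robust linear regression: M-estimation with
a bisquare (bounded-influence) loss at the usual tuning for ~95% Gaussian
efficiency, iteratively reweighted, with asymptotic Wald standard errors
and normal-approximation confidence intervals (no small-sample df
correction; analysis samples are in the hundreds). With symmetric,
outlier-free errors this agrees with ordinary least squares, and the test
suite checks both that agreement and the resistance to gross outliers.

For baseline TL the outcome is $\log_{10}$ CNRQ and coefficients are
reported as percent change, $(10^\beta - 1) \times 100$; for tracking the
outcome is $\Delta R$ itself, already in percentage points. The covariate
ladder is fixed: M1 adjusts for blood storage time and cohort; M2 adds
daily energy intake, ultra-processed food intake and baseline age; M3
adds sex; M4 (tracking outcome only) adds follow-up time and
$\log_{10}$ baseline TL. Complete cases are used per model with the n
reported on every estimate.

Covariate selection follows a change-in-estimate philosophy: candidates
first pass a bivariate screen against the outcome at p < 0.2
(univariable robust regression; joint Wald test for factors), then a
backward–forward elimination retains exactly those whose presence moves
the high-vs-low exposure coefficient by at least 10% (relative). The
bivariate screen gates entry; the forward pass can re-admit a removed
survivor. Every decision is recorded in an audit trail. Two unstated
details were fixed here deliberately: the screen uses univariable
regression (not correlation), and the 10% change is measured on the
high-tertile coefficient, the contrast the study reports.

Cohort compatibility is assessed by fitting each cohort separately,
pooling with inverse-variance fixed-effect weights, and quantifying
heterogeneity with Cochran's Q and $I^2 = \max(0, (Q - \mathrm{df})/Q)
\times 100$. When $I^2 < 50\%$ the result carries a recommendation flag
to analyse the cohorts jointly with cohort as a covariate — the strategy
the main models implement. Descriptive tables choose mean (SD) with ANOVA
or median (IQR) with Kruskal–Wallis by a Kolmogorov–Smirnov normality
check, and counts (%) with chi-square for categoricals; constant
variables are skipped with a flag. No multiple-testing adjustment is
applied anywhere, matching the reporting convention of this literature.
The sensitivity suite re-fits the main model adding single covariates
(other SB, diet score, BMI, season, extracurricular physical activity), a
maternal block, sex-restricted subsets, a preterm exclusion, and an
exposure-by-sex interaction tested with a joint Wald statistic; variants
whose subgroup falls below the fitting threshold are skipped with a flag,
never silently.

# The synthetic cohort generator

The generator emulates the study conditions this pipeline targets: three
cohorts of 223 children by default (~670 in total) with ~79% follow-up;
baseline T/S ratio lognormal with sdlog 0.25; multiplicative attrition
between visits (median factor 0.9, sdlog 0.35, which puts the
baseline-to-follow-up rank correlation near 0.6, the level reported for
child cohorts); screen and other-SB hours lognormal with medians near
1.2–1.3 h/day, reported to 0.1 h as weekday/weekend questionnaire items;
and a qPCR layer with triplicates, 0.075-cycle replicate noise (chosen so
intra-assay ICCs land near 0.95), 0.5-cycle run shifts, efficiencies 2.07
(T) and 2.0 (S), eight IRC aliquots per assay and a 6-point two-fold
dilution series on every run. Each output table draws from its own RNG
stream derived from the master seed, so adding a table never shifts the
draws of another, and a fixed seed reproduces every table exactly.

Two effects and one confounder are planted:

* **Baseline TL**: the highest screen-time tertile gets a multiplicative
  $(1 + e)$ factor (default $e = -0.04$), the middle tertile half of it.
* **Confounding**: energy and ultra-processed food (UPF) intake are
  generated correlated with screen time, and UPF additionally shortens
  baseline TL linearly on the log scale per 100 g/day. The UPF path is
  deliberately linear in grams so that the ladder's linear adjustment is
  correctly specified and the planted effect is exactly recoverable,
  while an unadjusted model is visibly confounded — the structure the
  covariate-selection procedure is tested against.
* **Tracking**: the literature does not report an SB-attrition effect
  size separately from the ranking analysis, so the generator exposes it
  as a free parameter defined directly on the $\Delta R$ scale. Because complete paired rankings are zero-sum, one *cannot*
  simply shift a group's mean $\Delta R$; instead the high tertile is
  displaced by $d = \text{effect}/100$ in within-cohort quantile space of
  follow-up TL (middle tertile by $d/2$), via an empirical-quantile
  remap. Re-ranking then repacks everyone, and to first order the
  realised position change of child $i$ is $d_i - \bar d$, so the
  high-vs-low regression contrast equals the planted parameter. A
  sub-grid jitter (a fraction of one rank spacing) is added before the
  remap: a displacement that is an exact multiple of the rank grid would
  land children on occupied grid points and tie-averaging would shrink
  the planted contrast by several percent.

What the generator does *not* emulate: raw fluorescence curves or
Cq-calling (Cq values are generated directly from the efficiency model);
informative loss to follow-up (drop-out is independent of exposure and
TL); non-additive run effects (run effects are additive Cq shifts, which
is exactly the structure IRC calibration removes); item non-response in
the questionnaire; and assay chemistry differences beyond what cohort- and
visit-separate normalisation absorbs. Passing tests therefore demonstrate
the *internal* correctness and calibration of the chain under these
idealisations, not robustness to, say, informative missingness.

# Numerical choices and degenerate inputs

* Tertiles require at least three distinct values; all-identical input is
  an error, not a silent one-group factor.
* Efficiency estimation needs three distinct dilution points; the slope
  is fitted on per-point mean Cq, so a balanced dilution design cancels
  run shifts out of the slope.
* The robust fit refuses rank-deficient designs and fits with fewer than
  (coefficients + 10) observations, with a diagnostic; sensitivity
  variants hitting that threshold are flagged as skipped.
* ICC with zero within-subject variance returns exactly 1; zero
  between-subject mean squares yield the computed (possibly negative)
  value.
* The change-in-estimate denominators are guarded at $10^{-8}$ so a
  near-zero exposure coefficient cannot produce infinite relative
  changes.
* Single-run datasets short-circuit the inter-run calibration to
  CF = 1, making CNRQ = NRQ as the definitions require.

# Validation problem sizes

The package's own validation uses: 100 replicate studies of 3 × 500
children (full follow-up) for effect recovery — the mean recovered
high-screen effects are required to sit within two simulation standard
errors of the planted −4% (baseline TL) and −2 points ($\Delta R$), and
the planted UPF confounder must be retained by covariate selection in
every replicate; and 200 replicate null studies of 3 × 200 children for
type-I calibration of the high-vs-low term, with the empirical rejection
rate required to fall in [0.02, 0.08] at the nominal 0.05 level. The
recovery experiment tracks all simulated children (no loss to follow-up)
so both outcomes are estimated on the full 1,500; type-I calibration is
insensitive to the cohort size used under the asymptotics of the Wald
tests. `scripts/acceptance.R` re-runs a smaller version of both
experiments from scratch and writes every quantity it computes as JSON.

# Known limitations

* Measurement error in the baseline-TL adjustment of the tracking model
  (M4) leaves a small residual of the baseline-TL path in the exposure
  contrast — the classical consequence of adjusting for an
  error-containing covariate. At the default noise level this is on the
  order of a tenth of a point of $\Delta R$ and well inside the recovery
  tolerance, but it is a real property of the design, not of the code.
* Percent-change confidence intervals are monotone transforms of Wald
  intervals; no bootstrap alternative is implemented.
* Per-run amplification efficiencies, absolute TL in kilobases,
  imputation of missing covariates and mixed-effects modelling of
  repeated TL are out of scope.

# A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1, n_per_cohort = 223)
st <- run_study(cfg)
tl_assoc(st$analysis, outcome = "tl4", exposure = "screen", model = "M3")
tl_assoc(st$analysis, outcome = "delta_r", exposure = "screen", model = "M4")
rank_correlation(st$analysis$r1, st$analysis$r2)$rho
cohort_heterogeneity(st$analysis, outcome = "tl4", exposure = "screen")
```
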