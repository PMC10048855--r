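# telotrack

Relative telomere length quantification and rank-based telomere tracking
for multi-cohort child studies.

`telotrack` is for biostatisticians and epidemiologists analysing
qPCR-based leukocyte telomere length (TL) in cohort studies where an
exposure — here, sedentary behaviour reported by parents — is related to
TL at a baseline visit and to how a child's TL *tracks* relative to
peers at follow-up. It implements the complete computational chain as
tested, reusable functions:

* **qPCR quantification** — calibrated normalised relative quantities
  (CNRQ): standard-curve efficiency `E = 10^(-1/slope)`, triplicate
  aggregation, delta-Cq relative quantities against the all-sample mean,
  the T/S ratio, inter-run calibrator (IRC) correction factors, and
  one-way random-effects ICC reliability metrics (intra- and
  inter-assay).
* **Exposure construction** — daily sedentary hours from weekday/weekend
  questionnaire items, `((wd × 5) + (we × 2)) / 7`, and tertile
  categorisation with explicit cut-points and tie rules.
* **Rank tracking** — within-cohort descending TL ranks at both visits
  and the tracking statistic `ΔR = ((R1 − R2)/(n − 1)) × 100`
  (negative = decline in ranking), which is invariant to assay-chemistry
  differences between visits because it only uses ranks.
* **Association ladder** — robust (bisquare M-estimation) linear models
  M1–M4 with percent-change reporting `(10^β − 1) × 100` for the
  log10-TL outcome, p < 0.2 + 10% change-in-estimate covariate selection
  with an audit trail, fixed-effect heterogeneity (Cochran Q, I²),
  descriptive tables, and a sensitivity-analysis suite.
* **Synthetic cohorts** — a generator producing three cohorts with known
  planted effects, confounded dietary covariates and raw plate-level Cq
  data (samples, IRCs, dilution series), so the entire chain is testable
  with known ground truth.

See `vignettes/telotrack-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

```r
library(telotrack)
cfg <- sim_config(seed = 1, n_per_cohort = 223)  # the default study size
st  <- run_study(cfg)   # simulate -> quantify plates -> assemble analysis

st$quant$blocks[["cohort_A_y4"]]
#> CNRQ quantification [cohort_A] (age 4): 223 samples, 6 runs
#>   efficiency: T 107.0%, S 99.1%
#>   ICC intra_T = 0.978
#>   ICC intra_S = 0.935
#>   ICC intra_TS = 0.940
#>   ICC inter_assay = 0.978

tl_assoc(st$analysis, outcome = "tl4", exposure = "screen", model = "M3")
#> Association model M3: tl4 ~ screen tertile (n = 669)
#>   tertile cut-points: 1.07, 1.61 h/day; reference = low
#>   middle  -0.704 (95% CI -5.861, +4.736), p = 0.795
#>   high    -3.815 (95% CI -10.040, +2.841), p = 0.255
#>   estimates are % change in TL vs the lowest tertile

tl_assoc(st$analysis, outcome = "delta_r", exposure = "screen", model = "M4")
#> Association model M4: delta_r ~ screen tertile (n = 534)
#>   tertile cut-points: 1.07, 1.61 h/day; reference = low
#>   middle  +0.937 (95% CI -4.492, +6.365), p = 0.735
#>   high    -0.812 (95% CI -7.695, +6.071), p = 0.817
#>   estimates are percentage points of ranking vs the lowest tertile

rank_correlation(st$analysis$r1, st$analysis$r2)$rho
#> [1] 0.60

cohort_heterogeneity(st$analysis, outcome = "tl4", exposure = "screen")
#> Fixed-effect pool: beta = -0.0149 (SE 0.0150); Q = 1.776 on 2 df; I2 = 0.0%
#>   I2 < 50%: pool cohorts with a cohort covariate
```

Reading the output: the generator plants a −4% baseline-TL effect and a
−2-point ΔR effect for the highest screen-time tertile. At this single
study's size (~670 children) the point estimates land near the planted
values (−3.8%, here −0.8 points for the noisier rank outcome) with wide
confidence intervals — a single cohort of this size is underpowered,
which is exactly what the simulation makes visible. The T-target
efficiency (107.0%) and ICCs (0.94–0.98) reflect the generator's assay
model; the Spearman ρ = 0.60 summarises how strongly the TL ranking at
baseline persists at follow-up; I² = 0% says the three cohorts'
estimates are compatible, so they are pooled with cohort as a covariate.

A thin command-line wrapper over the same functions is installed at
`inst/cli/telotrack.R` (subcommands `simulate`, `quantify`, `exposures`,
`track`, `associate`), reading and writing plain CSV/JSON.

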