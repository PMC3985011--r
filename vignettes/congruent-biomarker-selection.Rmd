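---
title: "Congruent biomarker selection for coronary atherogenesis by iterated Bayesian model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Congruent biomarker selection for coronary atherogenesis by iterated Bayesian model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atheroBMA)
```

# The inference problem

Diet-induced swine atherogenesis experiments produce three very different
kinds of measurement on a very small number of animals: a circulating
panel (lipoproteins, cytokines, an adhesion molecule) at baseline and at
the end of the diet period; a mass-spectrometry abundance matrix of
proteins secreted by incubated coronary artery segments; and per-segment
histomorphometry of the coronary tree. Atherosclerotic burden per case is
summarized by four indexes: mean and median intimal thickness (IT, mm,
maximal radial expansion of each lesion) and mean and median lesional
area (LA, mm², circumferential extension). Mean and median carry distinct
information: when lesions are localized in a few segments the median falls
well below the mean, while diffuse disease makes them coincide.

The question is which of the dozens of candidate variables are robustly
associated with burden when only a dozen or so treated cases exist. A
single selected regression model would hide the model uncertainty that
dominates at this sample size; the package instead averages over subset
models and then demands *congruence* of the evidence across the four
outcome indexes.

# Analysis scale

Every dependent and independent variable of the treated (HF, HHF) cases is
divided by the average of the standard-diet CNTL cases and natural-logged:
`x* = ln(x / mean(x over CNTL))`. This controls the wide spread of raw
magnitudes (mm vs mm² vs mg/dL vs arbitrary counts), makes a value equal
to the control average map to 0, and turns multiplicative effects into
additive ones. Two choices deserve emphasis:

* **Log base.** The natural log is used. The base does not affect which
  models are preferred (it rescales y and X jointly), but it rescales
  coefficients — and the congruence filter's magnitude floor (0.001) lives
  on this scale. Changing the base without changing the floor changes the
  filter.
* **Timepoints.** Baseline (BAS) and end-diet (END) plasma measurements
  enter as *separate* candidate variables, each normalized by the CNTL
  mean at its own timepoint. Normalizing BAS by CNTL-BAS (rather than by a
  pooled or END control mean) keeps the pre-diet variables centred at
  zero for all groups; the alternative conventions differ only by a
  per-variable additive constant, which the intercept absorbs, so model
  selection is unaffected — only the displayed variable values shift.

Protein matrices are first rescaled so every case has the same total
protein (the grand mean of the original row totals), compensating for
differing amounts of secreting tissue. Zero abundances are floored at half
the variable's smallest positive value before the log — this preserves
ranks, avoids `-Inf`, and is reported by a warning rather than applied
silently. LDL is computed by the Friedewald formula
(`TC − HDL − TG/5`, mg/dL) and offered to the model alongside the measured
lipids; a negative Friedewald value is treated like a zero abundance
(flagged, floored) rather than dropped.

# BIC-approximate Bayesian model averaging

For one outcome index over n cases and a candidate set of p variables, the
subset model M fits `y = β₀ + Σ_{j∈M} β_j x*_j + ε` by least squares
(pivoted QR). Its Bayesian information criterion is

    BIC_M = n · ln(max(RSS_M, ε_RSS)/n) + (|M|+1) · ln(n)

and, under a uniform prior over models, the approximate posterior model
probability is `P(M|D) ∝ exp(−(BIC_M − BIC_min)/2)`. `enumerateBMA()` fits
all 2^p subsets (capped at p ≤ 20, and at |M| ≤ n − 2 so every fit has at
least one residual degree of freedom), applies Occam's window — models
with `P_best/P(M) > ratio` are discarded and the rest renormalized — and
reports per-variable posterior inclusion probabilities (summed probability
of the surviving models containing the variable) and model-averaged
coefficients (probability-weighted slopes, with weight zero where the
variable is excluded, so a variable absent from every surviving model is
shrunk *exactly* to zero).

Numerical choices:

* **RSS floor** `ε_RSS = 1e-12 · var(y) · n` keeps the BIC finite when a
  subset fits perfectly (possible at these sample sizes); it is far below
  any RSS a noisy fit produces and so never reorders realistic models.
* **Collinear subsets are errors**, not pseudo-inverses: a silent
  pseudo-inverse would give that subset an arbitrary RSS-equivalent
  representative and make posterior ordering depend on numerical
  tie-breaking.
* **Occam's window default 20** (a surviving model must be within a factor
  20 of the best) and **retention threshold 0.5** (a retained variable is
  more likely in than out) are conventional values, exposed as arguments
  and echoed into every result object and run manifest.

# Iterated selection at large p

With more candidates than can be enumerated, `ibmaSelect()` iterates:
variables are ordered once by univariate R² against the outcome (ties
broken lexicographically so the order is total and reproducible), the
first `windowSize` form the active set, and after each enumeration the
variables with inclusion probability above the retention threshold stay
while the rest are replaced by the next-ranked unexamined candidates. Two
rules close gaps the basic scheme leaves open:

* **Nothing dropped.** If every active variable survives while candidates
  remain unexamined, the lowest-inclusion survivors are swapped out until
  one slot frees up; otherwise the walk could stall. A strong variable
  evicted this way can still be judged fairly — its last-window inclusion
  probability is what the result reports for it.
* **Reporting.** The returned `inclusionProb`/`avgCoefficient` cover every
  candidate: final-enumeration values for the surviving active set,
  last-examined-window values for the rest. Inside any single enumeration
  the sum-of-model-probabilities identities hold exactly.

`windowSize` defaults to `min(8, n − 3)`. The `n − 3` cap matters for
per-group runs: with 4 HF cases the window degenerates to 1 and the
procedure reduces to univariate screening — it executes, logs the cap, and
is expected to retain little; the pooled run is the headline analysis.

# The two-stage congruence filter

Per-index selection alone is fragile at this n. The filter demands:

1. **Stage 1 (index congruence).** Selected for ≥ 1 IT index *and* ≥ 1 LA
   index; variables supported by only one lesion-geometry family are
   discarded (`discarded_stage1`).
2. **Stage 2 (coefficient congruence).** Supporting coefficients must
   share a sign and at least one must reach the magnitude floor (default
   0.001). Opposite signs of comparable size (max/min absolute ratio ≤ 10)
   indicate inappropriate selection and discard the variable
   (`discarded_sign`); all-below-floor support discards on magnitude.

Two deliberately exposed readings of the sign rule exist. The default
(`strictSign = TRUE`) discards on *any* sign disagreement — opposite signs
at very different magnitudes are hardly stronger evidence than comparable
ones. The relaxed reading (`strictSign = FALSE`) discards only
comparable-size opposite signs and otherwise takes the direction of the
dominant coefficient. Sign is checked before magnitude, so a variable with
opposite-sign, all-tiny coefficients is classed `discarded_sign`; the
order is a labelling convention, not a different retained set. The ledger
is a pure function of the selection table and the thresholds.

`demoSelectionPattern()` bundles a worked selection table over named
lipoproteins, cytokines and secreted proteins whose cells follow the
selection pattern reported for a pooled high-cholesterol-diet swine
cohort; since per-index coefficients for such studies are not deposited,
the coefficient values in the fixture are synthetic, chosen so the ledger
exercises every verdict class (eight retained — seven positive and one
negative — plus stage-1, sign and magnitude discards). One subtlety it
encodes: an adhesion-molecule variable can look "relevantly selected"
per-index yet fall at stage 1 when its baseline support is IT-only and its
end-diet support LA-only — the two timepoints are distinct candidates and
are not merged.

# What the synthetic generator does and does not emulate

`generateCohort()` draws cohorts with the structure the analysis assumes:

* **Groups and sizes.** Defaults 3 CNTL / 4 HF / 6 HHF, the typical scale
  of such experiments; recovery and calibration testing uses larger
  configurations (see below).
* **Plasma.** Lognormal between-case variation (sd 0.2 on the log scale, a
  ~20% biological CV); end-diet values are the baseline times a
  group fold-change (defaults: LDL ×5, oxLDL ×3, IL-6 and TNFα ×2,
  TG ×1.5, ICAM-1 ×1.5, HDL ×1.2 for treated groups) times residual noise.
  Total cholesterol is built structurally as `HDL + LDL + TG/5`, so the
  Friedewald step downstream recovers the generated LDL exactly.
* **Secretome.** i.i.d. lognormal abundances (log-mean 4, log-sd 0.5 —
  arbitrary-unit counts with ~50% CV).
* **Burden.** Case-level log lesion burden is
  `intercept + Σ_j effect_j · ln(x_j) + N(0, noise_sd)` over the variables
  named in `trueEffectMap` — a log-log linear model, so the pipeline's
  regression is correctly specified and planted coefficients are the
  estimands. The intercept auto-centres the planted contribution and adds
  `ln 4`, putting treated lesions around four times the control intima
  (0.05 mm default), a plausible early-atherogenesis contrast. There is no
  separate group term: group differences in burden arise only through
  diet-shifted analytes that carry planted effects.
* **Histology.** Per-case profiles over 10 segments whose mean IT equals
  `exp(burden)` exactly (weights renormalized); the `localized` pattern
  concentrates mass in the proximal third of segments (unaffected segments
  at 25% of hot thickness), driving the median to roughly half the mean,
  while `diffuse` spreads it uniformly. HF cases default to localized and
  HHF to diffuse, reproducing the mild-early vs advanced-diffuse contrast.
  Lesional area is 4 mm × IT with small jitter.

Not emulated: measurement error structure of ELISA or MS (no
heteroscedastic or censored noise), correlation among proteins, missing
data beyond zeros, within-artery spatial autocorrelation, or any
pharmacokinetics of the diet. Passing recovery tests therefore shows the
pipeline works *when its model is correctly specified at realistic noise
levels* — not that real cohorts satisfy those assumptions. The generator's
distributions are stand-ins, not estimates of any study's data.

# Degenerate inputs and edge behaviour

* Configurations without controls are rejected (control normalization
  undefined); group filters leaving < 3 cases are refused.
* Zero-variance candidate columns are dropped with a warning before
  modeling.
* Empty model sets cannot occur: the null (intercept-only) model is always
  fitted, and when no variable survives the iterated walk the result is
  the null-model average with an empty retained set.
* An empty selection table yields an empty ledger, not an error.

# Problem sizes used by the test suite

The suite checks the enumeration path against an independent brute-force
oracle (normal equations over all subsets) on 25 seeded datasets with
n = 30 and p = 3..8 to 1e-10; parameter recovery on 200 cohorts with 40
treated cases, 50 candidates and three planted effects of size 1.0 at
noise 0.3 (mean planted inclusion ≥ 0.8, mean null inclusion ≤ 0.3, sign
agreement ≥ 95% among retained); null calibration of the full pipeline on
100 all-noise default-size cohorts (mean retained ≤ 1); and the pooled vs
HF-only contrast on 50 default-size cohorts. These sizes give stable
Monte-Carlo estimates while keeping the default run light;
`scripts/acceptance.R` recomputes the same quantities at reduced replicate
counts (50/30/30) for a quick reproduction.

# Known limitations

* BIC posterior probabilities are an asymptotic approximation used at
  decidedly non-asymptotic n; they are the method's defining convention,
  not a claim of calibrated posterior coverage.
* The iterated walk is greedy: a variable informative only jointly with a
  much later-ranked partner can be missed. Exhaustive enumeration is exact
  but capped at p ≤ 20.
* The congruence filter exploits the correlation between IT and LA indexes
  of the same cases; it suppresses, but cannot eliminate, false positives
  that correlate with burden noise consistently across indexes.
* Per-group runs at n = 4 are univariate screening in all but name and are
  reported for completeness, not inference.
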