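---
title: "Methods: stride selection, tibial strain, and probabilistic stress-fracture risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride selection, tibial strain, and probabilistic stress-fracture risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibfrax)
library(dplyr)
```

## The analysis chain

tibfrax implements the computational chain of a treadmill running study
asking whether a 10% reduction in stride length lowers tibial
stress-fracture risk, and whether the answer depends on stature. The chain
has five stages:

1. **Representative-stride selection** from a 20-s vertical
   ground-reaction-force (GRF) recording per participant and condition.
2. **Tissue-strain summarisation**: CT-derived tissue rules applied to a
   finite-element-style element table, reduced to the 90th-percentile
   cortical von Mises strain.
3. **Probabilistic stress-fracture risk**: a bone fatigue--repair--adaptation
   model driven by daily running distance and stride length.
4. **Cohort statistics**: stride-by-stature linear mixed-effects models,
   anthropometry ANOVA, pooled summaries and percent reductions.
5. **Synthetic data**: seeded generators that emulate the cohort so the whole
   chain runs and is testable without any recordings.

## Representative-stride selection

Foot strikes are upward crossings of a 25 N threshold on the vertical GRF.
The threshold value is standard; the debounce around it (10 consecutive
samples above to enter stance, 10 below to leave, i.e. 10 ms at 1 kHz) is
our choice and guards against chatter when noise rides near 25 N. A stride
spans consecutive ipsilateral foot strikes (a single left-side force signal
is assumed); incomplete leading and trailing cycles are discarded.

Each stride is linearly interpolated onto 100 uniformly spaced time
fractions $k/100$, $k = 0,\dots,99$ (half-open, so the start of the next
stride is excluded and the value at fraction 0 is the strike sample). The
pointwise median of the 100-point waveforms defines the median stride, and
strides are ranked by their root-mean-square (RMS) distance to it. The
source method says only "closest to the median"; we read that as an
$L_2$-type ranking and expose mean absolute distance as an alternative
(`metric = "mean-abs"`). Ties break toward the earlier stride.

For the preferred condition the representative stride is the top-ranked
stride. For the reduced condition the stride length of every candidate is
computed as duration times belt speed (speed is taken from trial metadata,
3.0 m/s by default, never re-estimated), and the selected stride is the one
whose length is closest to 90% of the preferred representative's length;
exact ties fall back to the median-distance rank. Both selectors are tested
against exhaustive search on randomized traces.

## Tissue rules and strain summary

Element moduli (MPa) partition into intramedullary tissue ($E < 6$ MPa,
$\nu = 0.167$), trabecular bone ($6 \le E < 8000$ MPa, $\nu = 0.325$) and
cortical bone ($E \ge 8000$ MPa, $\nu = 0.325$), with boundaries closed
exactly as printed. The strain summary is the 90th percentile of von Mises
strain over cortical elements only, per element, using the
linear-interpolation quantile convention (`stats::quantile` type 7); the
convention is configurable because the source does not state one.

`hu_to_modulus()` maps Hounsfield units through a linear phantom
calibration to density and a power law to modulus
($E = 10500\,\rho^{2.29}$ MPa by default, a widely used density--modulus
relation). The constants are configuration with documented defaults; no
downstream result in this package depends on their exact values because the
synthetic element tables carry moduli directly.

Kinetic normalisation uses $g = 9.81$ m/s²: forces in body weights
(BW = mass·g), moments per kilogram of body mass.

## The fatigue--repair--adaptation risk model

The strain-life relation is a power law in microstrain,
$$N_f(\varepsilon) = C\,\varepsilon^{-m},$$
with defaults $m = 9$ and $C = 3\times10^{38}$, anchoring
$N_f(5000\,\mu\varepsilon) \approx 1.5\times10^5$ cycles — the scale
reported for human cortical bone in bending, with a slope inside the
commonly reported 5--15 range. Daily loading cycles are running distance
divided by stride length (one tibial loading cycle per gait cycle, rounded
to an integer).

**Adaptation.** Bone apposition is modelled on a hollow circular
mid-diaphysis section (periosteal radius 11 mm, endosteal 7 mm by default)
whose periosteal radius grows at 4 μm/day. For a constant bending moment
the surface strain is proportional to $c/I$ with $c = r_p$ and
$I = \tfrac{\pi}{4}(r_p^4 - r_i^4)$, so the day-$t$ strain is the baseline
strain times the adaptation ratio $[c(t)/I(t)]\,/\,[c(0)/I(0)] \le 1$,
which equals 1 at day 0 and is non-increasing in time.

**Repair.** "A bone repair rate of 26 days" is implemented as an
exponential decay time constant: accumulated Miner damage is multiplied by
$e^{-1/26}$ on every calendar day, after that day's inflow; rest days decay
only. Alternative readings (linear removal, remodelling delay) are possible;
the exponential form keeps damage bookkeeping first-order and the time
constant is configuration.

**Failure probability.** Fatigue-life scatter is a single multiplicative
lognormal factor $s$ with $\log_{10} s \sim N(0, \sigma)$,
$\sigma = 0.57$ by default (a typical fatigue-scatter magnitude), shared
across days for a participant. Failure by day $T$ is the event that scaled
damage reached 1 on some day $t \le T$, so
$$P(T) = \Phi\!\left(\frac{\log_{10} \max_{t \le T} D_t}{\sigma}\right),$$
where $D_t$ is the deterministic damage after decay. The running maximum
matters: with repair, $D_t$ dips across rest days, and using $D_T$ alone
would make the cumulative probability non-monotone. The closed form is
verified against a Monte-Carlo oracle (10⁵ draws of $s$) in the test suite.
With $\sigma = 0$ the risk degenerates to a warned step function at
$D = 1$.

Regimens: `bct` is 10 weeks of five 1.7-km training days plus two rest days
(70 days, 85 km); `bct_doubled` doubles the daily distance to 3.4 km; `rt`
is 20 weeks at 9.6 km/day, five days a week (140 days, 960 km).

The absolute end-of-regimen risks depend on $C$, $m$, $\sigma$ and the
section geometry, which the source study inherits from prior work without
printing; under the defaults above, a back-of-envelope calculation (and the
pipeline) put the preferred-condition BCT risk near 1% and the RT risk near
10%. The package therefore treats absolute risks as order-of-magnitude
quantities and focuses on directions and relative reductions, which are
insensitive to the constants.

## Cohort statistics

For each outcome the full model is
`value ~ condition * stature_group + (1 | participant_id)`, tested with
Wald F-tests using Kenward-Roger degrees of freedom (the prescribed
small-sample method; Satterthwaite is available where speed matters and the
method used is recorded in the result). If the interaction is not
significant at $\alpha = 0.05$ it is removed and the main effects are
re-evaluated in the reduced model. When the interaction is retained, the
two stride levels are compared within each stature group on estimated
marginal means with Holm-Bonferroni adjustment; with only two stride
levels, a significant stride main effect alone needs no post hoc contrast,
so none is produced in that branch. Stress-fracture risks are
natural-log-transformed before modelling (zeros floored at a configurable
epsilon) and summarised as geometric means with t-based confidence
intervals back-transformed from the log scale.

Pooled, table-style summaries are plain means over participants when raw
values are available and group-size-weighted means (6/7/7) when only group
means are supplied. Reported percentages are rounded to the nearest
integer, matching the presentation convention.

## What the synthetic generators emulate — and what they do not

The generators target a 20-woman cohort in three stature groups (6/7/7)
running at 3.0 m/s, with the published group means and SDs for
anthropometry, representative stride lengths, and all thirteen
biomechanical outcomes (see `reference_outcomes()`).

* **GRF waveform**: each stance is a smooth double-humped curve (a small
  impact bump at ~18% of stance plus a dominant active peak at mid-stance)
  scaled to a peak near 2.4 BW, over a stance occupying 33% of the stride;
  flight is exactly zero. No waveform model is stated in the source; the
  selection algorithm uses only thresholded timing and pointwise medians,
  so any smooth shape with correct peak and timing serves.
* **Stride variability**: stride durations vary with CV 2% (a typical
  steady-state treadmill value; the source is silent), truncated at ±3 SD.
* **Outcomes**: each variable is group-by-condition mean + participant
  random intercept + residual, with 70% of the variance assigned to the
  intercept — exactly the random-intercept structure the mixed model
  assumes. The published cell means embed small group-by-condition
  patterns, so tests of test size construct explicit null or additive mean
  tables instead of using the default config.
* **Element tables**: moduli are drawn across all three tissue classes
  (roughly 15/35/50% intramedullary/trabecular/cortical) and the cortical
  strain cloud is rescaled so its 90th percentile equals the participant's
  target exactly; per-participant strain reductions are drawn with mean 12%
  and truncated to the 2--34% envelope observed across subjects.
* **Not emulated**: marker kinematics, inverse dynamics, CT images, FE
  meshing/solving, 3-D GRF components, bilateral signals. Passing tests
  show the post-processing chain is correct, not that the musculoskeletal
  or FE modelling they stand in for is.

Anthropometry is drawn from per-group normals truncated at ±3 SD to avoid
non-physiologic values. All generators take a single seed that fans out to
per-stage child seeds deterministically, so any stage reruns independently
and a fixed seed gives byte-identical output.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation), configurable.
* Resampling: fractions $k/100$ over a half-open stride, clamped at the
  last sample when $0.99\,n$ exceeds it.
* Distance metric: RMS default, mean-abs optional; ties toward the earlier
  stride index.
* Traces entirely below 25 N segment to an empty table with a warning;
  selectors require at least two strides.
* Zero strain or an empty regimen yields zero risk everywhere;
  `scatter_sd = 0` and zero preferred-condition risks produce warned
  degenerate outputs rather than errors.
* lme4 refuses exactly-zero residual variance; the identity tests use
  varying participant baselines with a constant shift instead.

## Problem sizes

The test suite and the acceptance script run at the study's own scale: 20
participants, 20-s trials at 1 kHz (~29 strides per trial), 2,000 elements
per table, 70--140-day regimens, a 10⁵-draw Monte-Carlo oracle on 20
randomized parameter sets, a 1,000-simulation check that the stride test
holds its nominal size on null cohorts, and a 60-run power check at the
published effect sizes.

## Known limitations

Only the vertical GRF is synthesised and only one (left) side is analysed.
The risk model is deterministic in everything except the shared
fatigue-life factor; per-day independent scatter, site-specific cortical
risk and muscle-fatigue modulation are out of scope. Absolute risk values
inherit the uncertainty of the strain-life constants; relative reductions
are the robust output.
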