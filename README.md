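# tibfrax

Stride selection, tibial strain summaries, and probabilistic
stress-fracture risk for treadmill running cohorts.

## The problem

Tibial stress fracture is the leading overuse injury in high-volume
runners — military recruits in basic combat training (BCT) and recreational
athletes alike — and women are affected disproportionately. Shortening the
running stride at constant speed lowers joint loads and tibial strain, but
quantifying how much that lowers *fracture risk*, and whether the benefit
depends on stature, requires a chain of computations: picking one
representative gait cycle from a noisy 20-s force recording, reducing a
finite-element strain field to a single cortical strain summary, pushing
that strain through a bone fatigue–repair–adaptation model over a training
regimen, and comparing conditions across a small grouped cohort with
repeated measures.

tibfrax implements that chain as composable, tibble-in/tibble-out R
functions, plus seeded synthetic-data generators that emulate a 20-woman
cohort (short/medium/tall stature, n = 6/7/7) running at 3.0 m/s with a
preferred and a 10%-reduced stride length, so the whole pipeline runs and
is testable without any recordings.

## The model at the core

* **Representative stride** — foot strikes are debounced upward crossings
  of 25 N on the vertical GRF; strides are time-normalised to 100 points;
  the preferred-condition representative minimises the RMS distance to the
  pointwise median waveform, and the reduced-condition representative has
  stride length (duration × speed) closest to 0.9 × the preferred
  representative's length, ties resolved by median distance.
* **Tissue rules** — elements with modulus E < 6 MPa are intramedullary
  (ν = 0.167), 6 MPa ≤ E < 8 GPa trabecular, E ≥ 8 GPa cortical
  (ν = 0.325); the strain summary is the 90th-percentile cortical von Mises
  strain.
* **Fracture risk** — strain-life N_f = C ε^−m; daily cycles =
  distance / stride length; Miner damage decays by exp(−1/26) per day
  (repair); strain declines by a beam-theory adaptation ratio as the
  periosteal radius grows 4 μm/day; failure probability is
  Φ(log₁₀ max_t D_t / σ) for a shared lognormal fatigue-life factor.
  Regimens: BCT (10 wk × 5 d × 1.7 km), doubled BCT (3.4 km), and
  recreational training, RT (20 wk × 5 d × 9.6 km).
* **Statistics** — per outcome, `value ~ condition * stature_group +
  (1 | participant_id)` with Kenward-Roger Wald F-tests; non-significant
  interactions are dropped and main effects re-evaluated; risks are
  log-transformed and pooled as geometric means.

See `vignettes/tibfrax-methods.Rmd` for assumptions, defaults and
limitations.

## Worked example

```r
library(tibfrax)
library(dplyr)

cfg    <- cohort_config(seed = 42)
cohort <- generate_cohort(cfg)
p      <- cohort[7, ]   # one medium-stature participant

trial_pref <- generate_trial(p, "preferred", cfg, seed = 42)
trial_red  <- generate_trial(p, "reduced10", cfg, seed = 43)
rep_pref <- select_representative_preferred(trial_pref)
rep_red  <- select_representative_reduced(trial_red, rep_pref$stride_length_m)
rep_pref[, c("stride", "duration_s", "stride_length_m")]
#>   stride duration_s stride_length_m
#> 1     12      0.726            2.18
rep_red[, c("stride", "stride_length_m", "target_length_m")]
#>   stride stride_length_m target_length_m
#> 1     21            1.95            1.96
```

Stride 12 of 27 is the waveform closest to the median preferred stride
(2.18 m at 3.0 m/s); in the reduced trial, stride 21's length (1.95 m) is
the closest to the 1.96 m target (90% of 2.18 m).

```r
strain <- bind_rows(
  cortical_strain_p90(generate_element_table(p, "preferred", seed = 42)),
  cortical_strain_p90(generate_element_table(p, "reduced10", seed = 42)))
strain
#>   participant_id condition n_cortical strain_p90_ue
#> 1 P07            preferred       1000         3911.
#> 2 P07            reduced10       1000         3636.

risk <- bind_rows(
  simulate_risk(strain$strain_p90_ue[1], rep_pref$stride_length_m,
                build_regimen("bct")) |> tail(1) |> mutate(condition = "preferred"),
  simulate_risk(strain$strain_p90_ue[2], rep_red$stride_length_m,
                build_regimen("bct")) |> tail(1) |> mutate(condition = "reduced10"))
risk[, c("condition", "day", "damage", "risk")]
#>   condition   day  damage       risk
#> 1 preferred    70 0.00516 0.0000541
#> 2 reduced10    70 0.00298 0.00000896

relative_risk_reduction(risk$risk[1], risk$risk[2])  # 83 (%)
percent_reduction(strain$strain_p90_ue[1], strain$strain_p90_ue[2])  # 7 (%)
```

For this participant a 7% strain reduction cuts the 70-day BCT fracture
risk by 83% — the convexity of the strain-life power law makes modest
strain reductions very effective, despite the shorter stride adding loading
cycles per kilometre.

Group-level tables pool with size weights (6/7/7):

```r
pooled_summary(reference_outcomes(), "tibial_strain_p90", "preferred")
#>   variable          condition     n  mean    sd
#> 1 tibial_strain_p90 preferred    20 5007.    NA
```

`run_pipeline(cohort_config(seed = 1))` chains all stages for the full
cohort and returns strides, strain summaries, per-regimen risk
trajectories, mixed-model results and the per-participant reduction
report; `plot_stride_selection()`, `plot_risk_trajectories()`,
`plot_participant_reductions()` and `autoplot()` visualise each stage.

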