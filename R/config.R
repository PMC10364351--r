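#' Cohort generation configuration
#'
#' Builds the configuration consumed by the synthetic-data generators. The
#' defaults encode the study conditions the package emulates: a 20-woman
#' cohort in three stature groups (6/7/7), two stride conditions at a
#' constant treadmill speed of 3.0 m/s, 20-s force recordings at 1,000 Hz,
#' a running vertical GRF with peak around 2.3-2.5 body weight, and outcome
#' distributions matching the published group summaries (see
#' [reference_outcomes()]).
#'
#' @param seed Integer seed fanned out to every generator stage.
#' @param group_sizes Named integer vector of participants per stature group.
#' @param anthropometry Tibble of per-group anthropometry means/SDs, as
#'   returned by [reference_anthropometry()].
#' @param stride_lengths Tibble of per-group, per-condition representative
#'   stride-length means/SDs in metres, as returned by
#'   [reference_stride_lengths()].
#' @param outcomes Tibble of per-group, per-condition outcome means/SDs, as
#'   returned by [reference_outcomes()].
#' @param speed Treadmill belt speed in m/s.
#' @param sampling_rate Force sampling rate in Hz.
#' @param trial_duration Trial duration in seconds.
#' @param stride_variability_cv Coefficient of variation of stride-to-stride
#'   duration within a trial (fraction of the mean stride duration). Default
#'   0.02, a typical steady-state treadmill value.
#' @param peak_grf_bw Mean and SD (named vector) of the peak vertical GRF in
#'   body weights for the preferred condition; the reduced condition uses a
#'   peak lower by `peak_grf_reduction`.
#' @param peak_grf_reduction Fractional drop of the GRF peak in the reduced
#'   condition (default 0.04, i.e. 2.5 -> 2.4 BW scale).
#' @param strain_reduction Mean, SD and truncation bounds (named vector
#'   `mean`, `sd`, `min`, `max`) of the per-participant fractional reduction
#'   in 90th-percentile tibial strain between conditions. Default mean 0.12
#'   truncated to \[0.02, 0.34\], the per-participant envelope the cohort
#'   displays.
#' @param intercept_share Fraction of each outcome variance attributed to the
#'   participant random intercept (within-subject correlation). Default 0.7.
#' @param truncation_sd Truncation half-width for anthropometry draws, in
#'   SDs (default 3; guards against non-physiologic values).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          group_sizes = c(short = 6L, medium = 7L, tall = 7L),
                          anthropometry = reference_anthropometry(),
                          stride_lengths = reference_stride_lengths(),
                          outcomes = reference_outcomes(),
                          speed = 3.0,
                          sampling_rate = 1000,
                          trial_duration = 20,
                          stride_variability_cv = 0.02,
                          peak_grf_bw = c(mean = 2.43, sd = 0.13),
                          peak_grf_reduction = 0.04,
                          strain_reduction = c(mean = 0.12, sd = 0.06,
                                               min = 0.02, max = 0.34),
                          intercept_share = 0.7,
                          truncation_sd = 3) {
  if (any(group_sizes <= 0)) {
    abort("all group sizes must be positive", class = "tibfrax_config_error")
  }
  if (any(outcomes$sd < 0) || any(anthropometry$sd < 0)) {
    abort("standard deviations must be non-negative", class = "tibfrax_config_error")
  }
  if (stride_variability_cv < 0 || stride_variability_cv > 0.2) {
    abort("stride_variability_cv must lie in [0, 0.2]", class = "tibfrax_config_error")
  }
  structure(
    list(
      seed = as.integer(seed), group_sizes = group_sizes,
      anthropometry = anthropometry, stride_lengths = stride_lengths,
      outcomes = outcomes, speed = speed, sampling_rate = sampling_rate,
      trial_duration = trial_duration,
      stride_variability_cv = stride_variability_cv,
      peak_grf_bw = peak_grf_bw, peak_grf_reduction = peak_grf_reduction,
      strain_reduction = strain_reduction,
      intercept_share = intercept_share, truncation_sd = truncation_sd
    ),
    class = "cohort_config"
  )
}

#' Fatigue, repair and adaptation model parameters
#'
#' Constants of the probabilistic stress-fracture model. The strain-life
#' (S-N) relation is the power law `N_f = C * strain^-m` with strain in
#' microstrain; fatigue-life scatter is a multiplicative lognormal factor
#' with `log10` standard deviation `scatter_sd`; fatigue damage decays with
#' an exponential repair time constant (days); bone adaptation grows the
#' periosteal radius of a hollow circular section at a constant apposition
#' rate. Defaults are documented literature-scale values for human cortical
#' bone in bending: a life of roughly 1.5e5 cycles at 5,000 microstrain with
#' slope 9, scatter of 0.57 log10 units, a 26-day repair rate and 4 um/day
#' apposition.
#'
#' @param sn_coefficient S-N coefficient `C` (cycles x microstrain^m).
#' @param sn_exponent S-N exponent `m` (dimensionless, > 0).
#' @param scatter_sd SD of log10 of the multiplicative fatigue-life factor.
#' @param repair_time_constant Exponential damage-repair time constant, days.
#' @param apposition_rate Periosteal bone deposition rate, um/day.
#' @param periosteal_radius,endosteal_radius Hollow-circular tibial
#'   mid-diaphysis cross-section radii, mm.
#' @return A list of class `fatigue_params`.
#' @export
fatigue_params <- function(sn_coefficient = 3e38,
                           sn_exponent = 9,
                           scatter_sd = 0.57,
                           repair_time_constant = 26,
                           apposition_rate = 4,
                           periosteal_radius = 11,
                           endosteal_radius = 7) {
  stopifnot(sn_coefficient > 0, sn_exponent > 0, scatter_sd >= 0,
            repair_time_constant > 0, apposition_rate >= 0)
  if (!(periosteal_radius > endosteal_radius && endosteal_radius > 0)) {
    abort("cross-section requires periosteal > endosteal > 0",
          class = "tibfrax_config_error")
  }
  structure(
    list(
      sn_coefficient = sn_coefficient, sn_exponent = sn_exponent,
      scatter_sd = scatter_sd, repair_time_constant = repair_time_constant,
      apposition_rate = apposition_rate,
      periosteal_radius = periosteal_radius,
      endosteal_radius = endosteal_radius
    ),
    class = "fatigue_params"
  )
}

# Deterministic fan-out of one user seed into per-stage child seeds, so any
# stage can be rerun independently of the others.
child_seed <- function(seed, stage, index = 0L) {
  stages <- c(cohort = 11L, trial = 23L, elements = 37L, outcomes = 53L,
              stats = 71L, generic = 89L)
  s <- stages[[match.arg(stage, names(stages))]]
  as.integer((as.double(seed) * 48271 + s * 9973 + index * 101) %% 2147483647)
}

# Truncated-normal sampler (mean +/- k*sd) by rejection; k >= 1 keeps the
# acceptance rate near 1 so the loop terminates quickly.
rnorm_trunc <- function(n, mean, sd, k = 3, lower = mean - k * sd,
                        upper = mean + k * sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}
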