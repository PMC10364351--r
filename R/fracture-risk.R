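#' Build a training regimen
#'
#' Returns the day-by-day running distances of the three simulated training
#' regimens: a 10-week basic-combat-training regimen (`bct`; five training
#' days of 1.7 km and two rest days per week), the same regimen with the
#' daily distance doubled to 3.4 km (`bct_doubled`), and a 20-week
#' recreational marathon-training regimen (`rt`; five training days of
#' 9.6 km and two rest days per week).
#'
#' @param kind One of `"bct"`, `"bct_doubled"`, `"rt"`, or `"custom"` (then
#'   `weeks` and `km_per_training_day` must be given).
#' @param weeks,km_per_training_day Custom regimen definition: number of
#'   weeks and running distance on each of the five weekly training days.
#' @return A tibble with columns `day` (1-based) and `distance_km`, plus a
#'   `regimen` column naming the regimen.
#' @export
#' @examples
#' sum(build_regimen("bct")$distance_km)  # 85 km over 70 days
build_regimen <- function(kind = c("bct", "bct_doubled", "rt", "custom"),
                          weeks = NULL, km_per_training_day = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    bct = list(weeks = 10, km = 1.7),
    bct_doubled = list(weeks = 10, km = 3.4),
    rt = list(weeks = 20, km = 9.6),
    custom = {
      stopifnot(!is.null(weeks), !is.null(km_per_training_day),
                km_per_training_day >= 0)
      list(weeks = weeks, km = km_per_training_day)
    }
  )
  week <- c(rep(def$km, 5), 0, 0)
  tibble(
    regimen = kind,
    day = seq_len(7 * def$weeks),
    distance_km = rep(week, def$weeks)
  )
}

#' Daily loading cycles from distance and stride length
#'
#' One tibial loading cycle is assigned per stride, so the number of daily
#' loading cycles is the running distance divided by the individual stride
#' length, rounded to the nearest integer.
#'
#' @param distance_km Running distance per day, km (>= 0).
#' @param stride_length_m Stride length, m (> 0).
#' @return Integer-valued numeric vector of loading cycles.
#' @export
#' @examples
#' daily_cycles(1.7, 2.06)  # 825
daily_cycles <- function(distance_km, stride_length_m) {
  if (any(stride_length_m <= 0)) {
    abort("stride length must be positive", class = "tibfrax_input_error")
  }
  stopifnot(all(distance_km >= 0))
  round(1000 * distance_km / stride_length_m)
}

#' Strain-life fatigue life
#'
#' Cycles to failure from the S-N power law `N_f = C * strain^-m`, strain in
#' microstrain.
#'
#' @param strain_ue Cyclic strain magnitude, microstrain (> 0).
#' @param params A [fatigue_params()].
#' @return Fatigue life in cycles.
#' @export
fatigue_life <- function(strain_ue, params = fatigue_params()) {
  if (any(strain_ue <= 0)) {
    abort("strain must be positive", class = "tibfrax_input_error")
  }
  params$sn_coefficient * strain_ue^(-params$sn_exponent)
}

#' Strain adaptation ratio from beam theory
#'
#' Models load-driven bone adaptation as periosteal apposition on a hollow
#' circular cross-section: the periosteal radius grows linearly,
#' `r_p(t) = r_p(0) + rate * t`, while the endosteal radius is fixed. For a
#' constant bending moment the peak surface strain is proportional to
#' `c / I` with `c = r_p` and `I = pi/4 (r_p^4 - r_i^4)`, so the adaptation
#' ratio is `[c(t)/I(t)] / [c(0)/I(0)]`, equal to 1 at day 0 and
#' non-increasing in time.
#'
#' @param day Days since the start of training (>= 0); vectorised.
#' @param params A [fatigue_params()] supplying the section radii and the
#'   apposition rate (um/day).
#' @return Numeric vector of strain adaptation ratios (<= 1).
#' @export
adaptation_ratio <- function(day, params = fatigue_params()) {
  stopifnot(all(day >= 0))
  rp0 <- params$periosteal_radius
  ri <- params$endosteal_radius
  rp <- rp0 + params$apposition_rate * 1e-3 * day   # um/day on mm radii
  c_over_i <- function(r) r / ((pi / 4) * (r^4 - ri^4))
  c_over_i(rp) / c_over_i(rp0)
}

#' Simulate the probabilistic stress-fracture risk trajectory
#'
#' Day-indexed bone fatigue-repair-adaptation bookkeeping. For each calendar
#' day `t` of the regimen the tibial strain is adjusted by the adaptation
#' ratio, the day's loading cycles add Miner damage `n_t / N_f(strain_t)`,
#' and accumulated damage then decays by `exp(-1 / repair_time_constant)`
#' (rest days decay only). Fatigue-life scatter is a single multiplicative
#' lognormal factor `s` (`log10 s ~ Normal(0, scatter_sd)`) shared across
#' days; failure by day `T` is the event that scaled damage has reached 1 at
#' any day up to `T`, giving the closed-form cumulative failure probability
#' `P(T) = Phi(log10(max_{t <= T} D_t) / scatter_sd)`.
#'
#' @param strain_p90_ue Baseline 90th-percentile cortical von Mises strain,
#'   microstrain (>= 0).
#' @param stride_length_m Stride length used to convert daily distance to
#'   loading cycles, m.
#' @param regimen A [build_regimen()] tibble.
#' @param params A [fatigue_params()].
#' @return A tibble with one row per day: `day`, `distance_km`, `cycles`,
#'   `adjusted_strain_ue`, `damage` (deterministic accumulated damage after
#'   decay) and `risk` (cumulative failure probability in `[0, 1]`).
#' @export
simulate_risk <- function(strain_p90_ue, stride_length_m, regimen,
                          params = fatigue_params()) {
  stopifnot(strain_p90_ue >= 0, nrow(regimen) >= 0)
  days <- regimen$day
  cycles <- daily_cycles(regimen$distance_km, stride_length_m)
  ratio <- adaptation_ratio(days, params)
  strain_t <- strain_p90_ue * ratio
  inflow <- ifelse(strain_t > 0 & cycles > 0,
                   cycles / fatigue_life(pmax(strain_t, 1e-12), params), 0)
  decay <- exp(-1 / params$repair_time_constant)

  damage <- numeric(length(days))
  d <- 0
  for (i in seq_along(days)) {
    d <- (d + inflow[i]) * decay
    damage[i] <- d
  }
  peak <- cummax(damage)
  risk <- if (params$scatter_sd == 0) {
    warn("scatter_sd = 0: degenerate step-function risk")
    as.numeric(peak >= 1)
  } else {
    ifelse(peak > 0, pnorm(log10(peak) / params$scatter_sd), 0)
  }
  tibble(day = days, distance_km = regimen$distance_km, cycles = cycles,
         adjusted_strain_ue = strain_t, damage = damage, risk = risk)
}

#' Relative risk reduction between stride conditions
#'
#' @param risk_pref,risk_reduced Final failure probabilities (or risks in
#'   percent) under the preferred and reduced stride lengths.
#' @return Percent reduction `100 * (risk_pref - risk_reduced) / risk_pref`;
#'   `NA` with a warning when the preferred risk is zero.
#' @export
#' @examples
#' relative_risk_reduction(2.3, 0.9)   # ~61
relative_risk_reduction <- function(risk_pref, risk_reduced) {
  out <- 100 * (risk_pref - risk_reduced) / risk_pref
  if (any(risk_pref == 0)) {
    warn("zero preferred-condition risk: reduction undefined, returning NA")
    out[risk_pref == 0] <- NA_real_
  }
  out
}
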