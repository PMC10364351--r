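# Shared fixtures, all built in code.

# A trace of clean half-sine stance pulses with known strike samples.
make_pulse_trace <- function(n_pulses = 4, stance_s = 0.25, flight_s = 0.45,
                             fs = 1000, peak_n = 1500, lead_s = 0.1,
                             peaks = rep(peak_n, n_pulses)) {
  stance <- round(stance_s * fs)
  flight <- round(flight_s * fs)
  lead <- round(lead_s * fs)
  force <- numeric(lead + n_pulses * (stance + flight))
  strikes <- integer(n_pulses)
  for (k in seq_len(n_pulses)) {
    i0 <- lead + (k - 1) * (stance + flight)       # 0-based strike sample
    pulse <- peaks[k] * sin(pi * (seq_len(stance) - 0.5) / stance)
    force[(i0 + 1):(i0 + stance)] <- pulse
    strikes[k] <- i0
  }
  list(
    trace = tibble::tibble(time_s = (seq_along(force) - 1) / fs,
                           force_n = force),
    strikes = strikes, fs = fs
  )
}

# Independent brute-force foot-strike scan: first index of a >= debounce run
# above threshold, requiring >= debounce below beforehand.
brute_force_strikes <- function(force, threshold = 25, debounce = 10) {
  above <- force > threshold
  strikes <- integer(0)
  in_stance <- FALSE
  i <- 1
  n <- length(above)
  while (i <= n) {
    j <- i
    while (j <= n && above[j] == above[i]) j <- j + 1
    len <- j - i
    if (above[i] && !in_stance && len >= debounce) {
      strikes <- c(strikes, i - 1L)
      in_stance <- TRUE
    }
    if (!above[i] && in_stance && len >= debounce) in_stance <- FALSE
    i <- j
  }
  strikes
}

# Exhaustive selector oracles, written as explicit loops.
oracle_closest_to_median <- function(waves) {
  m <- do.call(rbind, waves)
  med <- apply(m, 2, median)
  d <- numeric(length(waves))
  for (i in seq_along(waves)) d[i] <- sqrt(mean((waves[[i]] - med)^2))
  which(d == min(d))[1]
}

oracle_closest_length <- function(lengths, target, median_dist) {
  err <- abs(lengths - target)
  cand <- which(err == min(err))
  cand[which.min(median_dist[cand])]
}

# Config with no stride effect and no interaction: both conditions share the
# preferred-condition mean and SD of each group.
null_stride_config <- function(seed = 1L, ...) {
  out <- reference_outcomes() |>
    dplyr::group_by(variable, stature_group) |>
    dplyr::mutate(mean = mean[condition == "preferred"],
                  sd = sd[condition == "preferred"]) |>
    dplyr::ungroup()
  cohort_config(seed = seed, outcomes = out, ...)
}

# Config with the published stride effects but a strictly additive mean
# structure (group main effect + pooled condition effect, zero interaction)
# and homoscedastic SDs.
additive_stride_config <- function(seed = 1L, ...) {
  out <- reference_outcomes() |>
    dplyr::group_by(variable) |>
    dplyr::mutate(
      effect = weighted.mean(mean[condition == "reduced10"],
                             n[condition == "reduced10"]) -
        weighted.mean(mean[condition == "preferred"],
                      n[condition == "preferred"])
    ) |>
    dplyr::group_by(variable, stature_group) |>
    dplyr::mutate(mean = mean[condition == "preferred"] +
                    effect * (condition == "reduced10"),
                  sd = sd[condition == "preferred"]) |>
    dplyr::ungroup() |>
    dplyr::select(-effect)
  cohort_config(seed = seed, outcomes = out, ...)
}

# One-participant helper row.
test_participant <- function(stride = 2.06, strain = 5007, mass = 60,
                             reduction = 0.12) {
  tibble::tibble(
    participant_id = "T01",
    stature_group = factor("medium", levels = c("short", "medium", "tall")),
    age_yr = 20, mass_kg = mass, height_m = 1.63, foot_length_m = 0.24,
    body_fat_pct = 18, preferred_stride_length_m = stride,
    strain_preferred_ue = strain, strain_reduction = reduction
  )
}

quiet_fit <- function(...) {
  suppressWarnings(suppressMessages(fit_stride_stature_model(...)))
}
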