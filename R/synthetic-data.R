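#' Generate a synthetic cohort
#'
#' Draws a cohort of participants whose anthropometry, preferred stride
#' length and target tibial strain follow the per-group distributions in the
#' configuration. Anthropometry is sampled from per-group normal
#' distributions truncated at `truncation_sd` standard deviations, so all
#' masses, heights and foot lengths stay physiologic. Each participant also
#' receives a preferred-condition target 90th-percentile strain and a
#' fractional strain reduction for the reduced-stride condition, used by
#' [generate_element_table()].
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant: `participant_id`,
#'   `stature_group`, `age_yr`, `mass_kg`, `height_m`, `foot_length_m`,
#'   `body_fat_pct`, `preferred_stride_length_m`, `strain_preferred_ue`,
#'   `strain_reduction`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort, stature_group)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, "cohort"))
  k <- config$truncation_sd

  groups <- names(config$group_sizes)
  cohort <- purrr::map_dfr(groups, function(g) {
    n <- config$group_sizes[[g]]
    anth <- filter(config$anthropometry, .data$stature_group == g)
    draw <- function(var) {
      row <- filter(anth, .data$variable == var)
      rnorm_trunc(n, row$mean, row$sd, k = k)
    }
    sl <- filter(config$stride_lengths, .data$stature_group == g,
                 .data$condition == "preferred")
    st <- filter(config$outcomes, .data$variable == "tibial_strain_p90",
                 .data$stature_group == g, .data$condition == "preferred")
    sr <- config$strain_reduction
    tibble(
      stature_group = factor(g, levels = groups),
      age_yr = draw("age_yr"),
      mass_kg = draw("mass_kg"),
      height_m = draw("height_m"),
      foot_length_m = draw("foot_length_m"),
      body_fat_pct = draw("body_fat_pct"),
      preferred_stride_length_m = rnorm_trunc(n, sl$mean, sl$sd, k = k),
      strain_preferred_ue = rnorm_trunc(n, st$mean, st$sd, k = k),
      strain_reduction = rnorm_trunc(n, sr[["mean"]], sr[["sd"]],
                                     lower = sr[["min"]], upper = sr[["max"]])
    )
  })
  cohort |>
    mutate(participant_id = sprintf("P%02d", seq_len(nrow(cohort))),
           .before = 1)
}

#' Generate a synthetic vertical-GRF treadmill trial
#'
#' Synthesises a uniformly sampled vertical ground-reaction-force recording
#' for one participant and stride condition: consecutive strides whose
#' durations vary around `stride_length / speed` with the configured
#' coefficient of variation, each with a smooth double-humped running stance
#' waveform (impact plus active peak) spanning about a third of the stride
#' and zero-force flight in between. The reduced condition uses a stride
#' length of 90% of the participant's preferred stride length.
#'
#' @param participant One row of a [generate_cohort()] tibble.
#' @param condition `"preferred"` or `"reduced10"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this trial.
#' @return A tibble of class `grf_trace` with columns `time_s`, `force_n`
#'   and attributes `participant_id`, `condition`, `sampling_rate`, `speed`,
#'   `n_strides` (complete foot-strike-to-foot-strike cycles laid down) and
#'   `stride_durations_s`.
#' @export
generate_trial <- function(participant, condition = c("preferred", "reduced10"),
                           config = cohort_config(), seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(nrow(participant) == 1)
  set.seed(child_seed(seed, "trial"))

  speed <- config$speed
  fs <- config$sampling_rate
  dur <- config$trial_duration
  stride_len <- participant$preferred_stride_length_m *
    if (condition == "reduced10") 0.9 else 1.0
  mean_T <- stride_len / speed
  if (mean_T >= dur) {
    abort("stride duration exceeds the trace duration",
          class = "tibfrax_generation_error")
  }

  peak_mean_bw <- config$peak_grf_bw[["mean"]] *
    if (condition == "reduced10") 1 - config$peak_grf_reduction else 1
  peak_bw <- rnorm_trunc(1, peak_mean_bw, config$peak_grf_bw[["sd"]])
  peak_n <- peak_bw * participant$mass_kg * GRAVITY

  n_samp <- round(dur * fs)
  force <- numeric(n_samp)
  cv <- config$stride_variability_cv
  stance_frac <- 0.33

  t_strike <- 0.05                      # lead-in flight before first strike
  strikes <- numeric(0)
  durations <- numeric(0)
  repeat {
    T_i <- mean_T * (1 + if (cv > 0) rnorm_trunc(1, 0, cv) else 0)
    stance <- stance_frac * T_i
    if (t_strike + stance > dur) break
    i0 <- round(t_strike * fs) + 1
    i1 <- min(round((t_strike + stance) * fs), n_samp)
    tau <- (seq(i0, i1) - i0) / (i1 - i0)
    shape <- 0.65 * exp(-((tau - 0.18) / 0.09)^2) + exp(-((tau - 0.50) / 0.17)^2)
    pk_i <- peak_n * (1 + if (cv > 0) rnorm_trunc(1, 0, 0.02) else 0)
    force[i0:i1] <- pk_i * shape / max(shape)
    strikes <- c(strikes, t_strike)
    durations <- c(durations, T_i)
    t_strike <- t_strike + T_i
  }
  if (length(strikes) < 2) {
    abort("trace too short to contain a complete stride",
          class = "tibfrax_generation_error")
  }

  out <- tibble(time_s = (seq_len(n_samp) - 1) / fs, force_n = pmax(force, 0))
  structure(out,
            class = c("grf_trace", class(out)),
            participant_id = participant$participant_id,
            condition = condition,
            sampling_rate = fs, speed = speed,
            n_strides = length(strikes) - 1L,
            stride_durations_s = durations[-length(durations)])
}

#' Generate a synthetic finite-element element table
#'
#' Produces a per-element table standing in for a tibial finite-element
#' result: Young's moduli spanning the intramedullary, trabecular and
#' cortical classes, tissue labels and Poisson ratios from
#' [classify_tissue()], and von Mises strains whose cortical 90th percentile
#' equals the participant's target strain for the condition exactly (the
#' cortical strain cloud is rescaled onto the target, so the downstream
#' percentile summary recovers it). The reduced-condition target is the
#' preferred target lowered by the participant's `strain_reduction`.
#'
#' @inheritParams generate_trial
#' @param n_elements Number of elements (>= 10).
#' @return A tibble with columns `element_id`, `youngs_modulus_mpa`,
#'   `tissue`, `poisson`, `von_mises_strain_ue`, plus attributes
#'   `participant_id`, `condition`, `target_strain_ue`.
#' @export
generate_element_table <- function(participant, condition = c("preferred", "reduced10"),
                                   n_elements = 2000, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(nrow(participant) == 1)
  if (n_elements < 10) {
    abort("n_elements must be at least 10", class = "tibfrax_generation_error")
  }
  set.seed(child_seed(seed, "elements"))

  target <- participant$strain_preferred_ue *
    if (condition == "reduced10") 1 - participant$strain_reduction else 1

  n_im <- max(1L, round(0.15 * n_elements))
  n_tb <- max(1L, round(0.35 * n_elements))
  n_ct <- n_elements - n_im - n_tb
  moduli <- c(runif(n_im, 0.5, 6), runif(n_tb, 6, 8000), runif(n_ct, 8000, 22000))

  raw <- pmax(rnorm(n_ct, 1, 0.12), 0.05)
  ct_strain <- raw * target / quantile(raw, 0.9, type = 7, names = FALSE)
  strain <- c(runif(n_im + n_tb, 0, 0.6 * target), ct_strain)

  cls <- classify_tissue(moduli)
  tibble(
    element_id = seq_len(n_elements),
    youngs_modulus_mpa = moduli,
    tissue = cls$tissue,
    poisson = cls$poisson,
    von_mises_strain_ue = strain
  ) |>
    structure(participant_id = participant$participant_id,
              condition = condition, target_strain_ue = target)
}

#' Generate a long-format cohort outcomes table
#'
#' Draws every biomechanical outcome for every participant and condition
#' from the configured group-by-condition means with a participant random
#' intercept plus residual noise: for variable v,
#' `value = mean(group, condition) + b_i + e`, where `b_i` is shared across
#' the two conditions of a participant (SD `sqrt(intercept_share) * sd`) and
#' `e` is condition-specific (SD `sqrt(1 - intercept_share) * sd`). This is
#' exactly the random-intercept structure the downstream mixed model
#' assumes.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param variables Optional character vector restricting the variables
#'   generated; unknown names are an error.
#' @return A long tibble: `participant_id`, `stature_group`, `condition`,
#'   `variable`, `value`, `units`.
#' @export
generate_outcomes <- function(cohort, config = cohort_config(), seed = 1L,
                              variables = NULL) {
  set.seed(child_seed(seed, "outcomes"))
  spec <- config$outcomes
  if (!is.null(variables)) {
    unknown <- setdiff(variables, unique(spec$variable))
    if (length(unknown) > 0) {
      abort(paste("unknown outcome variable(s):", paste(unknown, collapse = ", ")),
            class = "tibfrax_config_error")
    }
    spec <- filter(spec, .data$variable %in% variables)
  }
  share <- config$intercept_share

  purrr::map_dfr(unique(spec$variable), function(v) {
    vs <- filter(spec, .data$variable == v)
    sd_b <- setNames(
      sqrt(share) * vs$sd[vs$condition == "preferred"],
      as.character(vs$stature_group[vs$condition == "preferred"])
    )
    b <- rnorm(nrow(cohort), 0, sd_b[as.character(cohort$stature_group)])
    purrr::map_dfr(c("preferred", "reduced10"), function(cond) {
      cell <- vs[vs$condition == cond, ]
      mu <- setNames(cell$mean, as.character(cell$stature_group))
      sde <- setNames(sqrt(1 - share) * cell$sd, as.character(cell$stature_group))
      g <- as.character(cohort$stature_group)
      tibble(
        participant_id = cohort$participant_id,
        stature_group = cohort$stature_group,
        condition = cond,
        variable = v,
        value = unname(mu[g]) + b + rnorm(nrow(cohort), 0, unname(sde[g])),
        units = cell$units[1]
      )
    })
  })
}
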