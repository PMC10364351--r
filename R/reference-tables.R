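#' Published cohort summary statistics
#'
#' Group-level summary statistics (mean and one standard deviation) for the
#' 20-woman treadmill cohort the package emulates: anthropometry per stature
#' group, representative-stride lengths per condition, and the biomechanical
#' outcomes (peak joint angles, peak joint moments, peak joint reaction
#' forces, peak vertical GRF, and 90th-percentile tibial von Mises strain)
#' per stature group and stride condition. These values calibrate the
#' synthetic-data generators and feed the table-style pooled summaries.
#'
#' @return
#' `reference_anthropometry()`: a tibble with one row per stature group and
#' variable (`age_yr`, `mass_kg`, `height_m`, `foot_length_m`,
#' `body_fat_pct`, `bmi`), columns `stature_group`, `n`, `variable`, `mean`,
#' `sd`.
#'
#' `reference_stride_lengths()`: a tibble with columns `stature_group`, `n`,
#' `condition`, `mean`, `sd` of representative stride length in metres.
#'
#' `reference_outcomes()`: a tibble with columns `variable`, `units`,
#' `stature_group`, `n`, `condition`, `mean`, `sd`.
#'
#' `reference_pooled()`: a tibble of cohort-pooled (all 20 women) means and
#' SDs per condition for the variables with a significant stride effect,
#' plus the back-transformed stress-fracture risks (in percent) for the
#' basic-combat-training (BCT) and recreational-training (RT) regimens,
#' columns `variable`, `units`, `condition`, `mean`, `sd` (`sd` is `NA` for
#' the risks, which are reported as geometric means).
#' @name reference_tables
NULL

group_tbl <- function(values) {
  # values: list(variable = c(S_mean, S_sd, M_mean, M_sd, T_mean, T_sd))
  purrr::imap_dfr(values, function(v, nm) {
    tibble(
      stature_group = factor(c("short", "medium", "tall"),
                             levels = c("short", "medium", "tall")),
      n = c(6L, 7L, 7L),
      variable = nm,
      mean = v[c(1, 3, 5)],
      sd = v[c(2, 4, 6)]
    )
  })
}

#' @rdname reference_tables
#' @export
reference_anthropometry <- function() {
  group_tbl(list(
    age_yr        = c(19.7, 1.0, 19.3, 0.7, 20.0, 1.1),
    mass_kg       = c(54.1, 5.4, 60.5, 3.9, 65.2, 4.7),
    height_m      = c(1.55, 0.03, 1.63, 0.02, 1.74, 0.02),
    foot_length_m = c(0.23, 0.01, 0.24, 0.01, 0.25, 0.01),
    body_fat_pct  = c(16.4, 2.4, 18.5, 4.0, 19.6, 1.5),
    bmi           = c(22.5, 2.4, 22.7, 1.9, 21.6, 1.7)
  ))
}

#' @rdname reference_tables
#' @export
reference_stride_lengths <- function() {
  pref <- group_tbl(list(stride_length_m = c(2.06, 0.15, 2.06, 0.12, 2.12, 0.09)))
  red  <- group_tbl(list(stride_length_m = c(1.85, 0.14, 1.86, 0.11, 1.90, 0.08)))
  bind_rows(
    mutate(pref, condition = "preferred"),
    mutate(red,  condition = "reduced10")
  ) |>
    select("stature_group", "n", "condition", "mean", "sd")
}

#' @rdname reference_tables
#' @export
reference_outcomes <- function() {
  # per variable: short pref (m, sd), short red, medium pref, medium red,
  # tall pref, tall red
  spec <- list(
    hip_adduction_angle        = list("deg", c(9.4, 5.9, 7.5, 4.0, 7.1, 2.4, 6.2, 3.1, 4.7, 3.4, 5.5, 3.7)),
    hip_flexion_angle          = list("deg", c(32.7, 6.8, 27.6, 6.7, 34.2, 3.3, 29.3, 7.4, 30.3, 7.1, 27.1, 9.1)),
    knee_flexion_angle         = list("deg", c(51.3, 7.0, 45.9, 8.5, 48.9, 4.2, 44.5, 3.5, 48.5, 4.2, 40.9, 4.6)),
    ankle_dorsiflexion_angle   = list("deg", c(14.3, 7.8, 12.4, 11.0, 15.8, 5.1, 17.0, 4.3, 16.9, 4.8, 13.6, 4.7)),
    hip_adduction_moment       = list("Nm/kg", c(1.4, 0.3, 1.3, 0.3, 1.5, 0.2, 1.5, 0.3, 1.6, 0.2, 1.4, 0.2)),
    hip_internal_rotation_moment = list("Nm/kg", c(0.9, 0.3, 0.7, 0.2, 1.0, 0.2, 0.9, 0.2, 0.9, 0.2, 0.8, 0.2)),
    knee_extension_moment      = list("Nm/kg", c(2.4, 0.5, 2.0, 0.6, 2.2, 0.3, 2.0, 0.4, 2.5, 0.6, 2.1, 0.6)),
    ankle_plantar_flexion_moment = list("Nm/kg", c(2.5, 0.2, 2.4, 0.4, 2.7, 0.2, 2.6, 0.3, 2.6, 0.3, 2.4, 0.2)),
    hip_jrf                    = list("BW", c(9.7, 1.9, 7.7, 0.7, 9.7, 1.2, 8.7, 1.7, 8.8, 1.3, 7.9, 1.4)),
    knee_jrf                   = list("BW", c(12.4, 0.6, 11.1, 1.4, 12.8, 1.1, 11.6, 1.1, 12.6, 0.8, 10.7, 0.6)),
    ankle_jrf                  = list("BW", c(12.7, 0.8, 12.1, 1.1, 13.1, 1.1, 12.1, 1.5, 12.1, 0.6, 10.7, 1.0)),
    peak_vertical_grf          = list("BW", c(2.5, 0.2, 2.4, 0.3, 2.4, 0.1, 2.3, 0.2, 2.4, 0.1, 2.3, 0.1)),
    tibial_strain_p90          = list("ue", c(5050, 1247, 4621, 1293, 5250, 795, 4611, 824, 4727, 539, 4059, 619))
  )
  purrr::imap_dfr(spec, function(s, nm) {
    v <- s[[2]]
    tidyr::expand_grid(
      stature_group = factor(c("short", "medium", "tall"),
                             levels = c("short", "medium", "tall")),
      condition = c("preferred", "reduced10")
    ) |>
      mutate(
        variable = nm, units = s[[1]],
        n = rep(c(6L, 7L, 7L), each = 2),
        mean = v[seq(1, 11, by = 2)],
        sd = v[seq(2, 12, by = 2)]
      ) |>
      select("variable", "units", "stature_group", "n", "condition", "mean", "sd")
  })
}

#' @rdname reference_tables
#' @export
reference_pooled <- function() {
  row <- function(variable, units, pref, pref_sd, red, red_sd) {
    tibble(variable = variable, units = units,
           condition = c("preferred", "reduced10"),
           mean = c(pref, red), sd = c(pref_sd, red_sd))
  }
  bind_rows(
    row("hip_flexion_angle", "deg", 32.7, 5.9, 28.0, 7.5),
    row("knee_flexion_angle", "deg", 49.5, 5.1, 43.6, 5.8),
    row("hip_adduction_moment", "Nm/kg", 1.5, 0.2, 1.4, 0.3),
    row("hip_internal_rotation_moment", "Nm/kg", 0.9, 0.2, 0.8, 0.2),
    row("knee_extension_moment", "Nm/kg", 2.3, 0.5, 2.0, 0.5),
    row("ankle_plantar_flexion_moment", "Nm/kg", 2.6, 0.3, 2.5, 0.3),
    row("hip_jrf", "BW", 9.4, 1.5, 8.1, 1.3),
    row("knee_jrf", "BW", 12.6, 1.2, 11.1, 1.1),
    row("ankle_jrf", "BW", 12.6, 0.9, 11.6, 1.5),
    row("tibial_strain_p90", "ue", 5007, 867, 4421, 922),
    row("sf_risk_bct", "pct", 2.3, NA_real_, 0.9, NA_real_),
    row("sf_risk_rt", "pct", 12.9, NA_real_, 5.5, NA_real_)
  )
}
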