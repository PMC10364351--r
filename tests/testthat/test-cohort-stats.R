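make_paired <- function(values_by_participant, delta = 0) {
  d <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:20),
                          condition = c("preferred", "reduced10"))
  d$stature_group <- rep(rep(c("short", "medium", "tall"), c(6, 7, 7)), each = 2)
  d$variable <- "v"
  d$value <- values_by_participant[d$participant_id] +
    delta * (d$condition == "reduced10")
  d
}

test_that("a constant within-subject shift is recovered exactly", {
  base <- stats::setNames(seq(10, 48, by = 2), sprintf("P%02d", 1:20))
  fit <- quiet_fit(make_paired(base, delta = -5), "v")
  fx <- tidy(fit, "fixed")
  expect_equal(fx$estimate[fx$term == "conditionreduced10"], -5,
               tolerance = 1e-6)
  expect_false(fit$interaction_retained)
  expect_null(fit$posthoc)
})

test_that("an injected group-by-condition interaction is retained with post hoc", {
  base <- stats::setNames(seq(10, 48, by = 2), sprintf("P%02d", 1:20))
  d <- make_paired(base)
  # condition effect differs strongly by group, tiny noise
  eff <- c(short = 0, medium = -5, tall = -15)
  set.seed(3)
  d$value <- d$value + eff[d$stature_group] * (d$condition == "reduced10") +
    rnorm(nrow(d), 0, 0.01)
  fit <- quiet_fit(d, "v")
  expect_true(fit$interaction_retained)
  expect_s3_class(fit$posthoc, "tbl_df")
  expect_equal(nrow(fit$posthoc), 3)          # one contrast per stature group
  expect_true(all(fit$posthoc$p.adj >= fit$posthoc$p.value))
  expect_equal(glance(fit)$p_interaction, fit$p_interaction)
})

test_that("participants missing a condition are excluded with a warning", {
  base <- stats::setNames(seq(10, 48, by = 2), sprintf("P%02d", 1:20))
  set.seed(9)
  d <- make_paired(base, delta = -3)
  d$value <- d$value + rnorm(nrow(d), 0, 1)
  d <- d[-1, ]  # drop one condition of P01
  expect_warning(fit <- suppressMessages(fit_stride_stature_model(d, "v")),
                 "excluded")
  expect_equal(fit$n_participants, 19)
})

test_that("log transform of risk round-trips and pools geometrically", {
  x <- c(0.023, 0.129, 0.009)
  expect_equal(back_transform_risk(log_transform_risk(x)), x)
  expect_equal(risk_geomean(c(1, 100))$geomean, 10)
  g <- risk_geomean(c(0.01, 0.05, 0.2))
  expect_true(g$lower < g$geomean && g$geomean < g$upper)
  expect_warning(log_transform_risk(c(0, 0.1)), "floored")
  expect_error(log_transform_risk(-0.1), class = "tibfrax_input_error")
})

test_that("anthropometry ANOVA matches closed-form F on a toy table", {
  toy <- tibble::tibble(
    stature_group = factor(rep(c("short", "medium", "tall"), each = 2)),
    age_yr = c(0, 2, 1, 3, 2, 4)
  )
  # group means 1, 2, 3; SSB = 4 (df 2); SSW = 6 (df 3); F = 2 / 2 = 1
  res <- anova_anthropometry(toy, variables = "age_yr")
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, stats::pf(1, 2, 3, lower.tail = FALSE))

  # identical groups: no between-group variance
  same <- tibble::tibble(
    stature_group = factor(rep(c("short", "medium", "tall"), each = 3)),
    age_yr = rep(c(18, 20, 22), times = 3)
  )
  res2 <- anova_anthropometry(same, variables = "age_yr")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  # means separated by 10 SDs
  far <- tibble::tibble(
    stature_group = factor(rep(c("short", "medium", "tall"), c(6, 7, 7))),
    age_yr = rep(c(0, 10, 20), c(6, 7, 7)) + rnorm(20, 0, 1)
  )
  expect_lt(anova_anthropometry(far, variables = "age_yr")$p_value, 0.001)

  expect_error(anova_anthropometry(toy[-1, ], variables = "age_yr"),
               class = "tibfrax_input_error")
})

test_that("pooled summaries weight group means by group size", {
  ref <- reference_outcomes()
  expect_equal(pooled_summary(ref, "tibial_strain_p90", "preferred")$mean,
               5007, tolerance = 0.001)
  expect_equal(pooled_summary(ref, "tibial_strain_p90", "reduced10")$mean,
               4421, tolerance = 0.01)
  expect_equal(round(pooled_summary(ref, "hip_jrf", "preferred")$mean, 1), 9.4)
  expect_equal(round(pooled_summary(ref, "hip_jrf", "reduced10")$mean, 1), 8.1)

  # equal group sizes and equal means: pooled mean is that mean
  eq <- tibble::tibble(variable = "x", condition = "preferred",
                       n = c(5, 5, 5), mean = c(7, 7, 7))
  expect_equal(pooled_summary(eq, "x", "preferred")$mean, 7)

  # raw long data: plain mean and SD
  raw <- tibble::tibble(variable = "x", condition = "preferred",
                        value = c(1, 2, 3, 4))
  expect_equal(pooled_summary(raw, "x", "preferred")$mean, 2.5)
  expect_equal(pooled_summary(raw, "x", "preferred")$sd, sd(1:4))
  expect_error(pooled_summary(raw, "y", "preferred"),
               class = "tibfrax_input_error")
})

test_that("percent reductions reproduce the reported integers", {
  expect_equal(percent_reduction(32.7, 28.0), 14)
  expect_equal(percent_reduction(49.5, 43.6), 12)
  expect_equal(percent_reduction(5007, 4421), 12)
  expect_equal(percent_reduction(3, 3), 0)
  expect_error(percent_reduction(0, 1), class = "tibfrax_input_error")
})

test_that("per-participant reductions report strain and risk together", {
  strain <- tibble::tibble(
    participant_id = rep(c("P01", "P02"), each = 2),
    condition = rep(c("preferred", "reduced10"), 2),
    strain_p90_ue = c(5000, 4400, 4800, 4800)
  )
  risks <- tidyr::expand_grid(
    participant_id = c("P01", "P02"),
    condition = c("preferred", "reduced10"),
    regimen = c("bct", "rt")
  ) |>
    dplyr::mutate(risk = c(0.02, 0.10, 0.01, 0.05, 0.03, 0.12, 0.035, 0.12))
  red <- per_participant_reductions(strain, risks)
  expect_equal(nrow(red), 4)
  p1 <- red[red$participant_id == "P01", ]
  expect_equal(unique(p1$strain_reduction_pct), 12)
  expect_equal(p1$risk_reduction_pct[p1$regimen == "bct"], 50)
  expect_false(any(p1$risk_increased))
  p2 <- red[red$participant_id == "P02", ]
  expect_equal(unique(p2$strain_reduction_pct), 0)
  expect_true(p2$risk_increased[p2$regimen == "bct"])  # 0.03 -> 0.035

  # identical trajectories: zero reduction everywhere
  risks0 <- risks |> dplyr::mutate(risk = 0.05)
  red0 <- per_participant_reductions(strain, risks0)
  expect_true(all(red0$risk_reduction_pct == 0))

  # a participant missing one condition is skipped with a warning
  expect_warning(
    red1 <- per_participant_reductions(strain[-1, ], risks),
    "skipping"
  )
  expect_equal(unique(red1$participant_id), "P02")
})
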