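#' Fit the stride-by-stature mixed-effects model for one outcome
#'
#' Fits the linear mixed-effects model used for every biomechanical outcome:
#' fixed categorical effects of stride condition, stature group and their
#' interaction, plus a participant random intercept for within-subject
#' dependence. The interaction is tested first with a Wald F-test
#' (Kenward-Roger degrees of freedom by default); if its p-value is at or
#' above `alpha` the interaction is removed and the main effects are
#' re-evaluated in the reduced model. When the interaction is retained, a
#' post hoc pairwise comparison of the two stride conditions is run within
#' each stature group on the estimated marginal means, with Holm-Bonferroni
#' adjustment. With only two stride levels a significant stride main effect
#' needs no post hoc contrast, so none is produced in that branch.
#'
#' @param outcomes Long outcomes tibble (`participant_id`, `stature_group`,
#'   `condition`, `variable`, `value`), e.g. from [generate_outcomes()].
#' @param variable Which outcome variable to model.
#' @param alpha Significance level for the interaction-dropping rule.
#' @param ddf Degrees-of-freedom method: `"Kenward-Roger"` (default) or
#'   `"Satterthwaite"`.
#' @return An object of class `stride_fit`; see [tidy.stride_fit()] and
#'   [glance.stride_fit()].
#' @export
fit_stride_stature_model <- function(outcomes, variable, alpha = 0.05,
                                     ddf = c("Kenward-Roger", "Satterthwaite")) {
  ddf <- match.arg(ddf)
  stopifnot(alpha > 0, alpha < 1)
  dat <- outcomes |>
    filter(.data$variable == !!variable) |>
    mutate(condition = factor(.data$condition,
                              levels = c("preferred", "reduced10")),
           stature_group = factor(.data$stature_group),
           participant_id = factor(.data$participant_id))
  if (nrow(dat) == 0) {
    abort(paste0("variable '", variable, "' not present in outcomes"),
          class = "tibfrax_input_error")
  }
  complete <- dat |>
    count(.data$participant_id) |>
    filter(.data$n == 2) |>
    pull(.data$participant_id)
  if (length(complete) < nrow(distinct(dat, .data$participant_id))) {
    warn("participants missing a condition were excluded from the model")
    dat <- filter(dat, .data$participant_id %in% complete)
  }

  full <- lmerTest::lmer(value ~ condition * stature_group + (1 | participant_id),
                         data = dat)
  a_full <- as.data.frame(stats::anova(full, type = 3, ddf = ddf))
  p_int <- a_full["condition:stature_group", "Pr(>F)"]

  interaction_retained <- is.finite(p_int) && p_int < alpha
  if (interaction_retained) {
    fit <- full
    a_tab <- a_full
  } else {
    fit <- lmerTest::lmer(value ~ condition + stature_group + (1 | participant_id),
                          data = dat)
    a_tab <- as.data.frame(stats::anova(fit, type = 3, ddf = ddf))
  }

  posthoc <- NULL
  if (interaction_retained) {
    emm <- emmeans::emmeans(fit, ~ condition | stature_group,
                            lmer.df = tolower(ddf))
    pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "none"))
    pr$p.adj <- stats::p.adjust(pr$p.value, method = "holm")
    posthoc <- as_tibble(pr)
  }

  structure(
    list(
      variable = variable, alpha = alpha, ddf = ddf,
      n_participants = length(unique(dat$participant_id)),
      full_model = full, model = fit,
      anova_full = a_full, anova = a_tab,
      p_interaction = unname(p_int),
      interaction_retained = interaction_retained,
      posthoc = posthoc
    ),
    class = "stride_fit"
  )
}

#' @export
print.stride_fit <- function(x, ...) {
  cat("Stride-by-stature mixed model for '", x$variable, "'\n", sep = "")
  cat("  participants:", x$n_participants, " ddf:", x$ddf, "\n")
  cat("  interaction", if (x$interaction_retained) "retained" else
    sprintf("dropped (p = %.3f); main effects re-evaluated", x$p_interaction), "\n")
  print(round(as.matrix(x$anova), 4))
  invisible(x)
}

#' Tidy a stride-by-stature model fit
#'
#' @param x A `stride_fit` from [fit_stride_stature_model()].
#' @param effects `"anova"` (Wald F table of the final model, default) or
#'   `"fixed"` (fixed-effect coefficients).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stride_fit
#' @export
tidy.stride_fit <- function(x, effects = c("anova", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "anova") {
    a <- x$anova
    tibble(term = rownames(a),
           statistic = a$`F value`, num_df = a$NumDF, den_df = a$DenDF,
           p_value = a$`Pr(>F)`)
  } else {
    co <- as.data.frame(summary(x$model)$coefficients)
    tibble(term = rownames(co), estimate = co$Estimate,
           std_error = co$`Std. Error`, df = co$df,
           statistic = co$`t value`, p_value = co$`Pr(>|t|)`)
  }
}

#' Glance at a stride-by-stature model fit
#'
#' @param x A `stride_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variable, participant count, df method, whether
#'   the interaction was retained, and the stride / stature / interaction
#'   p-values (interaction `NA` when dropped, per the reporting convention).
#' @method glance stride_fit
#' @export
glance.stride_fit <- function(x, ...) {
  a <- x$anova
  tibble(
    variable = x$variable,
    n_participants = x$n_participants,
    ddf = x$ddf,
    interaction_retained = x$interaction_retained,
    p_stride = a["condition", "Pr(>F)"],
    p_stature = a["stature_group", "Pr(>F)"],
    p_interaction = if (x$interaction_retained) x$p_interaction else NA_real_
  )
}

#' Log-transform stress-fracture risks
#'
#' Natural-log transform applied to risks before mixed-effects analysis
#' (risks are right-skewed). Zeros are floored at `epsilon` with a warning;
#' negative risks are an error. [back_transform_risk()] is the antilog, and
#' [risk_geomean()] reports the back-transformed (geometric) mean with a
#' t-based confidence interval on the log scale.
#'
#' @param risks Numeric vector of non-negative risks.
#' @param epsilon Floor applied to zero risks before taking logs.
#' @return `log_transform_risk()`: the natural logs.
#' @export
log_transform_risk <- function(risks, epsilon = 1e-6) {
  if (any(risks < 0)) abort("risks must be non-negative",
                            class = "tibfrax_input_error")
  if (any(risks == 0)) {
    warn(sprintf("%d zero risks floored at epsilon", sum(risks == 0)))
    risks <- pmax(risks, epsilon)
  }
  log(risks)
}

#' @rdname log_transform_risk
#' @param log_risks Values on the natural-log scale.
#' @return `back_transform_risk()`: the antilogs.
#' @export
back_transform_risk <- function(log_risks) exp(log_risks)

#' @rdname log_transform_risk
#' @param conf Confidence level for the interval.
#' @return `risk_geomean()`: a one-row tibble `geomean`, `lower`, `upper`,
#'   `n` on the original risk scale.
#' @export
risk_geomean <- function(risks, conf = 0.95, epsilon = 1e-6) {
  lx <- log_transform_risk(risks, epsilon)
  n <- length(lx)
  m <- mean(lx)
  half <- if (n > 1) qt(1 - (1 - conf) / 2, n - 1) * sd(lx) / sqrt(n) else 0
  tibble(geomean = exp(m), lower = exp(m - half), upper = exp(m + half), n = n)
}

#' One-way ANOVA on cohort anthropometry
#'
#' Tests each anthropometric variable for differences among the three
#' stature groups with a one-way analysis of variance.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param variables Columns to test.
#' @return A tibble `variable`, `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_anthropometry <- function(cohort,
                                variables = c("age_yr", "mass_kg", "height_m",
                                              "foot_length_m", "body_fat_pct")) {
  sizes <- table(cohort$stature_group)
  if (any(sizes < 2)) {
    abort("each stature group needs at least 2 members",
          class = "tibfrax_input_error")
  }
  purrr::map_dfr(variables, function(v) {
    fit <- aov(cohort[[v]] ~ cohort$stature_group)
    s <- summary(fit)[[1]]
    tibble(variable = v, statistic = s$`F value`[1],
           df1 = s$Df[1], df2 = s$Df[2], p_value = s$`Pr(>F)`[1])
  })
}

#' Cohort-pooled summary of an outcome
#'
#' Pools an outcome over all participants in one condition. Given raw
#' long-format outcomes (a `value` column), returns their mean and SD. Given
#' a group-level summary table (columns `mean` and `n`), returns the
#' group-size-weighted pooled mean (SD is `NA`, as the within-group spread
#' is not recoverable from group means alone).
#'
#' @param x A long outcomes tibble or a group-summary tibble such as
#'   [reference_outcomes()].
#' @param variable Outcome variable name.
#' @param condition `"preferred"` or `"reduced10"`.
#' @return A one-row tibble `variable`, `condition`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' pooled_summary(reference_outcomes(), "tibial_strain_p90", "preferred")
pooled_summary <- function(x, variable, condition) {
  sel <- filter(x, .data$variable == !!variable, .data$condition == !!condition)
  if (nrow(sel) == 0) abort("empty selection", class = "tibfrax_input_error")
  if ("value" %in% names(sel)) {
    tibble(variable = variable, condition = condition, n = nrow(sel),
           mean = mean(sel$value), sd = sd(sel$value))
  } else {
    tibble(variable = variable, condition = condition, n = sum(sel$n),
           mean = sum(sel$n * sel$mean) / sum(sel$n), sd = NA_real_)
  }
}

#' Percent reduction between conditions
#'
#' @param pref_value,reduced_value Values under the preferred and reduced
#'   stride lengths (preferred must be non-zero).
#' @param digits Rounding; default nearest integer, the convention used for
#'   reported percentages.
#' @return `round(100 * (pref - reduced) / pref, digits)`.
#' @export
#' @examples
#' percent_reduction(49.5, 43.6)  # 12
percent_reduction <- function(pref_value, reduced_value, digits = 0) {
  if (any(pref_value == 0)) {
    abort("preferred-condition value must be non-zero",
          class = "tibfrax_input_error")
  }
  round(100 * (pref_value - reduced_value) / pref_value, digits)
}

#' Per-participant strain and risk reductions
#'
#' Builds the subject-level report of percent reductions in
#' 90th-percentile tibial strain and in final stress-fracture risk (per
#' regimen) between the preferred and reduced stride conditions, flagging
#' participants whose risk increased. Participants missing either condition
#' are skipped with a warning.
#'
#' @param strain_summaries Tibble `participant_id`, `condition`,
#'   `strain_p90_ue` (e.g. bound rows of [cortical_strain_p90()]).
#' @param risks Tibble `participant_id`, `condition`, `regimen`, `risk`
#'   (final failure probability per regimen).
#' @return A tibble `participant_id`, `strain_reduction_pct`, `regimen`,
#'   `risk_reduction_pct`, `risk_increased`.
#' @export
per_participant_reductions <- function(strain_summaries, risks) {
  strain_w <- strain_summaries |>
    select("participant_id", "condition", "strain_p90_ue") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "strain_p90_ue")
  incomplete <- strain_w$participant_id[
    is.na(strain_w$preferred) | is.na(strain_w$reduced10)]
  if (length(incomplete) > 0) {
    warn(paste("skipping participants missing a condition:",
               paste(incomplete, collapse = ", ")))
    strain_w <- filter(strain_w, !.data$participant_id %in% incomplete)
  }
  strain_red <- strain_w |>
    mutate(strain_reduction_pct =
             100 * (.data$preferred - .data$reduced10) / .data$preferred) |>
    select("participant_id", "strain_reduction_pct")

  risk_red <- risks |>
    filter(!.data$participant_id %in% incomplete) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "risk") |>
    mutate(risk_reduction_pct = ifelse(
      .data$preferred > 0,
      100 * (.data$preferred - .data$reduced10) / .data$preferred,
      NA_real_),
      risk_increased = .data$reduced10 > .data$preferred) |>
    select("participant_id", "regimen", "risk_reduction_pct", "risk_increased")

  left_join(strain_red, risk_red, by = "participant_id")
}
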