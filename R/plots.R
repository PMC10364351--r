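#' Plot the stride-selection geometry of one trace
#'
#' Overlays every time-normalised stride waveform (grey), the pointwise
#' median waveform (black), and the selected representative stride (colour),
#' the visual counterpart of the median-distance ranking.
#'
#' @inheritParams select_representative_preferred
#' @return A ggplot object.
#' @export
plot_stride_selection <- function(trace, threshold_n = 25, debounce = 10,
                                  metric = c("rms", "mean-abs")) {
  strides <- segment_strides(trace, threshold_n, debounce)
  waves <- purrr::map(strides$samples, resample_to_100)
  ranking <- rank_by_median_distance(waves, metric = metric)
  best <- ranking$stride[1]
  med <- median_waveform(waves)

  long <- purrr::imap_dfr(waves, function(w, i) {
    tibble(stride = i, t_pct = 0:99, force_n = w)
  })
  ggplot(long, aes(x = .data$t_pct, y = .data$force_n, group = .data$stride)) +
    geom_line(colour = "grey70", linewidth = 0.3) +
    geom_line(data = tibble(stride = 0L, t_pct = 0:99, force_n = med),
              colour = "black", linewidth = 0.9) +
    geom_line(data = filter(long, .data$stride == best),
              colour = "#d95f02", linewidth = 0.9) +
    labs(x = "stride time (%)", y = "vertical GRF (N)",
         title = "Time-normalised strides, median (black), selected (orange)") +
    theme_minimal()
}

#' Plot stress-fracture risk trajectories
#'
#' Day-indexed cumulative failure probability per participant, coloured by
#' stride condition and facetted by regimen.
#'
#' @param trajectories The `trajectories` tibble of a [run_pipeline()]
#'   result (or any tibble with `day`, `risk`, `condition`, `regimen`,
#'   `participant_id`).
#' @return A ggplot object.
#' @export
plot_risk_trajectories <- function(trajectories) {
  ggplot(trajectories,
         aes(x = .data$day, y = 100 * .data$risk, colour = .data$condition,
             group = interaction(.data$participant_id, .data$condition))) +
    geom_line(alpha = 0.5, linewidth = 0.3) +
    facet_wrap(~regimen, scales = "free_x") +
    labs(x = "training day", y = "stress-fracture risk (%)",
         colour = "stride") +
    theme_minimal()
}

#' Plot per-participant strain and risk reductions
#'
#' Subject-level percent reductions in tibial strain and in final
#' stress-fracture risk for each regimen, between the preferred and
#' 10%-reduced stride conditions.
#'
#' @param reductions A [per_participant_reductions()] tibble.
#' @return A ggplot object.
#' @export
plot_participant_reductions <- function(reductions) {
  long <- bind_rows(
    reductions |>
      distinct(.data$participant_id, .data$strain_reduction_pct) |>
      transmute(.data$participant_id, measure = "strain",
                reduction_pct = .data$strain_reduction_pct),
    reductions |>
      transmute(.data$participant_id,
                measure = paste0("risk (", .data$regimen, ")"),
                reduction_pct = .data$risk_reduction_pct)
  )
  ggplot(long, aes(x = .data$participant_id, y = .data$reduction_pct,
                   fill = .data$measure)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "reduction (%)", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Autoplot a stride-by-stature model fit
#'
#' Condition-by-stature group means of the modelled outcome with normal
#' 95% confidence intervals of the group means, the standard view of the
#' stride and stature effects.
#'
#' @param object A `stride_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stride_fit
#' @export
autoplot.stride_fit <- function(object, ...) {
  dat <- object$model@frame |> as_tibble()
  summ <- dat |>
    group_by(.data$condition, .data$stature_group) |>
    summarise(mean = mean(.data$value),
              se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  ggplot(summ, aes(x = .data$condition, y = .data$mean,
                   colour = .data$stature_group,
                   group = .data$stature_group)) +
    geom_point(position = position_dodge(0.2)) +
    geom_line(position = position_dodge(0.2)) +
    geom_errorbar(aes(ymin = .data$mean - 1.96 * .data$se,
                      ymax = .data$mean + 1.96 * .data$se),
                  width = 0.1, position = position_dodge(0.2)) +
    labs(title = object$variable, x = "stride condition", y = "group mean") +
    theme_minimal()
}
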