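#' Segment a vertical-GRF trace into strides
#'
#' Identifies foot strikes as upward crossings of a force threshold
#' (default 25 N) and delimits each stride from one foot strike to the next.
#' Crossings are debounced: a stance registers only after `debounce`
#' consecutive samples above the threshold, and flight after `debounce`
#' consecutive samples below, which guards against signal chatter near the
#' threshold. Incomplete leading and trailing cycles are discarded.
#'
#' @param trace A `grf_trace` tibble (columns `time_s`, `force_n`) or any
#'   data frame with a `force_n` column.
#' @param threshold_n Vertical-GRF threshold in newtons.
#' @param debounce Minimum run length (samples) above/below the threshold to
#'   switch between flight and stance.
#' @param sampling_rate Sampling rate in Hz; defaults to the trace attribute,
#'   else 1000.
#' @param speed Belt speed in m/s used for stride length; defaults to the
#'   trace attribute, else 3.0.
#' @return A tibble with one row per stride: `stride` (1-based index),
#'   `start`, `end` (0-based half-open sample indices), `duration_s`,
#'   `stride_length_m`, and `samples` (list column of force values). Empty
#'   (with a warning) if fewer than two foot strikes are found.
#' @export
segment_strides <- function(trace, threshold_n = 25, debounce = 10,
                            sampling_rate = NULL, speed = NULL) {
  force <- trace$force_n
  if (length(force) == 0) abort("trace is empty", class = "tibfrax_input_error")
  sampling_rate <- sampling_rate %||% attr(trace, "sampling_rate") %||% 1000
  speed <- speed %||% attr(trace, "speed") %||% 3.0

  strikes <- detect_foot_strikes(force, threshold_n, debounce)
  if (length(strikes) < 2) {
    warn("fewer than two foot strikes; no complete stride in trace")
    return(tibble(stride = integer(), start = integer(), end = integer(),
                  duration_s = numeric(), stride_length_m = numeric(),
                  samples = list()))
  }
  start <- strikes[-length(strikes)]
  end <- strikes[-1]
  tibble(
    stride = seq_along(start),
    start = start, end = end,
    duration_s = (end - start) / sampling_rate,
    stride_length_m = (end - start) / sampling_rate * speed,
    samples = purrr::map2(start, end, function(s, e) force[(s + 1):e])
  )
}

# State machine over the force signal: returns 0-based indices of the first
# sample of each debounced above-threshold run (the foot strikes).
detect_foot_strikes <- function(force, threshold_n, debounce) {
  above <- force > threshold_n
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  strikes <- integer(0)
  in_stance <- FALSE
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && !in_stance && r$lengths[j] >= debounce) {
      strikes <- c(strikes, starts[j] - 1L)   # 0-based
      in_stance <- TRUE
    } else if (!r$values[j] && in_stance && r$lengths[j] >= debounce) {
      in_stance <- FALSE
    }
  }
  strikes
}

#' Resample one stride to 100 points
#'
#' Linearly interpolates a stride's force samples onto 100 uniformly spaced
#' time fractions `k/100, k = 0..99` of the stride (half-open: the start of
#' the next stride is not included), so strides of different durations are
#' represented by the same number of points.
#'
#' @param samples Numeric vector of force values for one stride, or a one-row
#'   stride tibble from [segment_strides()].
#' @return A numeric vector of length 100.
#' @export
resample_to_100 <- function(samples) {
  if (is.data.frame(samples)) samples <- samples$samples[[1]]
  n <- length(samples)
  if (n < 2) abort("stride must contain at least 2 samples",
                   class = "tibfrax_input_error")
  xout <- pmin((0:99) / 100 * n, n - 1)
  approx(x = seq_len(n) - 1, y = samples, xout = xout)$y
}

#' Pointwise median waveform
#'
#' @param waveforms A list of length-100 numeric vectors (or a matrix with
#'   100 columns, one row per stride).
#' @return A numeric vector of length 100: the median force at each of the
#'   100 normalised time points.
#' @export
median_waveform <- function(waveforms) {
  m <- waveform_matrix(waveforms)
  apply(m, 2, median)
}

waveform_matrix <- function(waveforms) {
  if (is.matrix(waveforms)) return(waveforms)
  if (length(waveforms) == 0) abort("no waveforms supplied",
                                    class = "tibfrax_input_error")
  do.call(rbind, waveforms)
}

#' Rank strides by closeness to the median waveform
#'
#' Computes the distance of each normalised waveform to the pointwise median
#' waveform and ranks the strides best-first. The default metric is the
#' root-mean-square pointwise difference; mean absolute difference is also
#' available. Ties are broken by the earlier stride index.
#'
#' @inheritParams median_waveform
#' @param metric `"rms"` (default) or `"mean-abs"`.
#' @return A tibble `stride`, `distance`, `rank`, ordered best first.
#' @export
rank_by_median_distance <- function(waveforms, metric = c("rms", "mean-abs")) {
  metric <- match.arg(metric)
  m <- waveform_matrix(waveforms)
  med <- apply(m, 2, median)
  d <- if (metric == "rms") {
    sqrt(rowMeans(sweep(m, 2, med)^2))
  } else {
    rowMeans(abs(sweep(m, 2, med)))
  }
  ord <- order(d, seq_along(d))
  tibble(stride = ord, distance = d[ord], rank = seq_along(ord))
}

#' Select the representative stride for the preferred condition
#'
#' Segments the trace, time-normalises every stride to 100 points, computes
#' the pointwise median waveform, and returns the stride whose waveform is
#' closest to the median.
#'
#' @inheritParams segment_strides
#' @param metric Distance metric, see [rank_by_median_distance()].
#' @return A one-row stride tibble (as from [segment_strides()]) with an
#'   additional `distance` column, and the full ranking in attribute
#'   `ranking`.
#' @export
select_representative_preferred <- function(trace, threshold_n = 25,
                                            debounce = 10,
                                            metric = c("rms", "mean-abs"),
                                            sampling_rate = NULL, speed = NULL) {
  strides <- segment_strides(trace, threshold_n, debounce, sampling_rate, speed)
  if (nrow(strides) < 2) {
    abort("need at least 2 strides to select a representative stride",
          class = "tibfrax_input_error")
  }
  waves <- purrr::map(strides$samples, resample_to_100)
  ranking <- rank_by_median_distance(waves, metric = metric)
  best <- ranking$stride[1]
  out <- strides[best, ] |> mutate(distance = ranking$distance[1])
  structure(out, ranking = ranking)
}

#' Select the representative stride for the 10%-reduced condition
#'
#' Segments the reduced-condition trace and converts each stride duration to
#' a stride length (duration times belt speed). Returns the stride whose
#' length is closest to `(1 - target_reduction)` times the reference
#' (preferred-condition) stride length; exact ties are resolved in favour of
#' the stride closest to the median waveform.
#'
#' @inheritParams select_representative_preferred
#' @param reference_length_m Stride length (m) of the representative
#'   preferred-condition stride, or a one-row stride tibble holding it.
#' @param target_reduction Targeted fractional stride-length reduction
#'   (default 0.10).
#' @return A one-row stride tibble with additional columns
#'   `target_length_m` and `length_error_m`; full candidate table in
#'   attribute `candidates`.
#' @export
select_representative_reduced <- function(trace, reference_length_m,
                                          target_reduction = 0.10,
                                          threshold_n = 25, debounce = 10,
                                          metric = c("rms", "mean-abs"),
                                          sampling_rate = NULL, speed = NULL) {
  if (is.data.frame(reference_length_m)) {
    reference_length_m <- reference_length_m$stride_length_m[1]
  }
  stopifnot(reference_length_m > 0)
  strides <- segment_strides(trace, threshold_n, debounce, sampling_rate, speed)
  if (nrow(strides) < 2) {
    abort("need at least 2 strides to select a representative stride",
          class = "tibfrax_input_error")
  }
  target <- (1 - target_reduction) * reference_length_m
  err <- abs(strides$stride_length_m - target)

  waves <- purrr::map(strides$samples, resample_to_100)
  ranking <- rank_by_median_distance(waves, metric = metric)
  med_rank <- ranking$rank[order(ranking$stride)]   # rank per stride index

  ord <- order(err, med_rank, strides$stride)
  best <- ord[1]
  out <- strides[best, ] |>
    mutate(target_length_m = target, length_error_m = err[best])
  structure(out, candidates = strides |>
              mutate(length_error_m = err, median_rank = med_rank) |>
              arrange(.data$length_error_m, .data$median_rank))
}
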