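#' Read and write vertical-GRF traces
#'
#' Traces are stored as two-column delimited text (`time_s`, `force_n`) with
#' a JSON sidecar (`<path>.json`) carrying the participant id, condition,
#' sampling rate and belt speed, so a trace round-trips with its metadata.
#'
#' @param trace A `grf_trace` tibble (see [generate_trial()]).
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_trace()`: `path`, invisibly. `read_trace()`: a `grf_trace`
#'   tibble.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("time_s", "force_n")], path,
                   row.names = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required to write trace sidecars")
  }
  meta <- list(
    participant_id = attr(trace, "participant_id"),
    condition = attr(trace, "condition"),
    sampling_rate = attr(trace, "sampling_rate"),
    speed = attr(trace, "speed"),
    n_strides = attr(trace, "n_strides")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  structure(out, class = c("grf_trace", class(out)),
            participant_id = meta$participant_id,
            condition = meta$condition,
            sampling_rate = meta$sampling_rate %||% 1000,
            speed = meta$speed %||% 3.0,
            n_strides = meta$n_strides)
}

#' Read and write long-format cohort outcome tables
#'
#' Outcomes are stored as CSV with columns `participant_id`,
#' `stature_group`, `condition`, `variable`, `value`, `units`.
#'
#' @param outcomes A long outcomes tibble, e.g. from [generate_outcomes()].
#' @param path CSV file path.
#' @return `write_outcomes()`: `path`, invisibly. `read_outcomes()`: a
#'   tibble with `stature_group` restored as an ordered factor.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  lev <- intersect(c("short", "medium", "tall"), unique(out$stature_group))
  out$stature_group <- factor(out$stature_group, levels = lev)
  out
}
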