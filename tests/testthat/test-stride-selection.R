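test_that("segmentation finds the constructed foot strikes", {
  px <- make_pulse_trace(n_pulses = 4)
  s <- segment_strides(px$trace)
  expect_equal(nrow(s), 3)
  # endpoints agree with an independent crossing scan; the crossing sits a
  # fixed 1 sample after pulse onset, where the half-sine first exceeds 25 N
  oracle <- brute_force_strikes(px$trace$force_n)
  expect_equal(s$start, oracle[1:3])
  expect_equal(s$end, oracle[2:4])
  expect_equal(s$start, px$strikes[1:3] + 1)
  expect_equal(s$duration_s, rep(0.7, 3))
  expect_equal(s$stride_length_m, rep(2.1, 3))
})

test_that("sub-threshold traces yield no strides, with a warning", {
  flat <- tibble::tibble(time_s = (0:999) / 1000, force_n = rep(10, 1000))
  expect_warning(s <- segment_strides(flat), "fewer than two")
  expect_equal(nrow(s), 0)
})

test_that("segmentation is idempotent and insensitive to padding", {
  px <- make_pulse_trace(n_pulses = 5, lead_s = 0.2)
  s1 <- segment_strides(px$trace)
  pad <- tibble::tibble(time_s = 0, force_n = rep(0, 500))
  padded <- tibble::tibble(
    time_s = seq_len(nrow(px$trace) + 1000) / 1000,
    force_n = c(pad$force_n, px$trace$force_n, pad$force_n)
  )
  s2 <- segment_strides(padded)
  expect_equal(nrow(s2), nrow(s1))
  expect_equal(s2$start - 500, s1$start)
  expect_equal(s2$duration_s, s1$duration_s)
  expect_lte(sum(s1$duration_s), max(px$trace$time_s) + 1e-3)
})

test_that("resampling to 100 points preserves lines and constants", {
  expect_equal(resample_to_100(rep(7.5, 40)), rep(7.5, 100))
  expect_equal(resample_to_100(as.numeric(0:99)), as.numeric(0:99),
               tolerance = 1e-12)
  # different durations both map to 100 points
  expect_length(resample_to_100(sin(seq(0, pi, length.out = 650))), 100)
  expect_length(resample_to_100(sin(seq(0, pi, length.out = 720))), 100)
  expect_error(resample_to_100(5), class = "tibfrax_input_error")
})

test_that("median waveform is the pointwise median", {
  w <- list(rep(1, 100), rep(5, 100), rep(9, 100))
  expect_equal(median_waveform(w), rep(5, 100))
  expect_equal(median_waveform(list(rep(2, 100), rep(4, 100))), rep(3, 100))
  expect_equal(median_waveform(w[2]), rep(5, 100))
  expect_error(median_waveform(list()), class = "tibfrax_input_error")
})

test_that("median-distance ranking orders strides and breaks ties by index", {
  w <- list(rep(5, 100), rep(5.1, 100), rep(9, 100))
  r <- rank_by_median_distance(w)
  expect_equal(r$stride, c(2, 1, 3))
  expect_equal(r$distance, c(0, 0.1, 3.9))

  # duplicated best stride: earlier index wins
  w2 <- list(rep(5, 100), rep(5, 100), rep(9, 100))
  expect_equal(rank_by_median_distance(w2)$stride[1], 1)

  expect_equal(rank_by_median_distance(w[1])$stride, 1)
})

test_that("preferred selector equals the exhaustive oracle on random traces", {
  set.seed(101)
  for (trial in 1:30) {
    n <- sample(4:12, 1)
    px <- make_pulse_trace(
      n_pulses = n, stance_s = runif(1, 0.2, 0.3),
      flight_s = runif(1, 0.35, 0.5),
      peaks = 1500 * (1 + rnorm(n, 0, 0.08))
    )
    sel <- select_representative_preferred(px$trace)
    waves <- lapply(segment_strides(px$trace)$samples, resample_to_100)
    expect_equal(sel$stride, oracle_closest_to_median(waves))
  }
  # all strides identical: first stride selected
  px <- make_pulse_trace(n_pulses = 4)
  expect_equal(select_representative_preferred(px$trace)$stride, 1)
  flat <- tibble::tibble(time_s = (0:999) / 1000, force_n = rep(0, 1000))
  expect_error(suppressWarnings(select_representative_preferred(flat)),
               class = "tibfrax_input_error")
})

test_that("representative stride length matches the generator's target", {
  cfg <- cohort_config(seed = 21)
  p <- test_participant(stride = 2.06)
  tr <- generate_trial(p, "preferred", cfg, seed = 8)
  sel <- select_representative_preferred(tr)
  expect_equal(sel$stride_length_m, 2.06, tolerance = 0.05)
  expect_gt(nrow(segment_strides(tr)), 20)
})

test_that("reduced selector targets 90% of the reference stride length", {
  # constructed candidates: lengths 1.90, 1.85, 1.80 for reference 2.06
  mk <- function(lengths) {
    stance <- 0.25
    px <- NULL
    force <- numeric(100) # 0.1 s lead
    for (L in c(lengths, 2.0)) {  # trailing stride closes the last cycle
      dur <- round(1000 * L / 3.0)
      st <- round(1000 * stance)
      pulse <- 1500 * sin(pi * (seq_len(st) - 0.5) / st)
      force <- c(force, pulse, numeric(dur - st))
    }
    tibble::tibble(time_s = (seq_along(force) - 1) / 1000, force_n = force)
  }
  tr <- mk(c(1.90, 1.85, 1.80))
  sel <- select_representative_reduced(tr, reference_length_m = 2.06)
  # 1.85 m is closest to the 1.854 m target (sample quantisation < 4 mm)
  expect_equal(sel$stride_length_m, 1.85, tolerance = 0.002)
  expect_equal(sel$target_length_m, 0.9 * 2.06)

  # generator-backed: selected ratio within [0.88, 0.92]
  cfg <- cohort_config(seed = 31)
  p <- test_participant()
  ref <- select_representative_preferred(generate_trial(p, "preferred", cfg,
                                                        seed = 11))
  red <- select_representative_reduced(
    generate_trial(p, "reduced10", cfg, seed = 12), ref$stride_length_m)
  expect_true(red$stride_length_m / ref$stride_length_m >= 0.88 &&
                red$stride_length_m / ref$stride_length_m <= 0.92)

  flat <- tibble::tibble(time_s = (0:999) / 1000, force_n = rep(0, 1000))
  expect_error(suppressWarnings(select_representative_reduced(flat, 2.0)),
               class = "tibfrax_input_error")
})

test_that("exact stride-length ties fall back to the median-distance rank", {
  # two strides with identical duration (hence identical length) but
  # different mid-stance waveforms; onsets are identical so the threshold
  # crossings and stride lengths tie exactly
  stance <- 250
  mkpulse <- function(dur, bump = 0) {
    tau <- (seq_len(stance) - 0.5) / stance
    w <- 1500 * sin(pi * tau) +
      bump * exp(-((tau - 0.5) / 0.08)^2)     # zero near onset
    c(w, numeric(dur - stance))
  }
  force <- c(numeric(100),
             mkpulse(620, bump = 600),  # stride 1: 1.86 m, far from median
             mkpulse(620),              # stride 2: 1.86 m, near the median
             mkpulse(700),              # stride 3: different length
             mkpulse(620))              # closes stride 3
  tr <- tibble::tibble(time_s = (seq_along(force) - 1) / 1000, force_n = force)
  s <- segment_strides(tr)
  expect_equal(s$duration_s[1], s$duration_s[2])
  sel <- select_representative_reduced(tr, reference_length_m = 0.620 * 3.0 / 0.9)
  # strides 1 and 2 tie exactly on length error; index order alone would pick
  # stride 1, but stride 2 is closer to the median waveform
  expect_equal(sel$stride, 2)
})
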