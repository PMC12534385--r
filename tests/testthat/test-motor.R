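make_pulse_trace <- function(times, sr = 100, noise = 0, seed = 1) {
  tr <- synthesize_trace(times, sample_rate_hz = sr)
  if (noise > 0) {
    set.seed(seed)
    tr$voltage <- tr$voltage + runif(length(tr$voltage), -noise, noise)
  }
  tr
}

test_that("crossing detection recovers a clean 1 Hz pulse train", {
  tr <- make_pulse_trace(1:9)
  ct <- detect_crossings(tr$voltage, tr$sample_rate_hz)
  expect_length(ct, 9)
  expect_true(all(abs(as.numeric(ct) - (1:9)) <= 1 / tr$sample_rate_hz))
})

test_that("sub-threshold noise does not change the crossing count", {
  clean <- make_pulse_trace(1:9)
  noisy <- make_pulse_trace(1:9, noise = 1.25)  # 50% of the 2.5 V threshold
  n1 <- length(detect_crossings(clean$voltage, 100, threshold = 2.5))
  n2 <- length(detect_crossings(noisy$voltage, 100, threshold = 2.5))
  expect_equal(n1, n2)
})

test_that("the refractory window collapses double spikes", {
  tr <- make_pulse_trace(c(1, 1.15, 2, 3), sr = 100)
  ct <- detect_crossings(tr$voltage, 100, refractory_s = 0.3)
  expect_length(ct, 3)
})

test_that("fewer than two crossings is an error", {
  v <- c(0, 0, 5, 5, 0, 0)
  expect_error(detect_crossings(v, 100), "insufficient")
})

test_that("speed and CV match hand arithmetic", {
  # constant 1 s revolutions
  sc <- speed_and_cv(crossing_times(0:10))
  expect_equal(sc$mean_speed_hz, 1)
  expect_equal(sc$cv, 0)
  # d = (0.9, 1.1): recompute the oracle from first principles
  ct <- crossing_times(c(0, 0.9, 2.0))
  sc <- speed_and_cv(ct)
  s <- 1 / c(0.9, 1.1)
  expect_equal(sc$mean_speed_hz, mean(s), tolerance = 1e-12)
  expect_equal(sc$cv, sd(s) / mean(s), tolerance = 1e-12)
  expect_equal(sc$mean_speed_hz, (1 / 0.9 + 1 / 1.1) / 2)
})

test_that("inter-beat deviation follows its definition", {
  expect_equal(ibd(crossing_times(0:5), "isochronous", soa_s = 2), 0)
  expect_equal(ibd(crossing_times(c(0, 0.9, 2.0)), "isochronous", soa_s = 2),
               0.1)
  # identically zero under self-initiated stimulation, any jitter
  set.seed(2)
  jittered <- crossing_times(cumsum(runif(30, 0.5, 1.5)))
  expect_identical(ibd(jittered, "self_initiated"), 0)
  expect_error(ibd(crossing_times(0:5), "isochronous", soa_s = NULL), "soa")
})

test_that("metrics are time-shift invariant and scale covariant", {
  set.seed(3)
  times <- cumsum(runif(40, 0.8, 1.2))
  base <- motor_summary(crossing_times(times), "isochronous", soa_s = 2)
  shifted <- motor_summary(crossing_times(times + 123.4), "isochronous",
                           soa_s = 2)
  expect_equal(base$mean_speed_hz, shifted$mean_speed_hz)
  expect_equal(base$cv, shifted$cv)
  expect_equal(base$ibd_s, shifted$ibd_s)
  for (c_ in c(0.5, 2, 3.7)) {
    scaled <- speed_and_cv(crossing_times(times[1] +
                                            c(0, cumsum(diff(times) * c_))))
    expect_equal(scaled$mean_speed_hz, base$mean_speed_hz / c_,
                 tolerance = 1e-10)
    expect_equal(scaled$cv, base$cv, tolerance = 1e-10)
  }
})

test_that("trace synthesis and detection round-trip event times", {
  set.seed(4)
  times <- cumsum(runif(25, 0.7, 1.3))
  tr <- synthesize_trace(times, sample_rate_hz = 100)
  rec <- detect_crossings(tr$voltage, 100)
  expect_length(rec, length(times))
  expect_true(all(abs(as.numeric(rec) - times) <= 1 / 100))
})

test_that("the metrics table aggregates per subject and session", {
  ts <- rbind(
    data.frame(subject_id = "a", session = "1", condition = "isochronous",
               time_s = seq(0, 20, by = 1)),
    data.frame(subject_id = "a", session = "2", condition = "self_initiated",
               time_s = seq(0, 30, by = 1.1)))
  mt <- motor_metrics_table(ts)
  expect_equal(nrow(mt), 2)
  iso <- mt[mt$condition == "isochronous", ]
  expect_equal(iso$mean_speed_hz, 1)
  expect_equal(iso$ibd_s, 0)
  self <- mt[mt$condition == "self_initiated", ]
  expect_equal(self$ibd_s, 0)           # by construction in this mode
  expect_equal(self$mean_speed_hz, 1 / 1.1, tolerance = 1e-9)
})
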