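test_that("generated pitch indices match the configured moments and support", {
  s <- gen_subjects(10000, seed = 60)
  expect_true(all(s$pitch_index >= -1 & s$pitch_index <= 1))
  expect_lt(abs(mean(s$pitch_index) - 0.36), 0.02)
  expect_lt(abs(sd(s$pitch_index) - 0.33), 0.02)
  # left skew, as configured
  sk <- mean(((s$pitch_index - mean(s$pitch_index)) / sd(s$pitch_index))^3)
  expect_lt(sk, 0)
  expect_identical(gen_subjects(50, seed = 3), gen_subjects(50, seed = 3))
  expect_error(gen_subjects(50, truth_params(pitch_mean = 2)), "infeasible")
})

test_that("null-truth recall centers at 20 of 40", {
  truth0 <- truth_params(intercept_logit = 0, day2_minus_day1 = 0,
                         iso_minus_self = 0, session2_minus_session1 = 0,
                         pitch_slope = 0, pitch_cond_day = 0, music_slope = 0,
                         sleep_mean_slope = 0, sleep_dev_slope = 0,
                         languages_beta = 0, sd_intercept = 0, sd_cond = 0,
                         sd_day = 0)
  tab <- gen_recall(gen_subjects(500, truth0, seed = 61), truth0, seed = 61)
  expect_true(all(tab$recalled >= 0 & tab$recalled <= 40))
  expect_lt(abs(mean(tab$recalled) - 20), 0.5)
})

test_that("a negative day effect lowers day-2 recall in expectation", {
  truth <- truth_params(day2_minus_day1 = -0.5, sd_intercept = 0.3)
  tab <- gen_recall(gen_subjects(400, truth, seed = 62), truth, seed = 62)
  m <- tapply(tab$recalled, tab$day, mean)
  expect_lt(m[["2"]], m[["1"]])
})

test_that("the generator shares the fitted model's linear-predictor builder", {
  truth <- truth_params()
  subjects <- gen_subjects(30, truth, seed = 63)
  spec <- pitchsync:::recovery_model_spec()
  tab <- gen_recall(subjects, truth, seed = 63, spec = spec)
  # rebuild the design from the emitted table with the same spec: the fixed
  # part of the stored linear predictor must be reproduced exactly
  des <- pitchsync:::build_design(spec, tab)
  eta_fixed <- drop(des$X %*% pitchsync:::truth_beta(truth, des))
  re <- attr(tab, "subject_effects")
  gb <- NULL
  for (b in des$blocks) if (b$type == "group") gb <- b
  eta_full <- eta_fixed + rowSums(gb$Tm * re[gb$gidx, , drop = FALSE])
  expect_equal(unname(attr(tab, "eta")), unname(eta_full), tolerance = 1e-12)
})

test_that("pedaling respects its bias and dispersion configuration", {
  # zero jitter: CV collapses and IBD equals the bias-induced constant
  truth <- truth_params(sdlog = c(isochronous = 1e-9, self_initiated = 1e-9),
                        speed_bias = c(isochronous = 0.1, self_initiated = 0.05),
                        speed_bias_subject_sd = 0)
  ts <- gen_pedaling(gen_subjects(4, truth, seed = 64), truth, seed = 64,
                     n_revolutions = 50)
  mt <- motor_metrics_table(ts)
  expect_true(all(mt$cv < 1e-6))
  iso <- mt[mt$condition == "isochronous", ]
  expect_equal(iso$ibd_s, rep(abs(1 / 1.1 - 1), nrow(iso)), tolerance = 1e-6)

  # configured dispersion ordering shows up in measured CVs
  truth2 <- truth_params()
  ts2 <- gen_pedaling(gen_subjects(10, truth2, seed = 65), truth2, seed = 65,
                      n_revolutions = 1500)
  mt2 <- motor_metrics_table(ts2)
  w <- reshape(mt2[c("subject_id", "condition", "cv")], idvar = "subject_id",
               timevar = "condition", direction = "wide")
  expect_gte(sum(w$cv.isochronous < w$cv.self_initiated), 9)
})

test_that("voltage traces invert crossing detection", {
  truth <- truth_params()
  out <- gen_pedaling(gen_subjects(2, truth, seed = 66), truth, seed = 66,
                      n_revolutions = 30, traces = TRUE)
  tr <- out$traces[[1]]
  sel <- out$timestamps$subject_id == tr$subject_id &
    out$timestamps$session == tr$session
  times <- out$timestamps$time_s[sel]
  rec <- detect_crossings(tr$voltage, tr$sample_rate_hz)
  expect_length(rec, length(times))
  expect_true(all(abs(as.numeric(rec) - times) <= 1 / tr$sample_rate_hz))
})

test_that("the simulated observer saturates and preserves ranking", {
  bat <- build_battery(order_seed = 1)
  truth <- truth_params()
  subs <- gen_subjects(50, truth, seed = 67)
  subs$pitch_index[1] <- 1
  subs$pitch_index[2] <- -1
  logs <- simulate_mf_responses(subs, bat, truth, seed = 67)
  dp <- vapply(split(logs$classification, logs$subject_id), function(cl)
    pitch_index(response_tally(cl))$delta_p, numeric(1))
  expect_gt(dp[[subs$subject_id[1]]], 0.9)
  expect_lt(dp[[subs$subject_id[2]]], -0.9)
  theta <- qlogis(pmin(pmax((subs$pitch_index + 1) / 2, 1e-4), 1 - 1e-4))
  expect_gt(cor(theta, dp[subs$subject_id], method = "spearman"), 0.9)
})

test_that("study bundles are regenerable byte-identically from truth + seed", {
  b1 <- small_bundle(n = 8, seed = 68, n_rev = 80)
  b2 <- small_bundle(n = 8, seed = 68, n_rev = 80)
  expect_identical(b1$study_table, b2$study_table)
  expect_identical(b1$pedal_timestamps, b2$pedal_timestamps)
  expect_true(all(vapply(b1$study_table, function(col)
    all(is.finite(col) | is.character(col)), TRUE)))
})

test_that("truth parameters round-trip through YAML", {
  tp <- truth_params(day2_minus_day1 = -0.2, sd_intercept = 0.5)
  path <- tempfile(fileext = ".yaml")
  write_truth_yaml(tp, path)
  tp2 <- read_truth_yaml(path)
  expect_equal(tp2$day2_minus_day1, -0.2)
  expect_equal(tp2$sdlog, tp$sdlog)
})

test_that("recovery bookkeeping has one row per replicate and parameter", {
  rec <- suppressWarnings(recovery_experiment(
    truth_params(), n_subjects = 10, reps = 2, chains = 2, iterations = 150,
    seed = 70))
  expect_equal(nrow(rec), 2 * 4)
  expect_false(any(rec$failed))
  expect_true(all(c("truth", "estimate", "covered", "pd") %in% names(rec)))
})
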