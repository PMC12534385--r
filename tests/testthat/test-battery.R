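test_that("default battery has 162 pairs and 324 unique sounds", {
  bat <- build_battery(order_seed = 1)
  expect_length(bat$pairs, 162)
  ids <- unlist(lapply(bat$pairs, function(p) c(p$first$id, p$second$id)))
  expect_length(unique(ids), 324)
})

test_that("battery ordering is a deterministic function of the seed", {
  m1 <- battery_manifest(build_battery(order_seed = 7))
  m2 <- battery_manifest(build_battery(order_seed = 7))
  m3 <- battery_manifest(build_battery(order_seed = 8))
  expect_identical(m1, m2)
  expect_false(identical(m1$pair_id, m3$pair_id) &&
                 identical(m1$f0_direction, m3$f0_direction))
})

test_that("every pair opposes F0 and F_SP and preserves the top harmonic", {
  man <- battery_manifest(build_battery(order_seed = 3))
  expect_true(all(man$f0_direction * man$fsp_direction == -1))
  top1 <- man$f0_first * (man$n_min_first + man$n_harm_first - 1)
  top2 <- man$f0_second * (man$n_min_second + man$n_harm_second - 1)
  expect_true(all(abs(top1 - top2) / top1 < 1e-9))
})

test_that("invalid pairs are rejected constructively", {
  a <- harmonic_complex(200, 2, 3)
  expect_error(sound_pair(a, a, "dup"), "does not change")
  # same F0 direction as F_SP direction
  b <- harmonic_complex(250, 2, 3, id = "b")
  expect_error(sound_pair(a, b, "same_dir"), "opposite|highest")
})

test_that("responses classify onto spectral/fundamental bijectively", {
  p <- example_pair()                       # F0 up, F_SP down
  expect_equal(classify_response(p, "second_higher"), "fundamental")
  expect_equal(classify_response(p, "first_higher"), "spectral")
  bat <- build_battery(tiny_design(), order_seed = 2)
  for (pair in bat$pairs) {
    cls <- c(classify_response(pair, "first_higher"),
             classify_response(pair, "second_higher"))
    expect_setequal(cls, c("spectral", "fundamental"))
  }
})

test_that("pitch index reproduces its closed forms", {
  expect_equal(pitch_index(162, 0)$delta_p, 1)
  expect_equal(pitch_index(0, 162)$delta_p, -1)
  expect_equal(pitch_index(81, 81)$delta_p, 0)
  expect_equal(pitch_index(120, 42)$delta_p, 78 / 162)
  expect_error(pitch_index(0, 0), "undefined|no classified")
})

test_that("pitch index is antisymmetric and bounded", {
  set.seed(1)
  for (i in 1:200) {
    a <- sample(0:200, 1)
    b <- sample(0:200, 1)
    if (a + b == 0) next
    d1 <- pitch_index(a, b)$delta_p
    d2 <- pitch_index(b, a)$delta_p
    expect_equal(d1, -d2)
    expect_gte(d1, -1)
    expect_lte(d1, 1)
  }
})

test_that("a response log scores into the expected index", {
  bat <- build_battery(tiny_design(), order_seed = 4)
  # always report the direction of F_SP -> pure spectral perceiver
  answers <- vapply(bat$pairs, function(p)
    if (sign(p$d_fsp) > 0) "second_higher" else "first_higher", "")
  expect_equal(score_battery(bat, answers)$delta_p, 1)
  flipped <- ifelse(answers == "first_higher", "second_higher", "first_higher")
  expect_equal(score_battery(bat, flipped)$delta_p, -1)
})
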