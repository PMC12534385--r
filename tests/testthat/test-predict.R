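# A small fitted binomial model whose draws can be overwritten for exact
# checks of the prediction path.
fit_small_binomial <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      set.seed(50)
      n <- 40
      dat <- data.frame(x = seq(-1, 1, length.out = n),
                        cond = rep(c("a", "b"), n / 2),
                        y = rbinom(n, 40, 0.5), trials = 40,
                        g = rep(sprintf("g%d", 1:10), 4))
      spec <- model_spec("binomial", "y", trials = "trials",
                         fixed = c("cond", "x"),
                         random = random_term("g", "1"),
                         priors = prior_set(intercept_location = 0))
      fit <<- sample_posterior(spec, dat, chains = 2, iterations = 200,
                               seed = 51, leapfrog_range = c(5L, 10L))
    }
    fit
  }
})

test_that("all-zero coefficients predict 20 of 40 on the count scale", {
  fit <- zero_draw_fit(fit_small_binomial())
  grid <- data.frame(cond = c("a", "b"), x = c(0, 0.5))
  preds <- marginal_predictions(fit, grid)
  expect_equal(unname(as.vector(preds)), rep(20, length(preds)))
})

test_that("contrasting predictions with themselves gives exactly zero", {
  fit <- fit_small_binomial()
  grid <- data.frame(cond = "a", x = 0.3)
  p <- marginal_predictions(fit, grid)
  ct <- contrast_predictions(p, p)
  expect_equal(ct$median, 0)
  expect_equal(ct$pd, 0.5)
  ct2 <- contrast_predictions(p + 1, p)
  expect_equal(ct2$median, 1)
  expect_equal(ct2$pd, 1)
  expect_error(contrast_predictions(p, cbind(p, p)), "shape")
})

test_that("a monotone intercept shift moves all predictions one way", {
  fit <- fit_small_binomial()
  grid <- data.frame(cond = c("a", "b", "a"), x = c(-0.5, 0, 0.5))
  p0 <- marginal_predictions(fit, grid)
  fit2 <- fit
  fit2$draws[, "b_(Intercept)"] <- fit2$draws[, "b_(Intercept)"] + 1
  p1 <- marginal_predictions(fit2, grid)
  expect_true(all(p1 > p0))
})

test_that("finite differences recover exact and analytic slopes", {
  # identity link, pure linear effect: slope is the coefficient, exactly
  set.seed(52)
  dat <- data.frame(y = rnorm(30), x = seq(-1, 1, length.out = 30))
  gfit <- sample_posterior(model_spec("gaussian", "y", fixed = "x"), dat,
                           chains = 2, iterations = 200, seed = 53,
                           leapfrog_range = c(5L, 10L))
  gfit <- zero_draw_fit(gfit, list(b_x = 0.7))
  fd <- finite_diff_slope(gfit, "x", data.frame(x = c(-0.4, 0, 0.4)))
  expect_equal(unname(as.vector(fd$slopes)), rep(0.7, length(fd$slopes)),
               tolerance = 1e-8)
  expect_false(any(fd$one_sided))
  # boundary points fall back to one-sided differences, flagged
  fdb <- finite_diff_slope(gfit, "x", data.frame(x = c(-1, 1)))
  expect_true(all(fdb$one_sided))

  # logistic: slope on the count scale at eta = 0 is beta * n / 4
  bfit <- zero_draw_fit(fit_small_binomial(), list(b_x = 0.8))
  fd2 <- finite_diff_slope(bfit, "x",
                           data.frame(cond = "a", x = 0), h = 1e-4)
  expect_equal(unname(as.vector(fd2$slopes)),
               rep(0.8 * 40 / 4, nrow(bfit$draws)), tolerance = 1e-4)
})

test_that("half-split contrasts detect flat and increasing effects", {
  fit0 <- zero_draw_fit(fit_small_binomial())
  grid <- data.frame(cond = "a", x = seq(-1, 1, length.out = 21))
  hs0 <- half_split_contrast(fit0, "x", grid = grid)
  expect_equal(hs0$median, 0)
  expect_equal(hs0$pd, 0.5)
  fit1 <- zero_draw_fit(fit_small_binomial(), list(b_x = 0.6))
  hs1 <- half_split_contrast(fit1, "x", grid = grid)
  expect_gt(hs1$median, 0)
  expect_equal(hs1$pd, 1)
  # symmetric grid: mean and median split agree
  hs_mean <- half_split_contrast(fit1, "x", grid = grid, split = "mean")
  expect_equal(hs1$median, hs_mean$median)
})

test_that("bayesian R2 hits its limiting values", {
  set.seed(54)
  dat <- data.frame(y = rnorm(30), x = seq(-1, 1, length.out = 30))
  gfit <- sample_posterior(model_spec("gaussian", "y", fixed = "x"), dat,
                           chains = 2, iterations = 200, seed = 55,
                           leapfrog_range = c(5L, 10L))
  # zero residual variance -> 1
  f1 <- zero_draw_fit(gfit, list(b_x = 1, log_sigma = -20))
  expect_equal(bayes_r2(f1)$median, 1, tolerance = 1e-6)
  # zero fitted variance -> 0
  f0 <- zero_draw_fit(gfit, list(log_sigma = 0))
  expect_equal(bayes_r2(f0)$median, 0)
  # equal fitted and residual variance -> 0.5
  vx <- var(1 * dat$x)
  f5 <- zero_draw_fit(gfit, list(b_x = 1, log_sigma = log(sqrt(vx))))
  expect_equal(bayes_r2(f5)$median, 0.5, tolerance = 1e-10)
})

test_that("icc tracks the group variance share", {
  set.seed(56)
  J <- 40
  dat <- data.frame(y = rnorm(2 * J), g = rep(sprintf("g%02d", 1:J), 2))
  spec <- model_spec("gaussian", "y", random = random_term("g", "1"))
  fit <- sample_posterior(spec, dat, chains = 2, iterations = 300, seed = 57,
                          leapfrog_range = c(5L, 10L))
  # no group variance -> ICC about 0
  f0 <- zero_draw_fit(fit, list(log_sd_g_1 = -20, log_sigma = 0))
  i0 <- icc(f0, seed = 58)
  expect_lt(abs(i0$median), 0.05)
  # group variance equal to residual variance -> ICC about 0.5
  f5 <- zero_draw_fit(fit, list(log_sd_g_1 = 0, log_sigma = 0))
  i5 <- icc(f5, seed = 59)
  expect_equal(i5$median, 0.5, tolerance = 0.12)
  expect_gte(i5$median, -0.05)
  expect_lte(i5$median, 1)
  expect_error(icc(fit, grouping = "nope"), "unknown")
})

test_that("reference grids complete unspecified covariates", {
  fit <- fit_small_binomial()
  g <- reference_grid(fit, cond = c("a", "b"))
  expect_equal(nrow(g), 2)
  expect_equal(g$x, rep(mean(fit$design$data$x), 2))
  expect_error(marginal_predictions(fit, data.frame(cond = "a")),
               "not found|missing")
})
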