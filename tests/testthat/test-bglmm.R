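make_full_design <- function() {
  set.seed(30)
  n <- 48
  dat <- data.frame(
    x = runif(n), g = rep(sprintf("g%d", 1:8), 6),
    cond = rep(c("iso", "self"), n / 2),
    recalled = rbinom(n, 40, 0.4), trials = 40,
    lang = sample(0:3, n, TRUE))
  spec <- model_spec("binomial", "recalled", trials = "trials",
                     fixed = c("cond", "x", "cond:x"),
                     smooths = list(smooth_term("x", k = 5)),
                     monotonic = "lang",
                     random = random_term("g", c("1", "cond")))
  pitchsync:::build_design(spec, dat)
}

test_that("analytic gradients match finite differences for every block", {
  des <- make_full_design()
  set.seed(31)
  for (rep in 1:3) {
    theta <- rnorm(des$pmap$n_par, 0, 0.4)
    lpg <- pitchsync:::log_posterior(des, theta, grad = TRUE)
    fd <- vapply(seq_along(theta), function(i) {
      h <- 1e-5
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (pitchsync:::log_posterior(des, tp)$lp -
         pitchsync:::log_posterior(des, tm)$lp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(lpg$grad - fd)), 1e-6)
  }
})

test_that("gaussian and gamma gradients match finite differences", {
  set.seed(32)
  n <- 30
  dat <- data.frame(y = rlnorm(n, 0, 0.4), x = rnorm(n),
                    se = runif(n, 0.05, 0.2))
  for (fam in c("gaussian", "gamma")) {
    spec <- model_spec(fam, "y", fixed = "x",
                       se = if (fam == "gaussian") "se" else NULL)
    des <- pitchsync:::build_design(spec, dat)
    theta <- rnorm(des$pmap$n_par, 0, 0.3)
    lpg <- pitchsync:::log_posterior(des, theta, grad = TRUE)
    fd <- vapply(seq_along(theta), function(i) {
      h <- 1e-5
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (pitchsync:::log_posterior(des, tp)$lp -
         pitchsync:::log_posterior(des, tm)$lp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(lpg$grad - fd)), 1e-6)
  }
})

test_that("the binomial log likelihood has its closed form at logit 0", {
  dat <- data.frame(y = 20, trials = 40)
  spec <- model_spec("binomial", "y", trials = "trials")
  des <- pitchsync:::build_design(spec, dat)
  ll <- pitchsync:::log_lik_eta(des, eta = 0, pars = list())$ll
  expect_equal(ll, lchoose(40, 20) + 40 * log(0.5))
})

test_that("a known observation SE of zero reduces to the plain gaussian", {
  dat <- data.frame(y = c(1.2, 0.8, 1.1), se = 0)
  spec0 <- model_spec("gaussian", "y", se = "se")
  spec1 <- model_spec("gaussian", "y")
  d0 <- pitchsync:::build_design(spec0, dat)
  d1 <- pitchsync:::build_design(spec1, dat)
  pars <- list(log_sigma = log(0.5))
  eta <- rep(1, 3)
  expect_equal(pitchsync:::log_lik_eta(d0, eta, pars)$ll,
               pitchsync:::log_lik_eta(d1, eta, pars)$ll)
})

test_that("gamma log-link simulation recovers the modeled mean", {
  set.seed(33)
  eta <- 0.7
  alpha <- 3
  y <- rgamma(20000, shape = alpha, rate = alpha / exp(eta))
  expect_equal(mean(y), exp(eta), tolerance = 0.02)
  # and the likelihood is maximized near the true eta
  dat <- data.frame(y = y)
  spec <- model_spec("gamma", "y")
  des <- pitchsync:::build_design(spec, dat)
  lls <- vapply(c(0.5, 0.7, 0.9), function(e)
    pitchsync:::log_lik_eta(des, rep(e, length(y)),
                            list(log_shape = log(alpha)))$ll, numeric(1))
  expect_equal(which.max(lls), 2L)
})

test_that("posterior mean matches the conjugate precision-weighted mean", {
  set.seed(34)
  n <- 60
  sigma_known <- 1
  y <- rnorm(n, 1.5, sigma_known)
  m0 <- 0; s0 <- 0.5
  spec <- model_spec("gaussian", "y", se = "se",
                     priors = prior_set(intercept_location = m0,
                                        intercept_scale = s0,
                                        sd_scale = 0.3))
  dat <- data.frame(y = y, se = sigma_known)
  fit <- sample_posterior(spec, dat, chains = 4, iterations = 1500, seed = 35,
                          leapfrog_range = c(5L, 15L))
  mu_conj <- (m0 / s0^2 + sum(y) / sigma_known^2) /
    (1 / s0^2 + n / sigma_known^2)
  expect_lt(abs(mean(fit$draws[, "b_(Intercept)"]) - mu_conj), 0.01)
})

test_that("logistic posterior center matches a brute-force grid MLE", {
  set.seed(36)
  n <- 200
  x <- rep(c(-0.5, 0.5), n / 2)
  eta <- 0.3 - 0.8 * x
  y <- rbinom(n, 1, plogis(eta))
  dat <- data.frame(y = y, x = x, trials = 1)
  spec <- model_spec("binomial", "y", trials = "trials", fixed = "x",
                     priors = prior_set(fixed_scale = 10,
                                        intercept_scale = 10,
                                        intercept_location = 0))
  fit <- sample_posterior(spec, dat, chains = 4, iterations = 1500, seed = 37,
                          leapfrog_range = c(5L, 15L))
  loglik <- function(b0, b1) {
    e <- b0 + b1 * x
    sum(y * e - log1p(exp(e)))
  }
  # coarse-to-fine grid search over the two coefficients
  g <- expand.grid(b0 = seq(-2, 2, by = 0.05), b1 = seq(-3, 1, by = 0.05))
  ll <- mapply(loglik, g$b0, g$b1)
  top <- g[which.max(ll), ]
  g2 <- expand.grid(b0 = seq(top$b0 - 0.06, top$b0 + 0.06, by = 0.002),
                    b1 = seq(top$b1 - 0.06, top$b1 + 0.06, by = 0.002))
  ll2 <- mapply(loglik, g2$b0, g2$b1)
  mle <- g2[which.max(ll2), ]
  expect_lt(abs(median(fit$draws[, "b_(Intercept)"]) - mle$b0), 0.05)
  expect_lt(abs(median(fit$draws[, "b_x"]) - mle$b1), 0.05)
})

test_that("a well-specified run converges with Rhat below 1.01", {
  set.seed(38)
  dat <- data.frame(y = rnorm(150, 2, 1), x = rnorm(150))
  spec <- model_spec("gaussian", "y", fixed = "x")
  fit <- sample_posterior(spec, dat, chains = 4, iterations = 1000, seed = 39,
                          leapfrog_range = c(5L, 15L))
  expect_true(all(fit$diagnostics$rhat < 1.01, na.rm = TRUE))
  expect_false(fit$rhat_flagged)
})

test_that("identical seed and configuration reproduce identical draws", {
  set.seed(40)
  dat <- data.frame(y = rbinom(24, 40, 0.3), trials = 40,
                    g = rep(letters[1:6], 4))
  spec <- model_spec("binomial", "y", trials = "trials",
                     random = random_term("g", "1"))
  f1 <- sample_posterior(spec, dat, chains = 2, iterations = 200, seed = 7,
                         leapfrog_range = c(5L, 10L))
  f2 <- sample_posterior(spec, dat, chains = 2, iterations = 200, seed = 7,
                         leapfrog_range = c(5L, 10L))
  expect_identical(f1$draws, f2$draws)
})

test_that("factor coding and a numeric dummy give the same fitted values", {
  set.seed(41)
  n <- 80
  cond <- rep(c("a", "b"), n / 2)
  y <- rnorm(n, ifelse(cond == "b", 1, 0), 1)
  dat <- data.frame(y = y, cond = cond, cond_num = as.numeric(cond == "b"))
  fit_f <- sample_posterior(model_spec("gaussian", "y", fixed = "cond"),
                            dat, chains = 2, iterations = 1500, seed = 42,
                            leapfrog_range = c(5L, 15L))
  fit_n <- sample_posterior(model_spec("gaussian", "y", fixed = "cond_num"),
                            dat, chains = 2, iterations = 1500, seed = 43,
                            leapfrog_range = c(5L, 15L))
  ga <- data.frame(cond = c("a", "b"), cond_num = c(0, 1))
  pa <- apply(marginal_predictions(fit_f, ga), 2, median)
  pb <- apply(marginal_predictions(fit_n, ga), 2, median)
  expect_equal(pa, pb, tolerance = 0.05)
})

test_that("inflating known SEs attenuates the fixed effects", {
  set.seed(44)
  n <- 60
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, 0.3)
  fits <- lapply(c(0.1, 3), function(sev) {
    dat <- data.frame(y = y, x = x, se = sev)
    sample_posterior(model_spec("gaussian", "y", fixed = "x", se = "se"),
                     dat, chains = 2, iterations = 800, seed = 45,
                     leapfrog_range = c(5L, 15L))
  })
  b_small <- abs(mean(fits[[1]]$draws[, "b_x"]))
  b_large <- abs(mean(fits[[2]]$draws[, "b_x"]))
  expect_lt(b_large, b_small)
})
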