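# Joint log posterior (log likelihood + log priors + transform Jacobians) on
# the unconstrained parameter scale, with analytic gradients for all blocks
# except the tiny correlation-transform Jacobian (finite-differenced; it is a
# data-free K x K computation).

log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

unpack_params <- function(design, theta) {
  pm <- design$pmap
  pars <- list(beta = theta[pmap_idx(pm, "beta")], blocks = list())
  for (bi in seq_along(design$blocks)) {
    b <- design$blocks[[bi]]
    if (b$type == "smooth") {
      pars$blocks[[bi]] <- list(u = theta[pmap_idx(pm, "smooth_u", bi)],
                                log_sd = theta[pmap_idx(pm, "smooth_logsd", bi)])
    } else if (b$type == "mono") {
      pars$blocks[[bi]] <- list(beta = theta[pmap_idx(pm, "mono_beta", bi)],
                                u = theta[pmap_idx(pm, "mono_u", bi)])
    } else if (b$type == "group") {
      z <- matrix(theta[pmap_idx(pm, "group_z", bi)], b$J, b$K)
      pars$blocks[[bi]] <- list(
        z = z, log_tau = theta[pmap_idx(pm, "group_logtau", bi)],
        y_corr = if (b$correlated) theta[pmap_idx(pm, "group_corr", bi)] else NULL)
    }
  }
  if (design$spec$family == "gaussian")
    pars$log_sigma <- theta[pmap_idx(pm, "log_sigma")]
  if (design$spec$family == "gamma")
    pars$log_shape <- theta[pmap_idx(pm, "log_shape")]
  pars
}

# Linear predictor and per-block caches (group-effect matrices, simplexes).
compute_eta <- function(design, pars) {
  eta <- drop(design$X %*% pars$beta)
  cache <- vector("list", length(design$blocks))
  for (bi in seq_along(design$blocks)) {
    b <- design$blocks[[bi]]
    pb <- pars$blocks[[bi]]
    if (b$type == "smooth") {
      # non-centered: coefficients are sd * u with u ~ N(0, 1)
      eta <- eta + exp(pb$log_sd) * drop(b$Z %*% pb$u)
    } else if (b$type == "mono") {
      zeta <- simplex_from_raw(pb$u)
      cz <- c(0, cumsum(zeta))
      ci <- cz[b$x + 1L]
      eta <- eta + pb$beta * ci
      cache[[bi]] <- list(zeta = zeta, ci = ci)
    } else if (b$type == "group") {
      tau <- exp(pb$log_tau)
      L <- if (b$correlated)
        chol_from_raw(pb$y_corr, b$K, design$spec$priors$lkj_eta)$L
      else diag(b$K)
      bmat <- (pb$z %*% t(L)) * rep(tau, each = b$J)
      eta <- eta + rowSums(b$Tm * bmat[b$gidx, , drop = FALSE])
      cache[[bi]] <- list(tau = tau, L = L, bmat = bmat)
    }
  }
  list(eta = eta, cache = cache)
}

log_lik_eta <- function(design, eta, pars, grad = FALSE) {
  y <- design$y
  fam <- design$spec$family
  if (fam == "binomial") {
    n <- design$trials
    ll <- sum(lchoose(n, y) + y * eta - n * log1pexp(eta))
    g <- if (grad) y - n * stats::plogis(eta) else NULL
    list(ll = ll, g_eta = g, g_extra = numeric(0))
  } else if (fam == "gaussian") {
    sigma <- exp(pars$log_sigma)
    v <- sigma^2 + if (is.null(design$se)) 0 else design$se^2
    r <- y - eta
    ll <- -0.5 * sum(log(2 * pi * v) + r^2 / v)
    g <- if (grad) r / v else NULL
    ge <- if (grad) sigma^2 * sum((r^2 - v) / v^2) else NULL
    list(ll = ll, g_eta = g, g_extra = c(log_sigma = ge))
  } else {
    if (abs(pars$log_shape) > 15)   # reject absurd shapes before lgamma/digamma
      return(list(ll = -Inf, g_eta = if (grad) numeric(length(eta)) else NULL,
                  g_extra = c(log_shape = 0)))
    alpha <- exp(pars$log_shape)
    w <- y * exp(-eta)
    ll <- sum(alpha * log(alpha) - lgamma(alpha) + (alpha - 1) * log(y) -
                alpha * eta - alpha * w)
    g <- if (grad) alpha * (w - 1) else NULL
    ge <- if (grad)
      alpha * sum(log(alpha) + 1 - digamma(alpha) + log(y) - eta - w)
    else NULL
    list(ll = ll, g_eta = g, g_extra = c(log_shape = ge))
  }
}

#' Joint log posterior density
#'
#' Log likelihood plus log priors plus random-effect log densities, on the
#' unconstrained parameter scale (SDs and shapes log-transformed, simplexes
#' via reference softmax, correlation Cholesky via canonical partial
#' correlations; all transform Jacobians included).
#'
#' @param design a \code{model_design} from \code{build_design}.
#' @param theta unconstrained parameter vector.
#' @param grad if TRUE also return the gradient.
#' @return list with \code{lp} and (optionally) \code{grad}.
#' @keywords internal
log_posterior <- function(design, theta, grad = FALSE) {
  pm <- design$pmap
  pr <- design$spec$priors
  pars <- unpack_params(design, theta)
  ce <- compute_eta(design, pars)
  lik <- log_lik_eta(design, ce$eta, pars, grad = grad)
  lp <- lik$ll
  g <- if (grad) numeric(pm$n_par) else NULL
  geta <- lik$g_eta

  # fixed effects
  lp <- lp + sum(stats::dnorm(pars$beta, design$beta_loc, design$beta_scale,
                              log = TRUE))
  if (grad)
    g[pmap_idx(pm, "beta")] <- drop(crossprod(design$X, geta)) -
      (pars$beta - design$beta_loc) / design$beta_scale^2

  for (bi in seq_along(design$blocks)) {
    b <- design$blocks[[bi]]
    pb <- pars$blocks[[bi]]
    if (b$type == "smooth") {
      sd_s <- exp(pb$log_sd)
      lp <- lp + sum(stats::dnorm(pb$u, log = TRUE)) -
        0.5 * (sd_s / pr$sd_scale)^2 + pb$log_sd
      if (grad) {
        zt <- drop(crossprod(b$Z, geta))
        g[pmap_idx(pm, "smooth_u", bi)] <- sd_s * zt - pb$u
        g[pmap_idx(pm, "smooth_logsd", bi)] <-
          sd_s * sum(pb$u * zt) - sd_s^2 / pr$sd_scale^2 + 1
      }
    } else if (b$type == "mono") {
      zeta <- ce$cache[[bi]]$zeta
      ci <- ce$cache[[bi]]$ci
      lp <- lp + stats::dnorm(pb$beta, 0, pr$fixed_scale, log = TRUE) +
        pr$dirichlet_alpha * sum(log(zeta))
      if (grad) {
        g[pmap_idx(pm, "mono_beta", bi)] <- sum(geta * ci) -
          pb$beta / pr$fixed_scale^2
        D <- b$D
        gu <- numeric(D - 1)
        for (j in 2:D) {
          ind <- as.numeric(b$x >= j)        # zeta_j contributes when x >= j
          gu[j - 1] <- pb$beta * zeta[j] * sum(geta * (ind - ci)) +
            pr$dirichlet_alpha * (1 - D * zeta[j])
        }
        g[pmap_idx(pm, "mono_u", bi)] <- gu
      }
    } else if (b$type == "group") {
      tau <- ce$cache[[bi]]$tau
      L <- ce$cache[[bi]]$L
      lp <- lp - 0.5 * sum(pb$z^2) - b$J * b$K * 0.5 * log(2 * pi) +
        sum(-0.5 * (tau / pr$sd_scale)^2 + pb$log_tau)
      if (b$correlated) {
        cf <- chol_from_raw(pb$y_corr, b$K, pr$lkj_eta)
        lp <- lp + cf$lkj + cf$logjac
      }
      if (grad) {
        G <- rowsum(b$Tm * geta, b$gidx)          # J x K, dll/db
        Gt <- G * rep(tau, each = b$J)
        g[pmap_idx(pm, "group_z", bi)] <- as.vector(Gt %*% L - pb$z)
        zLt <- pb$z %*% t(L)
        g[pmap_idx(pm, "group_logtau", bi)] <-
          tau * colSums(G * zLt) - tau^2 / pr$sd_scale^2 + 1
        if (b$correlated) {
          dL <- crossprod(Gt, pb$z)               # K x K, dll/dL
          ncor <- length(pb$y_corr)
          gy <- numeric(ncor)
          h <- 1e-6
          for (ii in seq_len(ncor)) {
            yp <- pb$y_corr; yp[ii] <- yp[ii] + h
            ym <- pb$y_corr; ym[ii] <- ym[ii] - h
            cp <- chol_from_raw(yp, b$K, pr$lkj_eta)
            cm <- chol_from_raw(ym, b$K, pr$lkj_eta)
            gy[ii] <- sum(dL * (cp$L - cm$L)) / (2 * h) +
              ((cp$lkj + cp$logjac) - (cm$lkj + cm$logjac)) / (2 * h)
          }
          g[pmap_idx(pm, "group_corr", bi)] <- gy
        }
      }
    }
  }

  if (design$spec$family == "gaussian") {
    lp <- lp - 0.5 * (exp(pars$log_sigma) / pr$sd_scale)^2 + pars$log_sigma
    if (grad)
      g[pmap_idx(pm, "log_sigma")] <- lik$g_extra[["log_sigma"]] -
        exp(2 * pars$log_sigma) / pr$sd_scale^2 + 1
  }
  if (design$spec$family == "gamma") {
    lp <- lp + stats::dnorm(pars$log_shape, 0, 2.5, log = TRUE)
    if (grad)
      g[pmap_idx(pm, "log_shape")] <- lik$g_extra[["log_shape"]] -
        pars$log_shape / 2.5^2
  }

  if (!is.finite(lp)) {
    lp <- -Inf
    if (grad) g[] <- 0
  }
  list(lp = lp, grad = g)
}
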