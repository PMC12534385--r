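# Posterior prediction machinery: rebuild the design at new covariate values
# and push every posterior draw through it.

# Fixed-effect + smooth-null-space design matrix for new data, in the exact
# column order of the fitted design.
newdata_X <- function(design, newdata) {
  spec <- design$spec
  n <- nrow(newdata)
  cols <- list(matrix(1, n, 1))
  for (label in spec$fixed)
    cols[[length(cols) + 1]] <- code_term(label, newdata, spec, design$meta)$M
  for (sm in design$smooth_meta) {
    xv <- as.numeric(newdata[[sm$term$var]])
    if (is.null(newdata[[sm$term$var]]))
      stop("grid is missing covariate: ", sm$term$var)
    pr <- tprs_mixed_predict(sm$mixed, xv)
    cols[[length(cols) + 1]] <- pr$Xf
    if (!is.null(sm$cells)) {
      cell_f <- interaction(lapply(sm$cells$by, function(v) {
        if (is.null(newdata[[v]])) stop("grid is missing covariate: ", v)
        as.character(newdata[[v]])
      }), sep = ".", drop = FALSE)
      for (cl in sm$cells$levels) {
        mask <- as.character(cell_f) == cl
        Xf <- matrix(0, n, 1)
        if (any(mask)) {
          prc <- tprs_mixed_predict(sm$cells$mixed[[cl]], xv[mask])
          Xf[mask, ] <- prc$Xf
        }
        cols[[length(cols) + 1]] <- Xf
      }
    }
  }
  X <- do.call(cbind, cols)
  if (ncol(X) != design$p) stop("internal error: prediction design mismatch")
  X <- sweep(X, 2, design$x_centers)
  colnames(X) <- colnames(design$X)
  X
}

# Smooth random-effect matrices for new data, aligned to design$blocks order.
newdata_smooth_Z <- function(design, newdata) {
  Zs <- list()
  for (sm in design$smooth_meta) {
    xv <- as.numeric(newdata[[sm$term$var]])
    Zs[[length(Zs) + 1]] <- tprs_mixed_predict(sm$mixed, xv)$Zr
    if (!is.null(sm$cells)) {
      cell_f <- interaction(lapply(sm$cells$by, function(v)
        as.character(newdata[[v]])), sep = ".", drop = FALSE)
      for (cl in sm$cells$levels) {
        mask <- as.character(cell_f) == cl
        mc <- sm$cells$mixed[[cl]]
        Zr <- matrix(0, nrow(newdata), ncol(mc$Zr))
        if (any(mask)) Zr[mask, ] <- tprs_mixed_predict(mc, xv[mask])$Zr
        Zs[[length(Zs) + 1]] <- Zr
      }
    }
  }
  Zs
}

# Group-effect draws: ndraw x J x K array of b values on the effect scale.
group_effect_draws <- function(fit, block_id) {
  b <- fit$design$blocks[[block_id]]
  pm <- fit$design$pmap
  zd <- fit$draws[, pmap_idx(pm, "group_z", block_id), drop = FALSE]
  taud <- exp(fit$draws[, pmap_idx(pm, "group_logtau", block_id), drop = FALSE])
  nd <- nrow(fit$draws)
  out <- array(0, c(nd, b$J, b$K))
  corr_idx <- if (b$correlated) pmap_idx(pm, "group_corr", block_id) else integer(0)
  for (s in seq_len(nd)) {
    z <- matrix(zd[s, ], b$J, b$K)
    L <- if (b$correlated)
      chol_from_raw(fit$draws[s, corr_idx], b$K,
                    fit$spec$priors$lkj_eta)$L else diag(b$K)
    out[s, , ] <- (z %*% t(L)) * rep(taud[s, ], each = b$J)
  }
  out
}

# Linear-predictor draws (ndraw x nrow) at new data. Group effects are
# marginalized to zero (population-level prediction) unless include_groups.
eta_draws <- function(fit, newdata, include_groups = FALSE) {
  design <- fit$design
  pm <- design$pmap
  X <- newdata_X(design, newdata)
  eta <- fit$draws[, pmap_idx(pm, "beta"), drop = FALSE] %*% t(X)
  Zs <- newdata_smooth_Z(design, newdata)
  zi <- 0
  for (bi in seq_along(design$blocks)) {
    b <- design$blocks[[bi]]
    if (b$type == "smooth") {
      zi <- zi + 1
      u <- fit$draws[, pmap_idx(pm, "smooth_u", bi), drop = FALSE] *
        exp(fit$draws[, pmap_idx(pm, "smooth_logsd", bi)])
      eta <- eta + u %*% t(Zs[[zi]])
    } else if (b$type == "mono") {
      xm <- newdata[[b$var]]
      if (is.null(xm)) stop("grid is missing covariate: ", b$var)
      xm <- as.integer(xm)
      if (any(xm < 0 | xm > b$D))
        stop("monotonic predictor outside fitted range 0..", b$D)
      ud <- fit$draws[, pmap_idx(pm, "mono_u", bi), drop = FALSE]
      betad <- fit$draws[, pmap_idx(pm, "mono_beta", bi)]
      czs <- t(apply(ud, 1, function(u) c(0, cumsum(simplex_from_raw(u)))))
      eta <- eta + betad * czs[, xm + 1L, drop = FALSE]
    } else if (b$type == "group" && include_groups) {
      gx <- as.character(newdata[[b$group]])
      if (is.null(newdata[[b$group]]))
        stop("grid is missing grouping variable: ", b$group)
      gj <- match(gx, b$groups)
      bd <- group_effect_draws(fit, bi)
      Tm <- matrix(1, nrow(newdata), 1)
      for (tv in setdiff(fit$spec$random$terms, "1"))
        Tm <- cbind(Tm, code_var(tv, newdata, fit$spec, design$meta))
      for (k in seq_len(b$K)) {
        bk <- bd[, , k, drop = FALSE]
        dim(bk) <- c(nrow(fit$draws), b$J)
        contrib <- bk[, gj, drop = FALSE]
        contrib[, is.na(gj)] <- 0
        eta <- eta + contrib * rep(Tm[, k], each = nrow(eta))
      }
    }
  }
  eta
}

inverse_link <- function(family, eta, trials = NULL) {
  switch(family,
         binomial = {
           p <- stats::plogis(eta)
           if (is.null(trials)) p else p * rep(trials, each = nrow(eta))
         },
         gaussian = eta,
         gamma = exp(eta))
}

#' Reference grid for posterior predictions
#'
#' Builds a prediction grid from the named covariate values, completing every
#' other model covariate at its reference: the mean of the fitted data for
#' numerics, the first (alphabetical) level for factors, the observed median
#' for monotonic ordinals.
#'
#' @param fit a \code{posterior_fit}.
#' @param ... named covariate values to cross (as in \code{expand.grid}).
#' @return data.frame grid covering all model terms.
#' @export
reference_grid <- function(fit, ...) {
  vary <- list(...)
  grid <- if (length(vary)) expand.grid(vary, stringsAsFactors = FALSE)
  else data.frame(row.names = 1)
  data <- fit$design$data
  spec <- fit$spec
  need <- unique(c(
    unlist(lapply(spec$fixed, function(l) strsplit(l, ":", fixed = TRUE)[[1]])),
    vapply(spec$smooths, function(s) s$var, ""),
    unlist(lapply(spec$smooths, function(s) s$by)),
    spec$monotonic))
  for (v in setdiff(need, names(vary))) {
    x <- data[[v]]
    grid[[v]] <- if (v %in% spec$monotonic) as.integer(stats::median(as.integer(x)))
    else if (v %in% names(fit$design$meta$factor_levels))
      fit$design$meta$factor_levels[[v]][1]
    else mean(as.numeric(x))
  }
  grid
}

#' Expected posterior predictions over a covariate grid
#'
#' Expected values of the posterior predictions (posterior fits) per draw and
#' grid row, on the response or link scale. Group effects are marginalized by
#' setting them to zero (population-level prediction) unless
#' \code{include_groups} and the grid names the fitted groups.
#'
#' @param fit a \code{posterior_fit}.
#' @param grid covariate table covering all model terms (see
#'   \code{\link{reference_grid}}).
#' @param scale \code{"response"} (inverse link; expected counts for the
#'   binomial family) or \code{"link"}.
#' @param include_groups add the fitted group effects (grid must contain the
#'   grouping variable).
#' @param trials binomial trials for the count scale; defaults to the model's
#'   trials (column in grid, else the fitted constant/mean).
#' @return matrix of draws (ndraws x nrow(grid)) with the grid attached as an
#'   attribute.
#' @export
marginal_predictions <- function(fit, grid, scale = c("response", "link"),
                                 include_groups = FALSE, trials = NULL) {
  scale <- match.arg(scale)
  eta <- eta_draws(fit, grid, include_groups = include_groups)
  if (scale == "link") {
    out <- eta
  } else {
    tr <- NULL
    if (fit$spec$family == "binomial") {
      tr <- trials
      if (is.null(tr)) {
        tr <- if (is.character(fit$spec$trials) &&
                  !is.null(grid[[fit$spec$trials]]))
          as.numeric(grid[[fit$spec$trials]])
        else rep(mean(fit$design$trials), nrow(grid))
      }
      if (length(tr) == 1) tr <- rep(tr, nrow(grid))
    }
    out <- inverse_link(fit$spec$family, eta, tr)
  }
  attr(out, "grid") <- grid
  attr(out, "scale") <- scale
  out
}

#' Contrast two sets of posterior predictions
#'
#' Summarizes the per-draw difference A - B (averaged over grid rows when the
#' predictions span several) with median, tiered HDIs and the probability of
#' direction, labeled pd_resp on the response scale and pd_link on the link
#' scale.
#'
#' @param preds_a,preds_b prediction draw matrices of equal dimension (from
#'   \code{\link{marginal_predictions}}), or draw vectors.
#' @param label optional contrast name.
#' @return a \code{summary_stats} row (with a \code{pd_label} column) and the
#'   per-draw differences as attribute \code{"draws"}.
#' @export
contrast_predictions <- function(preds_a, preds_b, label = NULL) {
  if (!all(dim(as.matrix(preds_a)) == dim(as.matrix(preds_b))))
    stop("prediction sets have mismatching shapes")
  d <- as.matrix(preds_a) - as.matrix(preds_b)
  dd <- if (ncol(d) > 1) rowMeans(d) else d[, 1]
  out <- summary_stats(dd, label = label)
  out$pd_label <- if (identical(attr(preds_a, "scale"), "link")) "pd_link" else "pd_resp"
  attr(out, "draws") <- dd
  out
}

#' Local slopes of the posterior predictions by finite differences
#'
#' Central difference (f(x + h/2) - f(x - h/2)) / h of the response-scale
#' posterior predictions with respect to a continuous predictor, per draw and
#' grid point. Where x +/- h/2 leaves the observed support a one-sided
#' difference is used and flagged.
#'
#' @param fit a \code{posterior_fit}.
#' @param predictor continuous predictor name.
#' @param grid covariate grid (rows = evaluation points).
#' @param h step size; default 1% of the predictor's observed range.
#' @param scale prediction scale.
#' @return list with \code{slopes} (ndraws x npoints), \code{x}, \code{h},
#'   \code{one_sided} (logical flags per point).
#' @export
finite_diff_slope <- function(fit, predictor, grid, h = NULL,
                              scale = c("response", "link")) {
  scale <- match.arg(scale)
  x_obs <- as.numeric(fit$design$data[[predictor]])
  if (is.null(x_obs)) stop("unknown predictor: ", predictor)
  rng <- range(x_obs)
  if (is.null(h)) h <- 0.01 * diff(rng)
  if (h <= 0) stop("h must be positive")
  x0 <- as.numeric(grid[[predictor]])
  lo <- x0 - h / 2
  hi <- x0 + h / 2
  one_sided <- lo < rng[1] | hi > rng[2]
  lo <- pmax(lo, rng[1])
  hi <- pmin(hi, rng[2])
  gl <- grid; gl[[predictor]] <- lo
  gh <- grid; gh[[predictor]] <- hi
  pl <- marginal_predictions(fit, gl, scale = scale)
  ph <- marginal_predictions(fit, gh, scale = scale)
  slopes <- sweep(ph - pl, 2, hi - lo, "/")
  list(slopes = slopes, x = x0, h = h, one_sided = one_sided)
}

#' Predictor-half contrast of posterior predictions
#'
#' Splits the grid at the median (or mean) of a continuous predictor and
#' summarizes, per draw, the average response-scale prediction over the upper
#' half minus the lower half. A compact scalar summary of a smooth effect.
#'
#' @param fit a \code{posterior_fit}.
#' @param predictor continuous predictor name.
#' @param grid covariate grid; defaults to the fitted data's covariates.
#' @param split \code{"median"} (default) or \code{"mean"}.
#' @param scale prediction scale.
#' @return a \code{summary_stats} row with attribute \code{"draws"}.
#' @export
half_split_contrast <- function(fit, predictor, grid = NULL,
                                split = c("median", "mean"),
                                scale = c("response", "link")) {
  split <- match.arg(split)
  scale <- match.arg(scale)
  if (is.null(grid)) grid <- fit$design$data
  x <- as.numeric(grid[[predictor]])
  if (is.null(grid[[predictor]])) stop("unknown predictor: ", predictor)
  cut <- if (split == "median") stats::median(x) else mean(x)
  upper <- x > cut
  lower <- x <= cut
  if (!any(upper) || !any(lower)) stop("empty predictor half at the ", split)
  preds <- marginal_predictions(fit, grid, scale = scale)
  dd <- rowMeans(preds[, upper, drop = FALSE]) -
    rowMeans(preds[, lower, drop = FALSE])
  out <- summary_stats(dd, label = paste0("half_split(", predictor, ")"))
  out$pd_label <- if (scale == "link") "pd_link" else "pd_resp"
  attr(out, "draws") <- dd
  out
}

#' Bayesian R-squared
#'
#' Per draw, var(fit) / (var(fit) + var(residual)) on the response scale,
#' with the model-implied residual variance (binomial: n p (1-p); Gaussian:
#' sigma^2 plus any known observation variance; Gamma: mu^2 / shape).
#' Predictions include the fitted group effects.
#'
#' @param fit a \code{posterior_fit}.
#' @return \code{summary_stats} row with per-draw values as attribute
#'   \code{"draws"}.
#' @export
bayes_r2 <- function(fit) {
  data <- fit$design$data
  eta <- eta_draws(fit, data, include_groups = TRUE)
  pm <- fit$design$pmap
  fam <- fit$spec$family
  nd <- nrow(eta)
  if (fam == "binomial") {
    tr <- fit$design$trials
    mu <- stats::plogis(eta) * rep(tr, each = nd)
    vres <- rowMeans(stats::plogis(eta) * (1 - stats::plogis(eta)) *
                       rep(tr, each = nd))
  } else if (fam == "gaussian") {
    mu <- eta
    sig2 <- exp(2 * fit$draws[, pmap_idx(pm, "log_sigma")])
    vres <- sig2 + if (is.null(fit$design$se)) 0 else mean(fit$design$se^2)
  } else {
    mu <- exp(eta)
    shp <- exp(fit$draws[, pmap_idx(pm, "log_shape")])
    vres <- rowMeans(mu^2) / shp
  }
  vfit <- apply(mu, 1, stats::var)
  if (all(vfit + vres == 0)) stop("zero total variance")
  r2 <- vfit / (vfit + vres)
  out <- summary_stats(r2, label = "bayes_r2")
  attr(out, "draws") <- r2
  out
}

#' Intra-class correlation via posterior-predictive variance decomposition
#'
#' Per draw, simulates the posterior predictive over the observed design with
#' freshly drawn group effects and with group effects removed; the ICC is the
#' share of predictive variance attributable to the grouping. The Monte-Carlo
#' estimator can be slightly negative.
#'
#' @param fit a \code{posterior_fit}.
#' @param grouping grouping variable name (must match the fitted random
#'   term).
#' @param seed RNG seed for the predictive simulation.
#' @return \code{summary_stats} row with per-draw values as attribute
#'   \code{"draws"}.
#' @export
icc <- function(fit, grouping = fit$spec$random$group, seed = 1) {
  design <- fit$design
  gb <- NULL
  for (bi in seq_along(design$blocks))
    if (design$blocks[[bi]]$type == "group" &&
        design$blocks[[bi]]$group == grouping) gb <- bi
  if (is.null(gb)) stop("unknown grouping: ", grouping)
  b <- design$blocks[[gb]]
  pm <- design$pmap
  set.seed(as.integer(seed))
  eta0 <- eta_draws(fit, design$data, include_groups = FALSE)
  nd <- nrow(eta0)
  taud <- exp(fit$draws[, pmap_idx(pm, "group_logtau", gb), drop = FALSE])
  corr_idx <- if (b$correlated) pmap_idx(pm, "group_corr", gb) else integer(0)
  fam <- fit$spec$family
  sim_y <- function(eta, s) {
    mu <- switch(fam, binomial = stats::plogis(eta), gaussian = eta,
                 gamma = exp(eta))
    switch(fam,
           binomial = stats::rbinom(length(eta), design$trials, mu),
           gaussian = stats::rnorm(length(eta), mu,
                                   sqrt(exp(2 * fit$draws[s, pmap_idx(pm, "log_sigma")]) +
                                          if (is.null(design$se)) 0 else design$se^2)),
           gamma = {
             shp <- exp(fit$draws[s, pmap_idx(pm, "log_shape")])
             stats::rgamma(length(eta), shape = shp, rate = shp / mu)
           })
  }
  iccs <- numeric(nd)
  for (s in seq_len(nd)) {
    L <- if (b$correlated)
      chol_from_raw(fit$draws[s, corr_idx], b$K, fit$spec$priors$lkj_eta)$L
    else diag(b$K)
    z_new <- matrix(stats::rnorm(b$J * b$K), b$J, b$K)
    b_new <- (z_new %*% t(L)) * rep(taud[s, ], each = b$J)
    eta_g <- eta0[s, ] + rowSums(b$Tm * b_new[b$gidx, , drop = FALSE])
    y_with <- sim_y(eta_g, s)
    y_without <- sim_y(eta0[s, ], s)
    v_with <- stats::var(y_with)
    iccs[s] <- if (v_with == 0) 0 else (v_with - stats::var(y_without)) / v_with
  }
  out <- summary_stats(iccs, label = paste0("icc(", grouping, ")"))
  attr(out, "draws") <- iccs
  out
}
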