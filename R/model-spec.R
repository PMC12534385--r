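#' Prior set for hierarchical Bayesian models
#'
#' Weakly informative priors on population-level effects and weakly
#' regularizing priors on group-level and smoothness-controlling parameters.
#' The intercept prior is centered on the empirical link-scale mean of the
#' response (data-derived location), computed when the design is built.
#'
#' @param fixed_scale normal prior scale for population-level coefficients.
#' @param intercept_scale normal prior scale for the intercept.
#' @param intercept_location intercept prior location; \code{NULL} (default)
#'   derives it from the data as the empirical link-scale response mean.
#' @param sd_scale half-normal scale for group-level SDs and smooth SDs.
#' @param lkj_eta LKJ concentration for group-level correlation matrices.
#' @param dirichlet_alpha Dirichlet concentration for monotonic simplexes.
#' @return an object of class \code{prior_set}.
#' @export
prior_set <- function(fixed_scale = 2.5, intercept_scale = 2.5,
                      intercept_location = NULL, sd_scale = 1,
                      lkj_eta = 2, dirichlet_alpha = 1) {
  stopifnot(fixed_scale > 0, intercept_scale > 0, sd_scale > 0, lkj_eta > 0,
            dirichlet_alpha > 0)
  structure(list(fixed_scale = fixed_scale, intercept_scale = intercept_scale,
                 intercept_location = intercept_location,
                 sd_scale = sd_scale, lkj_eta = lkj_eta,
                 dirichlet_alpha = dirichlet_alpha),
            class = "prior_set")
}

#' Penalized smooth term
#'
#' A low-rank thin-plate regression spline of a continuous covariate. With
#' \code{by}, a reference smooth over all observations is complemented by one
#' difference (deviation) smooth per level of the (possibly interacted)
#' factor(s), each sum-to-zero constrained within its level, encoding a
#' smooth-by-factor interaction.
#'
#' @param var continuous covariate name.
#' @param k basis dimension (default 6).
#' @param by optional character vector of factor names whose interaction
#'   levels get difference smooths.
#' @return an object of class \code{smooth_term}.
#' @export
smooth_term <- function(var, k = 6, by = NULL) {
  structure(list(var = var, k = k, by = by), class = "smooth_term")
}

#' Grouped random-effect term
#'
#' Group-level (random) intercept and slopes drawn from a multivariate
#' Gaussian over groups, with an unstructured correlation matrix (LKJ prior)
#' when \code{correlated}.
#'
#' @param group grouping variable name (e.g. subject id).
#' @param terms character vector of random terms: \code{"1"} for the
#'   intercept plus names of slope variables (binary factors or numerics).
#' @param correlated logical; if \code{FALSE} effects are independent.
#' @return an object of class \code{random_term}.
#' @export
random_term <- function(group, terms = "1", correlated = TRUE) {
  structure(list(group = group, terms = terms, correlated = correlated),
            class = "random_term")
}

#' Specify a hierarchical Bayesian regression model
#'
#' Supported families: binomial with logit link (counts out of
#' \code{trials}), Gaussian with identity link (optionally with known
#' per-observation standard errors added in quadrature to the residual
#' scale), and Gamma with log link. Categorical predictors use orthonormal
#' contrast coding so that marginal priors on all pairwise level differences
#' are equal.
#'
#' @param family \code{"binomial"}, \code{"gaussian"} or \code{"gamma"}.
#' @param response response column name.
#' @param fixed character vector of population-level terms; interactions as
#'   \code{"a:b"}.
#' @param trials binomial trials: column name or a single number.
#' @param se optional column of known per-observation SEs (Gaussian only).
#' @param smooths list of \code{\link{smooth_term}}.
#' @param monotonic character vector of ordinal predictors (integer values
#'   0..D) modeled with monotone simplex effects.
#' @param random a \code{\link{random_term}} or \code{NULL}.
#' @param factors character vector naming variables to treat as factors;
#'   character/factor/logical columns are treated as factors automatically.
#' @param priors a \code{\link{prior_set}}.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(family = c("binomial", "gaussian", "gamma"),
                       response, fixed = character(), trials = NULL, se = NULL,
                       smooths = list(), monotonic = character(),
                       random = NULL, factors = character(),
                       priors = prior_set()) {
  family <- match.arg(family)
  if (family == "binomial" && is.null(trials))
    stop("binomial family requires trials")
  if (!is.null(se) && family != "gaussian")
    stop("known observation SE is only supported for the gaussian family")
  if (inherits(smooths, "smooth_term")) smooths <- list(smooths)
  stopifnot(all(vapply(smooths, inherits, TRUE, "smooth_term")))
  if (!is.null(random)) stopifnot(inherits(random, "random_term"))
  stopifnot(inherits(priors, "prior_set"))
  structure(list(family = family, response = response, fixed = fixed,
                 trials = trials, se = se, smooths = smooths,
                 monotonic = monotonic, random = random, factors = factors,
                 priors = priors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s(%s)\n", x$family, x$response))
  if (length(x$fixed)) cat("  fixed:", paste(x$fixed, collapse = " + "), "\n")
  for (s in x$smooths)
    cat(sprintf("  smooth: s(%s, k=%d)%s\n", s$var, s$k,
                if (is.null(s$by)) "" else paste0(" by ", paste(s$by, collapse = ":"))))
  if (length(x$monotonic)) cat("  monotonic:", paste(x$monotonic, collapse = ", "), "\n")
  if (!is.null(x$random))
    cat(sprintf("  random: (%s | %s)%s\n", paste(x$random$terms, collapse = " + "),
                x$random$group, if (x$random$correlated) " correlated" else ""))
  invisible(x)
}
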