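#' Orthonormal contrast coding
#'
#' A k x (k-1) coding matrix whose columns are mutually orthonormal and
#' orthogonal to the constant vector. With this coding the implied marginal
#' priors on all pairwise differences between factor levels are equal, so
#' factor effects can be read as classical main effects.
#'
#' @param k number of factor levels (>= 2).
#' @return k x (k-1) matrix C with t(C) %*% C = I and colSums(C) = 0;
#'   deterministic in k.
#' @export
orthonormal_contrasts <- function(k) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  # Gram-Schmidt on centered level indicators, with a fixed sign convention
  # (first nonzero entry of each column positive).
  M <- diag(k) - 1 / k
  qr_ <- qr(M)
  C <- qr.Q(qr_)[, seq_len(k - 1), drop = FALSE]
  for (j in seq_len(ncol(C))) {
    nz <- which(abs(C[, j]) > 1e-12)[1]
    if (C[nz, j] < 0) C[, j] <- -C[, j]
  }
  C
}

#' Low-rank thin-plate regression spline basis
#'
#' Penalized thin-plate regression spline basis for a single continuous
#' covariate, with the sum-to-zero identifiability constraint absorbed. The
#' wiggliness penalty is positive semidefinite with the linear trend in its
#' nullspace. Basis and penalty construction are delegated to
#' \code{mgcv::smoothCon}.
#'
#' @param x covariate values (>= k distinct values).
#' @param k basis dimension before constraint absorption (>= 3).
#' @return list with \code{X} (n x (k-1) basis), \code{S} (penalty),
#'   \code{smooth} (the mgcv smooth object, for prediction).
#' @export
tprs_basis <- function(x, k = 10) {
  if (k < 3) stop("k must be >= 3")
  if (length(unique(x)) < k)
    stop("need at least k distinct covariate values")
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = k), data = dat,
                        absorb.cons = TRUE)[[1]]
  list(X = sm$X, S = sm$S[[1]], smooth = sm)
}

# Mixed-model reparameterization of a tprs smooth: fixed null-space columns
# (linear trend) plus penalized columns with iid N(0, sd^2) coefficients.
# Returns the transform needed to evaluate the smooth at new data.
tprs_mixed <- function(x, k = 10) {
  b <- tprs_basis(x, k)
  rp <- mgcv::smooth2random(b$smooth, "", type = 2)
  list(Xf = rp$Xf, Zr = rp$rand[[1]], rp = rp, smooth = b$smooth)
}

# Evaluate a reparameterized smooth at new covariate values; follows the
# prediction recipe documented for mgcv::smooth2random.
tprs_mixed_predict <- function(mixed, x_new) {
  sm <- mixed$smooth
  re <- mixed$rp
  X <- mgcv::PredictMat(sm, data.frame(x = x_new))
  if (!is.null(re$trans.U)) X <- X %*% re$trans.U
  X <- t(t(X) * re$trans.D)
  pen.ind <- re$pen.ind
  if (!is.null(re$rind)) {
    X[, re$rind] <- X[, re$pen.ind != 0]
    pen.ind[re$rind] <- pen.ind[pen.ind > 0]
  }
  list(Xf = X[, which(re$pen.ind == 0), drop = FALSE],
       Zr = X[, which(pen.ind == 1), drop = FALSE])
}

#' Monotonic effect of an ordinal predictor
#'
#' Encodes an ordinal predictor taking values 0..D via a simplex of D
#' nonnegative increment weights zeta (summing to 1) and a scale beta: the
#' effect at level x is beta times the cumulative weight sum up to x, so it is
#' 0 at the lowest level, beta at the highest, and monotone in between for
#' fixed beta.
#'
#' @param x integer ordinal values in 0..D.
#' @param zeta simplex weights (length D, nonnegative, summing to 1).
#' @param beta effect scale.
#' @return numeric effect per observation.
#' @export
monotonic_encoding <- function(x, zeta, beta) {
  if (any(zeta < 0)) stop("simplex weights must be nonnegative")
  if (abs(sum(zeta) - 1) > 1e-8) stop("simplex weights must sum to 1")
  D <- length(zeta)
  x <- as.integer(x)
  if (any(x < 0 | x > D)) stop("ordinal values must lie in 0..D")
  cz <- c(0, cumsum(zeta))
  beta * cz[x + 1L]
}
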