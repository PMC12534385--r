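# Convergence diagnostics: rank-normalized split-Rhat and bulk/tail effective
# sample size (the current standard definitions).

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chain_matrix <- function(x, chain) {
  # x: draws vector; chain: chain index per draw -> matrix draws x (2*chains)
  chains <- sort(unique(chain))
  cols <- list()
  for (ch in chains) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    cols[[length(cols) + 1]] <- v[seq_len(h)]
    cols[[length(cols) + 1]] <- v[h + seq_len(h)]
  }
  len <- min(lengths(cols))
  vapply(cols, function(v) v[seq_len(len)], numeric(len))
}

basic_rhat <- function(m) {
  # m: iterations x chains
  n <- nrow(m)
  if (n < 3) return(NA_real_)
  means <- colMeans(m)
  vars <- apply(m, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

chain_ess <- function(m) {
  # effective sample size via FFT autocovariance and Geyer's initial
  # monotone positive sequence, combined over chains
  n <- nrow(m); nch <- ncol(m)
  if (n < 3) return(NA_real_)
  acov <- apply(m, 2, function(v) {
    v <- v - mean(v)
    np <- stats::nextn(2 * n)
    f <- stats::fft(c(v, rep(0, np - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / np
    ac / ac[1] * stats::var(v) * (n - 1) / n
  })
  if (anyNA(acov[1, ]) || all(acov[1, ] == 0)) return(NA_real_)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (nch > 1) var_plus <- var_plus + stats::var(colMeans(m))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: paired sums, initial positive monotone sequence
  max_t <- 1
  t <- 1
  rho_hat_even <- 1
  rho_hat_odd <- rho[2]
  rho_keep <- numeric(n)
  rho_keep[1] <- rho_hat_even
  rho_keep[2] <- rho_hat_odd
  while (t < n - 4 && !is.na(rho_hat_even + rho_hat_odd) &&
         rho_hat_even + rho_hat_odd > 0) {
    t <- t + 2
    rho_hat_even <- rho[t]
    rho_hat_odd <- rho[t + 1]
    if (!is.na(rho_hat_even + rho_hat_odd) && rho_hat_even + rho_hat_odd >= 0) {
      rho_keep[t] <- rho_hat_even
      rho_keep[t + 1] <- rho_hat_odd
      max_t <- t + 1
    }
  }
  # enforce monotone decreasing paired sums
  ps <- rho_keep[seq_len(max_t)]
  if (max_t >= 4) {
    for (t in seq(3, max_t - 1, by = 2)) {
      pair <- ps[t] + ps[t + 1]
      prev <- ps[t - 2] + ps[t - 1]
      if (pair > prev) {
        ps[t] <- prev / 2
        ps[t + 1] <- prev / 2
      }
    }
  }
  tau <- -1 + 2 * sum(ps[seq_len(max_t)])
  max(nch * n / max(tau, 1 / log10(nch * n)), 0)
}

#' Rank-normalized split-Rhat
#'
#' @param x draws of one quantity.
#' @param chain chain index per draw (single chain if NULL).
#' @return potential scale reduction factor.
#' @export
rhat <- function(x, chain = NULL) {
  if (is.null(chain)) chain <- rep(1L, length(x))
  m <- split_chain_matrix(x, chain)
  z <- matrix(rank_normalize(as.vector(m)), nrow(m), ncol(m))
  basic_rhat(z)
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized draws; measures sampling efficiency for
#' location summaries.
#' @inheritParams rhat
#' @return effective sample size.
#' @export
ess_bulk <- function(x, chain = NULL) {
  if (is.null(chain)) chain <- rep(1L, length(x))
  m <- split_chain_matrix(x, chain)
  z <- matrix(rank_normalize(as.vector(m)), nrow(m), ncol(m))
  chain_ess(z)
}

#' Tail effective sample size
#'
#' Minimum of the ESS of the 5% and 95% quantile indicator draws; measures
#' efficiency for interval summaries.
#' @inheritParams rhat
#' @return effective sample size.
#' @export
ess_tail <- function(x, chain = NULL) {
  if (is.null(chain)) chain <- rep(1L, length(x))
  m <- split_chain_matrix(x, chain)
  q <- stats::quantile(as.vector(m), c(0.05, 0.95), names = FALSE)
  ess_q <- vapply(q, function(qq) {
    ind <- matrix(as.numeric(m <= qq), nrow(m), ncol(m))
    z <- matrix(rank_normalize(as.vector(ind)), nrow(m), ncol(m))
    chain_ess(z)
  }, numeric(1))
  min(ess_q)
}

mcmc_diagnostics <- function(draws, chain) {
  data.frame(
    parameter = colnames(draws),
    rhat = apply(draws, 2, rhat, chain = chain),
    ess_bulk = apply(draws, 2, ess_bulk, chain = chain),
    ess_tail = apply(draws, 2, ess_tail, chain = chain),
    row.names = NULL)
}
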