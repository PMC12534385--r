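#' Probability of direction
#'
#' The larger of the proportions of posterior samples above or below zero,
#' ranging between 0.5 and 1. Draws exactly equal to zero are split evenly
#' between the two sides (a measure-zero event for continuous draws).
#'
#' @param samples draws of one quantity.
#' @return pd in [0.5, 1].
#' @export
pd <- function(samples) {
  if (length(samples) == 0) stop("pd of an empty sample is undefined")
  n <- length(samples)
  zeros <- sum(samples == 0)
  pos <- sum(samples > 0) + zeros / 2
  neg <- sum(samples < 0) + zeros / 2
  max(pos, neg) / n
}

#' Convert pd to a two-sided p-value and an evidence ratio
#'
#' pd corresponds to a two-sided p-value of 2(1 - pd) (a pd of 0.975 maps to
#' p = 0.05), and to the posterior evidence ratio ER = pd / (1 - pd). A pd of
#' exactly 1 maps to ER = Inf.
#'
#' @param pd_value probability of direction in [0.5, 1].
#' @return list with \code{p} and \code{er}.
#' @export
pd_to_p_and_er <- function(pd_value) {
  if (any(pd_value < 0.5 | pd_value > 1))
    stop("pd must lie in [0.5, 1]")
  list(p = 2 * (1 - pd_value),
       er = ifelse(pd_value == 1, Inf, pd_value / (1 - pd_value)))
}

#' Highest density interval from posterior samples
#'
#' The shortest contiguous interval containing \code{ceiling(mass * n)} of
#' the sorted samples; ties between equally short windows are broken in favor
#' of the lower interval.
#'
#' @param samples posterior draws.
#' @param mass probability mass in (0, 1].
#' @return numeric c(lower, upper).
#' @export
hdi <- function(samples, mass = 0.9) {
  if (length(samples) == 0) stop("hdi of an empty sample is undefined")
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k < 2) stop("too few samples for the requested mass")
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[seq(k, n)] - x[seq_len(n - k + 1)]
  i <- which.min(widths)   # which.min takes the first (lowest) minimum
  c(x[i], x[i + k - 1])
}

#' Summarize posterior draws of one quantity
#'
#' Median, tiered highest-density intervals (66/90/95%), probability of
#' direction and evidence ratio.
#'
#' @param samples posterior draws.
#' @param label optional quantity name.
#' @return an object of class \code{summary_stats} (one-row data.frame).
#' @export
summary_stats <- function(samples, label = NULL) {
  h66 <- hdi(samples, 0.66)
  h90 <- hdi(samples, 0.90)
  h95 <- hdi(samples, 0.95)
  pdv <- pd(samples)
  er <- pd_to_p_and_er(pdv)$er
  out <- data.frame(
    quantity = if (is.null(label)) NA_character_ else label,
    median = stats::median(samples),
    hdi66_lo = h66[1], hdi66_hi = h66[2],
    hdi90_lo = h90[1], hdi90_hi = h90[2],
    hdi95_lo = h95[1], hdi95_hi = h95[2],
    pd = pdv, er = er)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("%s: median %.3f, 90%% HDI [%.3f, %.3f], pd %.3f (ER %.1f)\n",
              ifelse(is.na(x$quantity), "quantity", x$quantity),
              x$median, x$hdi90_lo, x$hdi90_hi, x$pd, x$er))
  invisible(x)
}
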