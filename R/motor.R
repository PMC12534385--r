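#' Detect pedal crossings in a photocell voltage trace
#'
#' Returns the times at which the voltage crosses \code{threshold} upward,
#' with linear interpolation between samples for sub-sample timing. Crossings
#' closer than \code{refractory_s} to the previous accepted crossing are
#' suppressed (a light-barrier pulse can produce multiple edges).
#'
#' @param voltage numeric vector of photocell samples.
#' @param sample_rate_hz sampling rate (default 100 Hz, the rate of the
#'   light-barrier recording).
#' @param threshold crossing threshold in volts; default is the midpoint of
#'   the trace's range.
#' @param refractory_s dead time after an accepted crossing (s).
#' @param t0 time of the first sample (s).
#' @return strictly increasing numeric vector of crossing times (class
#'   \code{crossing_times}).
#' @export
detect_crossings <- function(voltage, sample_rate_hz = 100, threshold = NULL,
                             refractory_s = 0.25, t0 = 0) {
  stopifnot(all(is.finite(voltage)), sample_rate_hz > 0, refractory_s >= 0)
  if (is.null(threshold)) threshold <- mean(range(voltage))
  below <- voltage[-length(voltage)] < threshold
  above <- voltage[-1] >= threshold
  idx <- which(below & above)
  if (length(idx) == 0) stop("insufficient events: no upward crossings found")
  frac <- (threshold - voltage[idx]) / (voltage[idx + 1] - voltage[idx])
  times <- t0 + (idx - 1 + frac) / sample_rate_hz
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times <- times[keep]
  if (length(times) < 2) stop("insufficient events: fewer than 2 crossings")
  crossing_times(times)
}

#' Pedal crossing-time series
#'
#' @param times_s strictly increasing event times in seconds.
#' @return numeric vector with class \code{crossing_times}.
#' @export
crossing_times <- function(times_s) {
  times_s <- as.numeric(times_s)
  if (length(times_s) < 2) stop("need at least 2 crossing times")
  if (any(diff(times_s) <= 0)) stop("crossing times must be strictly increasing")
  structure(times_s, class = "crossing_times")
}

# revolution durations between consecutive crossings (complete revolutions only)
revolution_durations <- function(times) {
  d <- diff(as.numeric(times))
  if (any(d <= 0)) stop("clock violation: nonpositive revolution duration")
  d
}

#' Mean pedaling speed and coefficient of variation
#'
#' Speed in Hz is the average inverse revolution duration; the CV is the
#' sample (n-1) standard deviation of the instantaneous speed (inverse
#' revolution duration) divided by the mean speed.
#'
#' @param times crossing times (any numeric vector of strictly increasing
#'   seconds).
#' @return list with \code{mean_speed_hz}, \code{cv}, \code{n_revolutions}.
#' @export
speed_and_cv <- function(times) {
  d <- revolution_durations(times)
  if (length(d) < 2) stop("need at least 2 complete revolutions for speed/CV")
  s <- 1 / d
  m <- mean(s)
  list(mean_speed_hz = m, cv = stats::sd(s) / m,
       n_revolutions = length(d))
}

#' Inter-beat deviation
#'
#' Synchronization error against isochronous stimulation: the mean absolute
#' deviation between each revolution duration and half the stimulus-onset
#' asynchrony (the pedaling target period, 1 s for the standard 2 s SOA).
#' Under self-initiated stimulation the stimulus onsets are defined by the
#' pedaling itself, so the deviation is zero by construction.
#'
#' @param times crossing times.
#' @param mode \code{"isochronous"} or \code{"self_initiated"}.
#' @param soa_s stimulus-onset asynchrony in seconds (required in isochronous
#'   mode; the standard design uses 2 s).
#' @return mean absolute deviation in seconds.
#' @export
ibd <- function(times, mode = c("isochronous", "self_initiated"), soa_s = 2) {
  mode <- match.arg(mode)
  if (mode == "self_initiated") return(0)
  if (is.null(soa_s) || !is.finite(soa_s) || soa_s <= 0)
    stop("isochronous mode requires a positive soa_s")
  d <- revolution_durations(times)
  mean(abs(d - soa_s / 2))
}

#' Summarize pedal timing for one session
#'
#' @param times crossing times.
#' @param mode stimulation mode.
#' @param soa_s stimulus-onset asynchrony (isochronous mode).
#' @return an object of class \code{motor_summary}: list with
#'   \code{mean_speed_hz}, \code{cv}, \code{ibd_s}, \code{n_revolutions},
#'   \code{mode}, \code{soa_s}.
#' @export
motor_summary <- function(times, mode = c("isochronous", "self_initiated"),
                          soa_s = 2) {
  mode <- match.arg(mode)
  sc <- speed_and_cv(times)
  structure(
    list(mean_speed_hz = sc$mean_speed_hz, cv = sc$cv,
         ibd_s = ibd(times, mode, soa_s), n_revolutions = sc$n_revolutions,
         mode = mode, soa_s = if (mode == "isochronous") soa_s else NA_real_),
    class = "motor_summary")
}

#' @export
print.motor_summary <- function(x, ...) {
  cat(sprintf("<motor_summary> %s: %.3f Hz over %d revolutions, CV %.4f, IBD %.4f s\n",
              x$mode, x$mean_speed_hz, x$n_revolutions, x$cv, x$ibd_s))
  invisible(x)
}

#' Motor metrics table from per-session crossing timestamps
#'
#' @param timestamps data.frame with columns \code{subject_id},
#'   \code{session}, \code{condition} (\code{"isochronous"} /
#'   \code{"self_initiated"}), \code{time_s}.
#' @param soa_s SOA for isochronous sessions.
#' @return data.frame with one row per subject x session and columns
#'   \code{mean_speed_hz}, \code{cv}, \code{ibd_s}, \code{n_revolutions}.
#' @export
motor_metrics_table <- function(timestamps, soa_s = 2) {
  req <- c("subject_id", "session", "condition", "time_s")
  stopifnot(all(req %in% names(timestamps)))
  keys <- unique(timestamps[c("subject_id", "session", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- timestamps$subject_id == keys$subject_id[i] &
      timestamps$session == keys$session[i] &
      timestamps$condition == keys$condition[i]
    ms <- motor_summary(crossing_times(sort(timestamps$time_s[sel])),
                        mode = as.character(keys$condition[i]), soa_s = soa_s)
    cbind(keys[i, , drop = FALSE],
          data.frame(mean_speed_hz = ms$mean_speed_hz, cv = ms$cv,
                     ibd_s = ms$ibd_s, n_revolutions = ms$n_revolutions))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthesize a photocell voltage trace from crossing times
#'
#' Inverse of \code{\link{detect_crossings}} for round-trip testing: a
#' baseline-level trace with rectangular pulses starting at each crossing
#' time.
#'
#' @param times crossing times (s).
#' @param sample_rate_hz sampling rate.
#' @param pulse_s pulse width (s).
#' @param low,high baseline and pulse voltage levels.
#' @param duration_s total trace length; defaults to last crossing + 1 s.
#' @return list with \code{voltage}, \code{sample_rate_hz}.
#' @export
synthesize_trace <- function(times, sample_rate_hz = 100, pulse_s = 0.1,
                             low = 0, high = 5, duration_s = NULL) {
  times <- as.numeric(times)
  if (is.null(duration_s)) duration_s <- max(times) + 1
  n <- ceiling(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  v <- rep(low, n)
  for (tt in times) v[t >= tt & t < tt + pulse_s] <- high
  list(voltage = v, sample_rate_hz = sample_rate_hz)
}
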