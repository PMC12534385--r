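# Synthetic study generator: produces study tables, pedal timestamp series
# and pitch-test response logs with the statistical structure the analysis
# assumes, plus the generating truth for recovery experiments.

#' Ground-truth parameters for synthetic studies
#'
#' Effects are stated as interpretable link-scale differences (second level
#' minus first) and converted internally onto the orthonormal design coding.
#' Defaults anchor the magnitudes at the study-scale response anchors: about
#' 0.9 words less on day 2 at a ~20% baseline recall rate, about 1.6 words
#' more in session 2, a weak condition effect, a 7-10% pedaling speed surplus
#' over the 1 Hz target, and lower cadence variability under isochronous
#' stimulation. The pitch index distribution is a shifted Beta on [-1, 1]
#' matched by moments to mean 0.36 / SD 0.33 (left-skewed).
#'
#' @param ... named overrides of any default field.
#' @return an object of class \code{truth_params}.
#' @export
truth_params <- function(...) {
  tp <- list(
    # memory model (link = log-odds scale)
    intercept_logit = -1.35,
    day2_minus_day1 = -0.14,
    iso_minus_self = 0.07,
    condday_interaction = 0,
    session2_minus_session1 = 0.25,
    pitch_slope = 0.15,
    pitch_cond = 0, pitch_day = 0,
    pitch_cond_day = 0.34,
    music_slope = 0.01,
    sleep_mean_slope = 0.05,
    sleep_dev_slope = 0.05, sleep_dev_day = 0,
    languages_beta = 0.15,
    languages_zeta = NULL,       # default: uniform simplex
    sd_intercept = 0.7, sd_cond = 0.12, sd_day = 0.12,
    re_corr = NULL,              # default: identity correlation
    # subject covariates
    pitch_mean = 0.36, pitch_sd = 0.33,
    sleep_typical_mean = 7.2, sleep_typical_sd = 0.6, sleep_night_sd = 0.5,
    music_zero_prob = 0.35, music_mean_years = 8, music_shape = 2,
    languages_max = 5, languages_prob = 0.5,
    # pedaling
    target_speed_hz = 1.0,
    speed_bias = c(isochronous = 0.10, self_initiated = 0.05),
    speed_bias_subject_sd = 0.04,
    sdlog = c(isochronous = 0.045, self_initiated = 0.08),
    n_revolutions = 1560, soa_s = 2,
    # missing-fundamental observer
    mf_difficulty_weight = 0.8)
  override <- list(...)
  unknown <- setdiff(names(override), names(tp))
  if (length(unknown)) stop("unknown truth fields: ", paste(unknown, collapse = ", "))
  tp[names(override)] <- override
  stopifnot(tp$sd_intercept >= 0, tp$sd_cond >= 0, tp$sd_day >= 0,
            all(tp$sdlog > 0), tp$pitch_sd > 0)
  structure(tp, class = "truth_params")
}

# method-of-moments Beta on [-1, 1]
beta_moments_ab <- function(mean_, sd_) {
  m <- (mean_ + 1) / 2
  s <- sd_ / 2
  if (m <= 0 || m >= 1) stop("infeasible mean for Beta on [-1, 1]")
  t <- m * (1 - m) / s^2 - 1
  if (t <= 0) stop("infeasible mean/SD combination for the Beta family")
  c(a = m * t, b = (1 - m) * t)
}

#' Generate a synthetic subject table
#'
#' Pitch index from a moment-matched shifted Beta on [-1, 1]; balanced sex
#' and condition order; years of musical training from a zero-inflated Gamma;
#' number of foreign languages Binomial(5, 0.5) (mean 2.5); typical sleep
#' duration Gaussian.
#'
#' @param n number of subjects (>= 2).
#' @param truth a \code{truth_params}.
#' @param seed integer seed.
#' @return data.frame with one row per subject.
#' @export
gen_subjects <- function(n, truth = truth_params(), seed = 1) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  ab <- beta_moments_ab(truth$pitch_mean, truth$pitch_sd)
  pitch <- 2 * stats::rbeta(n, ab["a"], ab["b"]) - 1
  sex <- rep(c("f", "m"), length.out = n)[sample.int(n)]
  cond_order <- rep(c("iso_first", "self_first"), length.out = n)[sample.int(n)]
  music <- ifelse(stats::runif(n) < truth$music_zero_prob, 0,
                  stats::rgamma(n, shape = truth$music_shape,
                                rate = truth$music_shape / truth$music_mean_years))
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    pitch_index = pitch,
    sex = sex,
    condition_order = cond_order,
    music_years = round(music, 1),
    n_languages = stats::rbinom(n, truth$languages_max, truth$languages_prob),
    sleep_typical = stats::rnorm(n, truth$sleep_typical_mean,
                                 truth$sleep_typical_sd))
}

# 4 design rows per subject: condition order fixes the session:condition map.
design_rows <- function(subjects) {
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    first <- if (s$condition_order == "iso_first") "isochronous" else "self_initiated"
    second <- setdiff(c("isochronous", "self_initiated"), first)
    data.frame(subject_id = s$subject_id,
               session = rep(c("1", "2"), each = 2),
               condition = rep(c(first, second), each = 2),
               day = rep(c("1", "2"), 2))
  })
  do.call(rbind, rows)
}

# Linear memory model used both to generate and to fit (shared code path).
recovery_model_spec <- function(priors = prior_set()) {
  model_spec("binomial", "recalled", trials = "trials",
             fixed = c("condition", "day", "condition:day", "session"),
             random = random_term("subject_id", c("1", "condition", "day")),
             priors = priors)
}

# Map the interpretable truth differences onto the orthonormal design coding
# of a built design. Unmentioned columns get 0.
truth_beta <- function(truth, design) {
  C2 <- orthonormal_contrasts(2)
  dC <- C2[2, 1] - C2[1, 1]      # coded level-2 minus level-1
  nm <- colnames(design$X)
  beta <- stats::setNames(rep(0, length(nm)), nm)
  put <- function(col, val) {
    if (col %in% nm) beta[col] <<- val
  }
  put("(Intercept)", truth$intercept_logit)
  put("condition", truth$iso_minus_self / (-dC))   # isochronous is level 1
  put("day", truth$day2_minus_day1 / dC)
  put("condition:day", truth$condday_interaction / (-dC * dC))
  put("session", truth$session2_minus_session1 / dC)
  put("pitch_index", truth$pitch_slope)
  put("pitch_index:condition", truth$pitch_cond / (-dC))
  put("pitch_index:day", truth$pitch_day / dC)
  put("pitch_index:condition:day", truth$pitch_cond_day / (-dC * dC))
  put("music_years", truth$music_slope)
  put("sleep_mean", truth$sleep_mean_slope)
  put("sleep_dev", truth$sleep_dev_slope)
  put("sleep_dev:day", truth$sleep_dev_day / dC)
  beta
}

#' Generate binomial recall rows from known truth
#'
#' Builds the same linear predictor the fitted model uses (identical design
#' builder), draws correlated subject effects, and samples recall counts
#' Binomial(40, inverse-logit(eta)). Emits 4 rows per subject (2 conditions x
#' 2 days) with sleep covariates attached.
#'
#' @param subjects table from \code{\link{gen_subjects}}.
#' @param truth a \code{truth_params}.
#' @param seed integer seed.
#' @param spec model whose design defines the linear predictor; defaults to
#'   the condition/day/session recovery model.
#' @return study table (one row per subject x condition x day).
#' @export
gen_recall <- function(subjects, truth = truth_params(), seed = 1,
                       spec = recovery_model_spec()) {
  set.seed(as.integer(seed) + 1L)
  tab <- design_rows(subjects)
  tab <- merge(tab, subjects, by = "subject_id", sort = FALSE)
  tab <- tab[order(tab$subject_id, tab$session, tab$day), ]
  rownames(tab) <- NULL
  # session-level sleep: the night before each learning session
  key <- paste(tab$subject_id, tab$session)
  usleep <- stats::setNames(
    tab$sleep_typical[!duplicated(key)] +
      stats::rnorm(sum(!duplicated(key)), 0, truth$sleep_night_sd),
    unique(key))
  tab$sleep_h <- round(usleep[key], 1)
  sm <- tapply(tab$sleep_h, tab$subject_id, mean)
  tab$sleep_mean <- as.numeric(sm[tab$subject_id])
  tab$sleep_dev <- tab$sleep_h - tab$sleep_mean
  tab$trials <- 40L
  tab$recalled <- 0L                     # placeholder for design construction
  design <- build_design(spec, tab)
  eta <- drop(design$X %*% truth_beta(truth, design))
  # monotonic languages effect
  if (length(spec$monotonic)) {
    D <- max(as.integer(tab$n_languages))
    zeta <- truth$languages_zeta
    if (is.null(zeta)) zeta <- rep(1 / D, D)
    stopifnot(length(zeta) == D)
    eta <- eta + monotonic_encoding(tab$n_languages, zeta, truth$languages_beta)
  }
  # correlated subject effects (intercept + any condition/day slopes in spec)
  gb <- NULL
  for (b in design$blocks) if (b$type == "group") gb <- b
  if (!is.null(gb)) {
    sds <- c(truth$sd_intercept, truth$sd_cond, truth$sd_day)[seq_len(gb$K)]
    R <- truth$re_corr
    if (is.null(R)) R <- diag(gb$K)
    stopifnot(nrow(R) == gb$K, ncol(R) == gb$K)
    L <- chol(R)
    bmat <- (matrix(stats::rnorm(gb$J * gb$K), gb$J, gb$K) %*% L) *
      rep(sds, each = gb$J)
    eta <- eta + rowSums(gb$Tm * bmat[gb$gidx, , drop = FALSE])
    attr(tab, "subject_effects") <- bmat
  }
  tab$recalled <- stats::rbinom(nrow(tab), tab$trials, stats::plogis(eta))
  attr(tab, "eta") <- eta
  tab
}

#' Generate pedal-crossing timestamps for every subject and session
#'
#' Revolution durations are lognormal with subject- and condition-specific
#' location and dispersion: the isochronous condition gets lower dispersion
#' and a larger positive speed bias over the 1 Hz target, the self-initiated
#' condition a smaller bias. Optionally synthesizes 100 Hz photocell voltage
#' traces that invert \code{\link{detect_crossings}}.
#'
#' @param subjects subject table with \code{condition_order}.
#' @param truth a \code{truth_params}.
#' @param seed integer seed.
#' @param n_revolutions revolutions per session (default from truth).
#' @param traces also return synthesized voltage traces.
#' @return data.frame of timestamps (subject_id, session, condition, time_s);
#'   with \code{traces}, a list with elements \code{timestamps} and
#'   \code{traces}.
#' @export
gen_pedaling <- function(subjects, truth = truth_params(), seed = 1,
                         n_revolutions = truth$n_revolutions, traces = FALSE) {
  set.seed(as.integer(seed) + 2L)
  if (any(unlist(truth$sdlog) < 0) || truth$target_speed_hz <= 0)
    stop("nonpositive duration parameters")
  rows <- design_rows(subjects)
  rows <- unique(rows[c("subject_id", "session", "condition")])
  subj_bias <- stats::setNames(
    stats::rnorm(nrow(subjects), 0, truth$speed_bias_subject_sd),
    subjects$subject_id)
  out <- vector("list", nrow(rows))
  trc <- if (traces) vector("list", nrow(rows)) else NULL
  for (i in seq_len(nrow(rows))) {
    cond <- rows$condition[i]
    sdl <- truth$sdlog[[cond]]
    speed <- truth$target_speed_hz *
      (1 + truth$speed_bias[[cond]] + subj_bias[[rows$subject_id[i]]])
    mu <- -log(speed) - sdl^2 / 2     # lognormal mean duration = 1/speed
    d <- stats::rlnorm(n_revolutions, mu, sdl)
    times <- cumsum(c(1, d))          # first crossing at 1 s
    out[[i]] <- data.frame(subject_id = rows$subject_id[i],
                           session = rows$session[i], condition = cond,
                           time_s = times)
    if (traces)
      trc[[i]] <- c(rows[i, , drop = FALSE],
                    synthesize_trace(times, sample_rate_hz = 100))
  }
  ts <- do.call(rbind, out)
  rownames(ts) <- NULL
  if (traces) list(timestamps = ts, traces = trc) else ts
}

#' Simulate responses to the missing-fundamental test battery
#'
#' A latent-tendency observer: each subject answers spectrally with
#' probability inverse-logit(theta + w * difficulty(pair)), where theta is
#' the subject's latent spectral tendency (the logit of the pitch index
#' rescaled to [0, 1]) and difficulty is the standardized mean harmonic
#' order n_min of the pair (sounds with higher sounding harmonics favor
#' spectral listening).
#'
#' @param subjects subject table with \code{pitch_index}.
#' @param battery a \code{test_battery}.
#' @param truth a \code{truth_params}.
#' @param seed integer seed.
#' @return data.frame (subject_id, pair_id, answer, classification).
#' @export
simulate_mf_responses <- function(subjects, battery, truth = truth_params(),
                                  seed = 1) {
  set.seed(as.integer(seed) + 3L)
  man <- battery_manifest(battery)
  nmin_mean <- (man$n_min_first + man$n_min_second) / 2
  difficulty <- as.numeric(scale(nmin_mean))
  theta <- stats::qlogis(pmin(pmax((subjects$pitch_index + 1) / 2, 1e-4),
                              1 - 1e-4))
  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    p_sp <- stats::plogis(theta[i] + truth$mf_difficulty_weight * difficulty)
    spectral <- stats::runif(nrow(man)) < p_sp
    # translate the percept into the key press that classifies as such
    answer <- ifelse(spectral,
                     ifelse(man$fsp_direction > 0, "second_higher", "first_higher"),
                     ifelse(man$f0_direction > 0, "second_higher", "first_higher"))
    out[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                           pair_id = man$pair_id, answer = answer,
                           classification = ifelse(spectral, "spectral",
                                                   "fundamental"))
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic study bundle
#'
#' Study table (recall + covariates + motor metrics derived from the
#' generated pedal timestamps via the crossing-time metrics), pedal
#' timestamps, and the generating truth. Regenerable byte-identically from
#' (truth, seed).
#'
#' @param truth a \code{truth_params}.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param spec generating/fitting model spec (see \code{\link{gen_recall}}).
#' @param n_revolutions pedal revolutions per session.
#' @param mf_battery optional \code{test_battery}; when given, MF response
#'   logs are simulated and scored, and the scored pitch index is attached as
#'   \code{delta_p_measured}.
#' @return an object of class \code{study_bundle}.
#' @export
gen_study <- function(truth = truth_params(), n_subjects = 47, seed = 1,
                      spec = recovery_model_spec(),
                      n_revolutions = truth$n_revolutions, mf_battery = NULL) {
  subjects <- gen_subjects(n_subjects, truth, seed)
  study <- gen_recall(subjects, truth, seed, spec)
  pedal <- gen_pedaling(subjects, truth, seed, n_revolutions)
  metrics <- motor_metrics_table(pedal, soa_s = truth$soa_s)
  study <- merge(study, metrics[c("subject_id", "condition", "mean_speed_hz",
                                  "cv", "ibd_s", "n_revolutions")],
                 by = c("subject_id", "condition"), sort = FALSE)
  study <- study[order(study$subject_id, study$session, study$day), ]
  rownames(study) <- NULL
  mf <- NULL
  if (!is.null(mf_battery)) {
    mf <- simulate_mf_responses(subjects, mf_battery, truth, seed)
    dp <- vapply(split(mf$classification, mf$subject_id), function(cl)
      pitch_index(response_tally(cl))$delta_p, numeric(1))
    study$delta_p_measured <- as.numeric(dp[study$subject_id])
  }
  structure(list(study_table = study, pedal_timestamps = pedal,
                 mf_responses = mf, subjects = subjects, truth = truth,
                 seed = as.integer(seed)),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d subjects, %d study rows, %d pedal events, seed %d\n",
              nrow(x$subjects), nrow(x$study_table),
              nrow(x$pedal_timestamps), x$seed))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates synthetic studies from known truth, fits the model,
#' and tabulates estimation error, 90% HDI coverage and the probability of
#' direction of the day and condition link-scale differences. Failed fits
#' are recorded, not dropped.
#'
#' @param truth a \code{truth_params}.
#' @param n_subjects subjects per replicate.
#' @param reps number of replicates (>= 2).
#' @param chains,iterations MCMC configuration per fit.
#' @param seed integer master seed.
#' @param spec generating/fitting model (see \code{\link{gen_recall}}).
#' @param leapfrog_range HMC trajectory lengths; the default short range is
#'   adequate for this low-correlation model and keeps replicates fast.
#' @return data.frame with one row per replicate x monitored parameter:
#'   truth, posterior median, 90% HDI, coverage flag, pd, sign agreement.
#' @export
recovery_experiment <- function(truth = truth_params(), n_subjects = 47,
                                reps = 20, chains = 4, iterations = 600,
                                seed = 1, spec = recovery_model_spec(),
                                leapfrog_range = c(5L, 15L)) {
  stopifnot(reps >= 2)
  C2 <- orthonormal_contrasts(2)
  dC <- C2[2, 1] - C2[1, 1]
  monitored <- list(
    day2_minus_day1 = function(fit) fit$draws[, "b_day"] * dC,
    iso_minus_self = function(fit) fit$draws[, "b_condition"] * (-dC),
    session2_minus_session1 = function(fit) fit$draws[, "b_session"] * dC,
    sd_intercept = function(fit)
      exp(fit$draws[, "log_sd_subject_id_1"]))
  rows <- list()
  for (r in seq_len(reps)) {
    rep_seed <- as.integer(seed) + 1000L * r
    res <- tryCatch({
      study <- gen_recall(gen_subjects(n_subjects, truth, rep_seed),
                          truth, rep_seed, spec)
      fit <- sample_posterior(spec, study, chains = chains,
                              iterations = iterations, seed = rep_seed,
                              leapfrog_range = leapfrog_range)
      lapply(names(monitored), function(nm) {
        dr <- monitored[[nm]](fit)
        tv <- truth[[nm]]
        h <- hdi(dr, 0.90)
        pdv <- pd(dr)
        data.frame(rep = r, parameter = nm, truth = tv,
                   estimate = stats::median(dr),
                   hdi90_lo = h[1], hdi90_hi = h[2],
                   covered = tv >= h[1] & tv <= h[2],
                   pd = pdv,
                   sign_agree = if (tv == 0) NA else
                     sign(stats::median(dr)) == sign(tv),
                   failed = FALSE)
      })
    }, error = function(e) {
      list(data.frame(rep = r, parameter = NA_character_, truth = NA_real_,
                      estimate = NA_real_, hdi90_lo = NA_real_,
                      hdi90_hi = NA_real_, covered = NA, pd = NA_real_,
                      sign_agree = NA, failed = TRUE))
    })
    rows <- c(rows, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read truth parameters as YAML
#'
#' @param truth a \code{truth_params}.
#' @param path file path.
#' @return \code{path} (write) or a \code{truth_params} (read).
#' @export
write_truth_yaml <- function(truth, path) {
  vals <- unclass(truth)
  for (nm in names(vals))   # named vectors serialize as YAML maps
    if (!is.null(names(vals[[nm]]))) vals[[nm]] <- as.list(vals[[nm]])
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("speed_bias", "sdlog"))
    vals[[nm]] <- unlist(vals[[nm]])
  do.call(truth_params, vals)
}
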