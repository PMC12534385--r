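# Study pipeline: screening and scheduling rules, the concrete model
# specifications, data preparation (transforms, decompositions, the IBD copy
# rule) and the orchestration of all fits into a results report.

#' Screen pseudoword learning scores
#'
#' Participants remembering more than 20 of 40 pseudowords are excluded
#' before the study to prevent a ceiling effect (strictly greater than 20;
#' 20 itself is kept).
#'
#' @param scores named vector of correct counts out of 40 per subject.
#' @return list with \code{kept} and \code{excluded} (character ids) and a
#'   \code{table} with per-subject reasons.
#' @export
screening_filter <- function(scores) {
  if (length(scores) == 0)
    return(list(kept = character(), excluded = character(),
                table = data.frame(subject = character(), score = numeric(),
                                   decision = character())))
  if (any(scores < 0 | scores > 40)) stop("scores must lie in [0, 40]")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  excl <- scores > 20
  list(kept = ids[!excl], excluded = ids[excl],
       table = data.frame(subject = ids, score = as.numeric(scores),
                          decision = ifelse(excl, "excluded: > 20 of 40 correct",
                                            "kept")))
}

#' Build one learning-session schedule
#'
#' 350 lead-in sine tones (650 Hz, 50 ms), then two blocks of the same 40
#' vocabulary items, the second block in a new seeded order, separated by a
#' 7-minute break; each item is followed by a two-tone repeat cue. In the
#' isochronous condition item onsets are stamped at a fixed 2 s SOA; in the
#' self-initiated condition onsets are pedal-triggered (no stamps).
#'
#' @param condition \code{"isochronous"} or \code{"self_initiated"}.
#' @param item_ids exactly 40 vocabulary item labels.
#' @param seed integer seed for the block orders.
#' @param soa_s stimulus-onset asynchrony in the isochronous condition (s).
#' @return an object of class \code{session_schedule}.
#' @export
build_session_schedule <- function(condition = c("isochronous", "self_initiated"),
                                   item_ids, seed = 1, soa_s = 2) {
  condition <- match.arg(condition)
  if (length(item_ids) != 40 || anyDuplicated(item_ids))
    stop("exactly 40 unique item ids are required")
  set.seed(as.integer(seed))
  block1 <- sample(item_ids)
  block2 <- sample(item_ids)
  if (length(item_ids) > 1 && identical(block2, block1))
    block2 <- sample(item_ids)     # re-draw the (vanishingly rare) identity
  onsets <- if (condition == "isochronous")
    (seq_along(item_ids) - 1) * soa_s else NULL
  structure(
    list(condition = condition,
         lead_in = list(n_tones = 350, freq_hz = 650, tone_duration_s = 0.05),
         blocks = list(block1 = block1, block2 = block2),
         block_onsets_s = onsets,
         repeat_cue_tones = 2L,
         break_s = 420,
         soa_s = if (condition == "isochronous") soa_s else NA_real_),
    class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %s: %d lead-in tones, 2 x %d items, %.0f s break%s\n",
              x$condition, x$lead_in$n_tones, length(x$blocks$block1),
              x$break_s,
              if (!is.na(x$soa_s)) sprintf(", SOA %.1f s", x$soa_s) else ""))
  invisible(x)
}

#' Build the two-session study schedule for one participant
#'
#' Allocates 80 unique vocabulary items into two disjoint 40-item session
#' lists (seeded), one session per stimulation condition in the given order.
#'
#' @param condition_order \code{"iso_first"} or \code{"self_first"}.
#' @param seed integer seed.
#' @param item_ids 80 unique item labels.
#' @return list of two \code{session_schedule}s plus the item allocation.
#' @export
build_study_schedules <- function(condition_order = c("iso_first", "self_first"),
                                  seed = 1,
                                  item_ids = sprintf("item%02d", 1:80)) {
  condition_order <- match.arg(condition_order)
  if (length(item_ids) != 80 || anyDuplicated(item_ids))
    stop("exactly 80 unique item ids are required")
  set.seed(as.integer(seed))
  pick <- sample(item_ids, 40)
  items1 <- pick
  items2 <- setdiff(item_ids, pick)
  conds <- if (condition_order == "iso_first")
    c("isochronous", "self_initiated") else c("self_initiated", "isochronous")
  list(session1 = build_session_schedule(conds[1], items1, seed = seed + 1L),
       session2 = build_session_schedule(conds[2], items2, seed = seed + 2L),
       items = list(session1 = items1, session2 = items2))
}

#' Validate a study table
#'
#' Checks the 2x2 within-subject structure (4 rows per subject: 2 conditions
#' x 2 testing days), count bounds and the pitch-index range; aborts with a
#' row-level message on the first violation.
#'
#' @param study study table.
#' @return the table, invisibly, on success.
#' @export
validate_study_table <- function(study) {
  req <- c("subject_id", "session", "condition", "day", "recalled", "trials",
           "pitch_index")
  miss <- setdiff(req, names(study))
  if (length(miss)) stop("study table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(study$recalled < 0 | study$recalled > study$trials)
  if (length(bad)) stop("row ", bad[1], ": recalled outside [0, trials]")
  bad <- which(study$pitch_index < -1 | study$pitch_index > 1)
  if (length(bad)) stop("row ", bad[1], ": pitch_index outside [-1, 1]")
  for (sid in unique(study$subject_id)) {
    sub <- study[study$subject_id == sid, ]
    if (nrow(sub) != 4 ||
        nrow(unique(sub[c("condition", "day")])) != 4)
      stop("subject ", sid, ": expected 4 rows (2 conditions x 2 days)")
  }
  invisible(study)
}

#' Prepare a study table for modeling
#'
#' Adds the derived model covariates: subject-mean and subject-centered
#' sleep, log CV with its between/within decomposition, and log IBD with the
#' isochronous estimates copied onto the same subject's self-initiated rows
#' (IBD is treated as a subject trait, measurable only under isochronous
#' stimulation).
#'
#' @param study validated study table.
#' @return the augmented table.
#' @export
prepare_study_table <- function(study) {
  if (!is.null(study$sleep_h) && is.null(study$sleep_mean)) {
    sm <- tapply(study$sleep_h, study$subject_id, mean)
    study$sleep_mean <- as.numeric(sm[study$subject_id])
    study$sleep_dev <- study$sleep_h - study$sleep_mean
  }
  if (!is.null(study$cv)) {
    if (any(study$cv <= 0)) stop("CV must be positive for the log transform")
    study$log_cv <- log(study$cv)
    bm <- tapply(study$log_cv, study$subject_id, mean)
    study$log_cv_between <- as.numeric(bm[study$subject_id])
    study$log_cv_within <- study$log_cv - study$log_cv_between
  }
  if (!is.null(study$ibd_s)) study <- copy_ibd(study)
  study
}

#' Copy isochronous IBD onto self-initiated rows
#'
#' @param study study table with \code{ibd_s}.
#' @return table whose \code{ibd_s} (and \code{log_ibd}) are condition-
#'   invariant within subject.
#' @export
copy_ibd <- function(study) {
  iso <- study[study$condition == "isochronous", ]
  per_subj <- tapply(iso$ibd_s, iso$subject_id, function(v) mean(unique(v)))
  missing <- setdiff(unique(study$subject_id), names(per_subj))
  if (length(missing))
    stop("no isochronous IBD available for subject ", missing[1])
  study$ibd_s <- as.numeric(per_subj[study$subject_id])
  if (any(study$ibd_s <= 0)) stop("IBD must be positive for the log transform")
  study$log_ibd <- log(study$ibd_s)
  study
}

#' Memory model specification
#'
#' Binomial-logit recall model: subject random intercept plus random slopes
#' for condition and day (correlated); fixed condition x day interaction and
#' session (order) effect; pitch-index effect as a penalized thin-plate
#' smooth with one difference smooth per condition x day cell (smooth
#' variant) or as linear main effect plus 2- and 3-way interactions (linear
#' variant); monotonic number of foreign languages; smooth (or linear) years
#' of musical training; smooth (or linear) subject-mean sleep plus a linear
#' subject-centered sleep effect interacting with day.
#'
#' @param variant \code{"smooth"} or \code{"linear"}.
#' @param k_pitch,k_controls smooth basis dimensions.
#' @param priors a \code{\link{prior_set}}.
#' @return a \code{model_spec}.
#' @export
memory_model_spec <- function(variant = c("smooth", "linear"), k_pitch = 6,
                              k_controls = 5, priors = prior_set()) {
  variant <- match.arg(variant)
  base_fixed <- c("condition", "day", "condition:day", "session",
                  "sleep_dev", "sleep_dev:day")
  if (variant == "smooth") {
    model_spec("binomial", "recalled", trials = "trials",
               fixed = base_fixed,
               smooths = list(
                 smooth_term("pitch_index", k = k_pitch,
                             by = c("condition", "day")),
                 smooth_term("music_years", k = k_controls),
                 smooth_term("sleep_mean", k = k_controls)),
               monotonic = "n_languages",
               random = random_term("subject_id", c("1", "condition", "day")),
               priors = priors)
  } else {
    model_spec("binomial", "recalled", trials = "trials",
               fixed = c(base_fixed, "pitch_index", "pitch_index:condition",
                         "pitch_index:day", "pitch_index:condition:day",
                         "music_years", "sleep_mean"),
               monotonic = "n_languages",
               random = random_term("subject_id", c("1", "condition", "day")),
               priors = priors)
  }
}

#' Motor-covariate memory model specification
#'
#' Binomial recall model testing one motor metric as predictor: smooth
#' effects of the (log-transformed) metric with difference smooths per
#' condition x day cell, the usual controls (session, linear sleep effects,
#' monotonic languages, smooth musical training) and subject random
#' intercept/slopes. log CV enters as between-subject plus within-subject
#' components; log IBD is copied from the isochronous rows onto the same
#' subject's self-initiated rows before modeling (use
#' \code{\link{prepare_study_table}}).
#'
#' @param metric \code{"speed"}, \code{"log_cv"} or \code{"log_ibd"}.
#' @param k smooth basis dimension for the metric smooths.
#' @param priors a \code{\link{prior_set}}.
#' @return a \code{model_spec}.
#' @export
motor_covariate_model_spec <- function(metric = c("speed", "log_cv", "log_ibd"),
                                       k = 5, priors = prior_set()) {
  metric <- match.arg(metric)
  controls_fixed <- c("condition", "day", "condition:day", "session",
                      "sleep_mean", "sleep_dev", "sleep_dev:day")
  metric_smooths <- switch(metric,
    speed = list(smooth_term("mean_speed_hz", k = k,
                             by = c("condition", "day"))),
    log_cv = list(smooth_term("log_cv_between", k = k,
                              by = c("condition", "day")),
                  smooth_term("log_cv_within", k = k,
                              by = c("condition", "day"))),
    log_ibd = list(smooth_term("log_ibd", k = k,
                               by = c("condition", "day"))))
  model_spec("binomial", "recalled", trials = "trials",
             fixed = controls_fixed,
             smooths = c(metric_smooths,
                         list(smooth_term("music_years", k = k))),
             monotonic = "n_languages",
             random = random_term("subject_id", c("1", "condition", "day")),
             priors = priors)
}

#' Motor-performance outcome model specifications
#'
#' Three models of the motor metrics themselves: average cycling speed with
#' a Gaussian likelihood (identity link) informed about the known
#' per-observation standard error of the mean speed, with a subject random
#' intercept; CV with a Gamma likelihood (log link) and subject random
#' intercept (both observed twice per subject, once per condition); IBD with
#' a Gamma likelihood on the isochronous rows only (one row per subject, no
#' random intercept). Predictors: stimulation condition (speed/CV), pitch
#' index, sex and session.
#'
#' @param priors a \code{\link{prior_set}}.
#' @return named list of three \code{model_spec}s (\code{speed}, \code{cv},
#'   \code{ibd}).
#' @export
motor_outcome_model_specs <- function(priors = prior_set()) {
  list(
    speed = model_spec("gaussian", "mean_speed_hz", se = "speed_se",
                       fixed = c("condition", "pitch_index", "sex", "session"),
                       random = random_term("subject_id", "1"),
                       priors = priors),
    cv = model_spec("gamma", "cv",
                    fixed = c("condition", "pitch_index", "sex", "session"),
                    random = random_term("subject_id", "1"),
                    priors = priors),
    ibd = model_spec("gamma", "ibd_s",
                     fixed = c("pitch_index", "sex", "session"),
                     priors = priors))
}

#' Per-condition motor outcome table
#'
#' One row per subject x condition with the motor metrics and the known
#' standard error of the mean speed (sd of instantaneous speed over the
#' square root of the revolution count).
#'
#' @param study prepared study table with motor columns.
#' @return data.frame for the outcome models.
#' @export
motor_outcome_data <- function(study) {
  need <- c("subject_id", "session", "condition", "pitch_index", "sex",
            "mean_speed_hz", "cv", "n_revolutions")
  miss <- setdiff(need, names(study))
  if (length(miss)) stop("missing motor columns: ", paste(miss, collapse = ", "))
  out <- unique(study[c("subject_id", "session", "condition", "pitch_index",
                        "sex", "mean_speed_hz", "cv", "ibd_s",
                        "n_revolutions")])
  if (is.null(out$ibd_s)) stop("missing IBD column")
  out$speed_se <- out$cv * out$mean_speed_hz / sqrt(out$n_revolutions)
  rownames(out) <- NULL
  out
}

fixed_effect_summaries <- function(fit) {
  nm <- grep("^b_", colnames(fit$draws), value = TRUE)
  out <- do.call(rbind, lapply(nm, function(p)
    summary_stats(fit$draws[, p], label = p)))
  out$pd_label <- "pd_link"
  out
}

#' Run the full study analysis
#'
#' Validates and prepares the study table, fits the requested models (memory
#' smooth and linear variants, the three motor-covariate models and the
#' three motor-outcome models), and assembles a report: per fixed effect the
#' median, 66/90/95% HDIs, pd and evidence ratio; condition and day
#' response-scale contrasts and marginal means; pitch-index half-split
#' contrast and finite-difference slopes; Bayesian R-squared; ICC; full
#' convergence diagnostics. Fully seeded: the same configuration and seed
#' reproduce an identical report.
#'
#' @param study study table (see \code{\link{validate_study_table}}).
#' @param models character subset of \code{c("memory", "memory_linear",
#'   "cov_speed", "cov_log_cv", "cov_log_ibd", "out_speed", "out_cv",
#'   "out_ibd")}.
#' @param chains,iterations MCMC configuration.
#' @param seed integer seed.
#' @param n_pitch_grid grid resolution for pitch-index summaries.
#' @return an object of class \code{report_bundle}.
#' @export
run_study_analysis <- function(study,
                               models = c("memory", "memory_linear"),
                               chains = 4, iterations = 3000, seed = 1,
                               n_pitch_grid = 25) {
  validate_study_table(study)
  study <- prepare_study_table(study)
  all_models <- c("memory", "memory_linear", "cov_speed", "cov_log_cv",
                  "cov_log_ibd", "out_speed", "out_cv", "out_ibd")
  models <- match.arg(models, all_models, several.ok = TRUE)
  if (!is.null(study$ibd_s)) {
    # copy rule: IBD must be condition-invariant within subject before fitting
    chk <- tapply(study$ibd_s, study$subject_id,
                  function(v) length(unique(v)))
    if (any(chk != 1)) stop("IBD not condition-invariant after copying")
  }
  fits <- list()
  report <- list()
  next_seed <- as.integer(seed)
  for (m in models) {
    next_seed <- next_seed + 17L
    spec <- switch(m,
      memory = memory_model_spec("smooth"),
      memory_linear = memory_model_spec("linear"),
      cov_speed = motor_covariate_model_spec("speed"),
      cov_log_cv = motor_covariate_model_spec("log_cv"),
      cov_log_ibd = motor_covariate_model_spec("log_ibd"),
      out_speed = motor_outcome_model_specs()$speed,
      out_cv = motor_outcome_model_specs()$cv,
      out_ibd = motor_outcome_model_specs()$ibd)
    dat <- if (startsWith(m, "out_")) {
      md <- motor_outcome_data(study)
      if (m == "out_ibd") md[md$condition == "isochronous", ] else md
    } else study
    fit <- sample_posterior(spec, dat, chains = chains,
                            iterations = iterations, seed = next_seed)
    fits[[m]] <- fit
    entry <- list(
      fixed = fixed_effect_summaries(fit),
      diagnostics = fit$diagnostics,
      bayes_r2 = bayes_r2(fit))
    if (!is.null(spec$random)) entry$icc <- icc(fit, seed = next_seed)
    if (m %in% c("memory", "memory_linear")) {
      g_cond <- reference_grid(fit, condition = c("isochronous",
                                                  "self_initiated"))
      pc <- marginal_predictions(fit, g_cond)
      entry$condition_contrast <- contrast_predictions(
        pc[, 1, drop = FALSE], pc[, 2, drop = FALSE],
        label = "isochronous - self_initiated")
      g_day <- reference_grid(fit, day = c("1", "2"))
      pdm <- marginal_predictions(fit, g_day)
      entry$day_contrast <- contrast_predictions(
        pdm[, 2, drop = FALSE], pdm[, 1, drop = FALSE], label = "day2 - day1")
      entry$marginal_means <- data.frame(
        level = c("isochronous", "self_initiated", "day1", "day2"),
        median = c(apply(pc, 2, stats::median), apply(pdm, 2, stats::median)))
      pr <- range(study$pitch_index)
      g_pitch <- reference_grid(fit, pitch_index = seq(pr[1], pr[2],
                                                       length.out = n_pitch_grid))
      entry$pitch_half_split <- half_split_contrast(fit, "pitch_index",
                                                    grid = g_pitch)
      fd <- finite_diff_slope(fit, "pitch_index", g_pitch)
      entry$pitch_slopes <- data.frame(
        pitch_index = fd$x,
        median_slope = apply(fd$slopes, 2, stats::median),
        pd = apply(fd$slopes, 2, pd),
        one_sided = fd$one_sided)
    }
    report[[m]] <- entry
  }
  structure(list(report = report, fits = fits, models = models,
                 seed = as.integer(seed), chains = chains,
                 iterations = iterations,
                 manifest = report_manifest(study, models, chains,
                                            iterations, seed)),
            class = "report_bundle")
}

# Stable content hash (FNV-1a over the serialized text) for determinism
# manifests; avoids external digest dependencies.
content_hash <- function(x) {
  txt <- paste(utils::capture.output(print(x, digits = 15)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

report_manifest <- function(study, models, chains, iterations, seed) {
  list(models = models, chains = chains, iterations = iterations, seed = seed,
       n_rows = nrow(study), n_subjects = length(unique(study$subject_id)),
       study_hash = content_hash(study))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> models: %s | %d chains x %d iterations, seed %d\n",
              paste(x$models, collapse = ", "), x$chains, x$iterations,
              x$seed))
  for (m in x$models) {
    r2 <- x$report[[m]]$bayes_r2
    cat(sprintf("  %s: Bayesian R2 %.2f [%.2f, %.2f], max Rhat %.3f\n", m,
                r2$median, r2$hdi95_lo, r2$hdi95_hi,
                max(x$report[[m]]$diagnostics$rhat, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write a report bundle to CSV files
#'
#' One CSV per model with the fixed-effect summaries, one with diagnostics,
#' plus a run manifest (models, seeds, sizes, study hash) as YAML.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report_csv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in bundle$models) {
    utils::write.csv(bundle$report[[m]]$fixed,
                     file.path(dir, paste0(m, "_fixed.csv")), row.names = FALSE)
    utils::write.csv(bundle$report[[m]]$diagnostics,
                     file.path(dir, paste0(m, "_diagnostics.csv")),
                     row.names = FALSE)
  }
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
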