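# Synthetic EMA cohort generator. Emulates the structure of a two-group
# (patients with opioid use disorder vs. healthy controls) 28-day EMA study:
# day-varying preference parameters with controllable between/within variance
# ratios, an AR(1) mood process whose within-person deviations shift
# gain-domain risk tolerance, repetition drift, a stable group offset in
# log discount rate, and group-dependent prompt compliance.

REPORTED_PARAMS <- c("risk_tol_gain", "risk_tol_loss", "amb_tol_gain",
                     "amb_tol_loss", "log_kappa")

# Bounds of the reported-scale parameters implied by the native fit bounds.
reported_bounds <- function(parameter) {
  switch(parameter,
    risk_tol_gain = c(-1, 9),     # alpha in [0, 10]
    risk_tol_loss = c(-9, 1),
    amb_tol_gain = c(-5, 5),      # beta in [-5, 5]
    amb_tol_loss = c(-5, 5),
    log_kappa = c(log(1e-4), 0),  # kappa in [0.0001, 1]
    stop("unknown parameter: ", parameter)
  )
}

# between-person SD that yields a target ICC at a given within-person SD
sd_between_for_icc <- function(icc, within_sd) {
  within_sd * sqrt(icc / (1 - icc))
}

#' Configuration of a synthetic EMA cohort
#'
#' Returns the default study conditions: 23 patients and 21 controls followed
#' for 28 days, up to three task prompts per day completed with
#' group-dependent probability (54.14% patients, 80.84% controls), day-level
#' preference parameters on the reported scale with between/within SDs chosen
#' so the intraclass correlations are 0.43 (risk tolerance in gains), 0.40
#' (losses), 0.53 (ambiguity tolerance, both domains) and 0.67 (log discount
#' rate), a +2.17 patient offset in mean log discount rate (steeper
#' discounting), within-person mood coupling of 0.02 reported-scale units of
#' gain risk tolerance per point of the 0-100 composite mood scale, and
#' repetition drifts of -0.08 (risk tolerance in losses), -0.06 (ambiguity
#' tolerance in losses) and -0.06 (log discount rate) per completed
#' administration.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `daypref_config`.
#' @examples
#' cfg <- cohort_config(n_days = 7, seed = 42)
#' @export
cohort_config <- function(...) {
  # Dispersion magnitudes keep the population well inside the parameter
  # support (alpha >= 0 puts a bound at risk_tol_gain = -1, so that scale
  # is tighter); ICC targets depend only on the between/within ratio. For
  # the mood-coupled gain risk tolerance the day-to-day mood swing
  # contributes ~0.043 variance (0.02/point x ~10.4-point swings), which is
  # part of the within-person budget, so its noise SD is reduced to keep
  # the total within SD at 0.35.
  within_sd <- c(risk_tol_gain = 0.28, risk_tol_loss = 0.60,
                 amb_tol_gain = 0.80, amb_tol_loss = 0.80,
                 log_kappa = 0.80)
  total_within <- c(risk_tol_gain = 0.35, risk_tol_loss = 0.60,
                    amb_tol_gain = 0.80, amb_tol_loss = 0.80,
                    log_kappa = 0.80)
  target_icc <- c(risk_tol_gain = 0.43, risk_tol_loss = 0.40,
                  amb_tol_gain = 0.53, amb_tol_loss = 0.53,
                  log_kappa = 0.67)
  config <- list(
    n_patients = 23L,
    n_controls = 21L,
    n_days = 28L,
    compliance = c(patient = 0.5414, control = 0.8084),
    mood_compliance = c(patient = 0.5414, control = 0.8084),
    n_mood_prompts = 3L,
    param_means = c(risk_tol_gain = -0.25, risk_tol_loss = -0.2,
                    amb_tol_gain = -0.4, amb_tol_loss = -0.2,
                    log_kappa = -4.5),
    within_sd = within_sd,
    between_sd = mapply(sd_between_for_icc, target_icc, total_within),
    group_offset_log_kappa = 2.17,
    mood_within_effect = 0.02,
    mood_within_effect_patient_extra = 0,
    mood_mean = c(patient = 55, control = 65),
    mood_between_sd = 10,
    mood_ar = 0.5,
    mood_innovation_sd = 9,
    mood_prompt_sd = 8,
    repetition_drift = c(risk_tol_gain = 0, risk_tol_loss = -0.08,
                         amb_tol_gain = 0, amb_tol_loss = -0.06,
                         log_kappa = -0.06),
    gamma_risk = 3,
    gamma_itc = 1.5,
    itc_convention = "immediate0",
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  config[names(overrides)] <- overrides
  if (!"between_sd" %in% names(overrides)) {
    # The diagnosis offset is itself between-person variance: the pooled
    # ICC target for log kappa counts the group gap, so the within-group
    # between-person SD is the remainder of that budget.
    p_pat <- config$n_patients / (config$n_patients + config$n_controls)
    offset_var <- config$group_offset_log_kappa^2 * p_pat * (1 - p_pat)
    total_b2 <- config$between_sd[["log_kappa"]]^2
    config$between_sd[["log_kappa"]] <-
      sqrt(max(total_b2 - offset_var, 0.1^2))
  }
  validate_config(config)
  structure(config, class = "daypref_config")
}

validate_config <- function(config) {
  rates <- c(config$compliance, config$mood_compliance)
  if (any(rates < 0 | rates > 1)) stop("compliance rates must lie in [0,1]")
  sds <- c(config$within_sd, config$between_sd, config$mood_between_sd,
           config$mood_innovation_sd, config$mood_prompt_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (config$mood_ar < 0 || config$mood_ar >= 1) {
    stop("mood_ar must lie in [0, 1)")
  }
  if (config$n_days < 1 || config$n_patients + config$n_controls < 2) {
    stop("cohort must have >= 2 subjects and >= 1 day")
  }
  invisible(config)
}

# truncated-normal draw by resampling (falls back to clamping after 100
# rounds; bounds are several SDs out in all default settings)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  x <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean[bad], sd)
  }
  clamp(x, lo, hi)
}

#' Simulate a complete synthetic EMA study
#'
#' Generates, per subject and day: a composite mood trajectory (AR(1) around
#' a person mean, observed through noisy anticorrelated positive/negative
#' ratings), reported-scale preference parameters (person mean + repetition
#' drift + mood coupling + day noise, truncated to the fit bounds), simulated
#' trial-by-trial choices on the exact task trial sets via the choice models,
#' and group-dependent compliance thinning at the prompt level. Fully
#' deterministic given the config's seed.
#'
#' @param config A [cohort_config()].
#' @param choices If `FALSE`, skip trial-level choice simulation and return
#'   only ratings and the ground-truth table (much faster; used for
#'   truth-level calibration studies).
#' @return A list of class `daypref_cohort` with data.frames `choices`
#'   (trial-level records; schema of [read_choices()]), `ratings` (one row
#'   per completed mood prompt) and `truth` (per subject-day latent
#'   parameters and completion flags).
#' @export
simulate_cohort <- function(config = cohort_config(), choices = TRUE) {
  validate_config(config)
  n_subj <- config$n_patients + config$n_controls
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subj)),
    group = rep(c("patient", "control"),
                c(config$n_patients, config$n_controls))
  )
  with_seed(derive_seed(config$seed, "cohort"), {
    truth <- vector("list", n_subj)
    ratings <- vector("list", n_subj)
    for (i in seq_len(n_subj)) {
      sub <- simulate_subject(subjects$subject_id[i], subjects$group[i],
                              config)
      truth[[i]] <- sub$truth
      ratings[[i]] <- sub$ratings
    }
    truth <- do.call(rbind, truth)
    ratings <- do.call(rbind, ratings)
    choice_tab <- if (choices) simulate_choices(truth, config) else NULL
  })
  structure(list(choices = choice_tab, ratings = ratings, truth = truth,
                 config = config),
            class = "daypref_cohort")
}

simulate_subject <- function(subject_id, group, config) {
  n_days <- config$n_days
  bounds <- lapply(REPORTED_PARAMS, reported_bounds)
  names(bounds) <- REPORTED_PARAMS

  # person means on the reported scale
  means <- config$param_means
  if (group == "patient") {
    means[["log_kappa"]] <- means[["log_kappa"]] + config$group_offset_log_kappa
  }
  person <- vapply(REPORTED_PARAMS, function(p) {
    rnorm_trunc(1, means[[p]], config$between_sd[[p]],
                bounds[[p]][1], bounds[[p]][2])
  }, numeric(1))

  # latent composite mood: AR(1) around the person mean
  mood_mu <- rnorm_trunc(1, config$mood_mean[[group]],
                         config$mood_between_sd, 15, 85)
  stat_sd <- config$mood_innovation_sd / sqrt(1 - config$mood_ar^2)
  mood <- numeric(n_days)
  mood[1] <- rnorm(1, mood_mu, stat_sd)
  for (d in seq_len(n_days)[-1]) {
    mood[d] <- mood_mu + config$mood_ar * (mood[d - 1] - mood_mu) +
      rnorm(1, 0, config$mood_innovation_sd)
  }
  mood <- clamp(mood, 10, 90)

  # prompt-level compliance
  tasks <- c("risk-gain", "risk-loss", "itc")
  completed <- matrix(rbinom(n_days * 3, 1, config$compliance[[group]]) == 1,
                      nrow = n_days, dimnames = list(NULL, tasks))
  reps <- apply(completed, 2, cumsum)   # repetition count incl. current day

  mood_effect <- config$mood_within_effect +
    if (group == "patient") config$mood_within_effect_patient_extra else 0
  mood_dev <- mood - mood_mu

  # Day noise is truncated symmetrically around the systematic value
  # (person mean + drift + mood coupling): the admissible noise range is
  # +/- the distance to the nearer fit bound, so E[day value] equals the
  # systematic value exactly and configured couplings survive undistorted.
  # Near a bound the day noise variance shrinks; a systematic value outside
  # the bounds (possible under extreme drift) is clamped with no noise.
  day_par <- sapply(REPORTED_PARAMS, function(p) {
    task <- switch(p, risk_tol_gain = , amb_tol_gain = "risk-gain",
                   risk_tol_loss = , amb_tol_loss = "risk-loss", "itc")
    base <- person[[p]] +
      config$repetition_drift[[p]] * (reps[, task] - 1) +
      (if (p == "risk_tol_gain") mood_effect * mood_dev else 0)
    margin <- pmin(base - bounds[[p]][1], bounds[[p]][2] - base)
    base <- clamp(base, bounds[[p]][1], bounds[[p]][2])
    if (config$within_sd[[p]] == 0) {
      base
    } else {
      base + ifelse(margin > 0,
                    rnorm_trunc(n_days, 0, config$within_sd[[p]],
                                -pmax(margin, 0), pmax(margin, 0)),
                    0)
    }
  })

  truth <- data.frame(subject_id = subject_id, group = group,
                      day = seq_len(n_days), day_par,
                      mood_latent = mood,
                      completed_risk_gain = completed[, "risk-gain"],
                      completed_risk_loss = completed[, "risk-loss"],
                      completed_itc = completed[, "itc"])

  # mood prompts: positive = composite + noise, negative = (100 - composite)
  # + the same noise, so the observed composite equals the latent value and
  # the two items are strongly anticorrelated.
  n_prompts <- config$n_mood_prompts
  prompt_done <- rbinom(n_days * n_prompts, 1,
                        config$mood_compliance[[group]]) == 1
  mood_rep <- rep(mood, each = n_prompts)
  # the prompt disturbance is truncated so both items stay on the 0-100
  # scale, which keeps the day composite exactly equal to the latent mood
  room <- pmin(mood_rep, 100 - mood_rep)
  delta <- rnorm_trunc(n_days * n_prompts, 0, config$mood_prompt_sd,
                       -room, room)
  ratings <- data.frame(
    subject_id = subject_id, group = group,
    day = rep(seq_len(n_days), each = n_prompts),
    prompt_index = rep(seq_len(n_prompts), n_days),
    positive = mood_rep + delta,
    negative = 100 - mood_rep + delta
  )[prompt_done, , drop = FALSE]
  rownames(ratings) <- NULL
  list(truth = truth, ratings = ratings)
}

# Trial-level choice simulation on the exact task trial sets.
simulate_choices <- function(truth, config) {
  rows <- vector("list", nrow(truth) * 3)
  k <- 0
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    day_seed <- derive_seed(config$seed, "trials", tr$subject_id, tr$day)
    if (tr$completed_risk_gain || tr$completed_risk_loss) {
      for (cond in c("gain", "loss")) {
        done <- if (cond == "gain") tr$completed_risk_gain else
          tr$completed_risk_loss
        if (!done) next
        trials <- risk_trials(cond, seed = day_seed)
        nat <- native_params(
          risk_tol = tr[[paste0("risk_tol_", cond)]],
          amb_tol = tr[[paste0("amb_tol_", cond)]],
          condition = cond)
        pr <- risk_choice_prob(trials, nat$alpha, nat$beta, config$gamma_risk)
        trials$choice <- rbinom(nrow(trials), 1, pr)
        trials$task <- paste0("risk-", cond)
        k <- k + 1
        rows[[k]] <- cbind(subject_id = tr$subject_id, group = tr$group,
                           day = tr$day, trials)
      }
    }
    if (tr$completed_itc) {
      trials <- itc_trials(config$itc_convention, seed = day_seed)
      kappa <- exp(tr$log_kappa)
      pr <- itc_choice_prob(trials, kappa, config$gamma_itc)
      trials$choice <- rbinom(nrow(trials), 1, pr)
      trials$task <- "itc"
      k <- k + 1
      rows[[k]] <- cbind(subject_id = tr$subject_id, group = tr$group,
                         day = tr$day, trials)
    }
  }
  if (k == 0) return(NULL)
  out <- do.call(rbind, lapply(rows[seq_len(k)], normalize_choice_columns))
  rownames(out) <- NULL
  out
}

CHOICE_COLUMNS <- c("subject_id", "group", "day", "task", "condition",
                    "trial_index", "guaranteed", "v", "p", "A",
                    "v_immediate", "v_delayed", "d_immediate", "d_delayed",
                    "choice")

normalize_choice_columns <- function(df) {
  for (col in setdiff(CHOICE_COLUMNS, names(df))) {
    df[[col]] <- if (col == "condition") NA_character_ else NA_real_
  }
  df[CHOICE_COLUMNS]
}

#' @export
print.daypref_cohort <- function(x, ...) {
  cat("Synthetic EMA cohort\n")
  cat(sprintf("  subjects: %d (%d patients, %d controls), days: %d\n",
              x$config$n_patients + x$config$n_controls,
              x$config$n_patients, x$config$n_controls, x$config$n_days))
  if (!is.null(x$choices)) {
    cat(sprintf("  choices: %d trial records\n", nrow(x$choices)))
  }
  cat(sprintf("  ratings: %d mood prompts; truth: %d subject-days\n",
              nrow(x$ratings), nrow(x$truth)))
  invisible(x)
}

#' Recast a ground-truth table as a day-fit table
#'
#' Converts the generator's latent subject-day parameters into the day-fit
#' schema of [fit_days()] (one row per completed subject-day-task, flagged
#' converged), so the variance-decomposition and state-model stages can be
#' run on noiseless parameters. This isolates the statistical stages from
#' estimation noise in calibration studies.
#'
#' @param truth Ground-truth table from [simulate_cohort()].
#' @return A day-fit table with the reported-scale parameter columns filled
#'   from the latent truth.
#' @export
truth_as_fits <- function(truth) {
  rows <- list()
  for (task in c("risk-gain", "risk-loss", "itc")) {
    done <- switch(task,
                   "risk-gain" = truth$completed_risk_gain,
                   "risk-loss" = truth$completed_risk_loss,
                   truth$completed_itc)
    t_rows <- truth[done, , drop = FALSE]
    if (nrow(t_rows) == 0) next
    fit <- data.frame(subject_id = t_rows$subject_id, group = t_rows$group,
                      day = t_rows$day, task = task)
    fit$risk_tol <- switch(task, "risk-gain" = t_rows$risk_tol_gain,
                           "risk-loss" = t_rows$risk_tol_loss, NA_real_)
    fit$amb_tol <- switch(task, "risk-gain" = t_rows$amb_tol_gain,
                          "risk-loss" = t_rows$amb_tol_loss, NA_real_)
    fit$log_kappa <- if (task == "itc") t_rows$log_kappa else NA_real_
    fit$converged <- TRUE
    rows <- c(rows, list(fit))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$day, out$task), , drop = FALSE]
}

#' Variance-component ICC of the generator's latent parameters
#'
#' Computes the one-way random-effects ICC of a noiseless latent parameter
#' series in the ground-truth table, via the ANOVA moment estimator. Used to
#' verify that the generator hits its configured between/within variance
#' ratio.
#'
#' @param truth Ground-truth table from [simulate_cohort()].
#' @param parameter One of `"risk_tol_gain"`, `"risk_tol_loss"`,
#'   `"amb_tol_gain"`, `"amb_tol_loss"`, `"log_kappa"`.
#' @return The ICC (between variance over total).
#' @export
truth_icc <- function(truth, parameter = REPORTED_PARAMS) {
  parameter <- match.arg(parameter)
  icc_anova(truth$subject_id, truth[[parameter]])$icc
}
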