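# Mixed-effects state-dependence analysis: day-level composite mood,
# repetition effects, diagnostic group differences, and within/between-person
# mood effects with diagnosis interactions. Fixed-effect inference uses
# Satterthwaite degrees of freedom via lmerTest.

#' Build day-level composite mood from momentary ratings
#'
#' Averages the positive and negative ratings of all prompts a subject
#' completed on a day, then forms the composite as the mean of positive mood
#' and the reflected (100 minus) negative mood, keeping the 0-100 scale.
#' Days without any completed prompt are absent.
#'
#' @param ratings Data.frame with `subject_id`, `day`, `positive`, `negative`
#'   (0-100) and optionally `group`.
#' @return Data.frame with one row per subject-day: `subject_id`, (`group`,)
#'   `day`, `positive`, `negative`, `composite`.
#' @examples
#' build_mood_days(data.frame(subject_id = "S1", day = 1,
#'                            positive = 70, negative = 20))
#' @export
build_mood_days <- function(ratings) {
  stopifnot(all(ratings$positive >= 0 & ratings$positive <= 100),
            all(ratings$negative >= 0 & ratings$negative <= 100))
  keys <- c("subject_id", intersect("group", names(ratings)), "day")
  out <- aggregate(ratings[c("positive", "negative")], ratings[keys], mean)
  out$composite <- (out$positive + (100 - out$negative)) / 2
  out[order(out$subject_id, out$day), , drop = FALSE]
}

# Running count of completed administrations per subject and task, up to and
# including the current day. Computed directly from the day-fit table (each
# row is one completed administration), so missed days do not advance it.
add_repetition <- function(series) {
  series <- series[order(series$subject_id, series$day), , drop = FALSE]
  key <- interaction(series$subject_id, drop = TRUE)
  series$repetition <- stats::ave(series$day, key, FUN = seq_along)
  series
}

code_diagnosis <- function(group, coding) {
  # default coding: control = 0, patient = 1
  if (coding == "control0") as.numeric(group == "patient")
  else as.numeric(group == "control")
}

# Fit a random-intercept LME for one parameter series and package the
# fixed-effects table with Satterthwaite df and 95% Wald CIs.
fit_state_lme <- function(series, formula, parameter, model,
                          coding = "control0") {
  fit <- lmerTest::lmer(formula, data = series, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular =
                                                      "ignore"))
  smry <- summary(fit, ddf = "Satterthwaite")
  co <- as.data.frame(smry$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  tcrit <- qt(0.975, co$df)
  terms <- data.frame(
    term = rownames(co), estimate = co$estimate, se = co$se,
    ci_lo = co$estimate - tcrit * co$se,
    ci_hi = co$estimate + tcrit * co$se,
    t = co$t, df = co$df, p = co$p, row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    parameter = parameter, model = model, terms = terms,
    ranef_variance = vc$vcov[vc$grp == "subject_id"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    n_observations = nrow(series),
    n_subjects = length(unique(series$subject_id)),
    diagnosis_coding = coding, formula = deparse(formula), fit = fit
  ), class = "daypref_lme")
}

#' @export
print.daypref_lme <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed model (%s) for %s: %s\n", x$model, x$parameter,
              x$formula))
  cat(sprintf("  %d observations, %d subjects; diagnosis coding: %s\n",
              x$n_observations, x$n_subjects, x$diagnosis_coding))
  print(format(x$terms, digits = digits), row.names = FALSE)
  invisible(x)
}

prepare_series <- function(fits, parameter, use_nonconverged = FALSE) {
  series <- parameter_series(fits, parameter,
                             use_nonconverged = use_nonconverged)
  add_repetition(series)
}

#' Repetition (practice) effect on a day-level parameter
#'
#' Fits `value ~ repetition + (1 | subject)` where repetition is the number
#' of times the subject had completed that task up to and including the
#' current day. A negative slope for, e.g., log discount rate means subjects
#' grow more patient with repeated administrations.
#'
#' @inheritParams parameter_series
#' @return A `daypref_lme` result (fixed-effect table with Satterthwaite df,
#'   95% CI, variance components).
#' @export
fit_repetition_model <- function(fits, parameter,
                                 use_nonconverged = FALSE) {
  series <- prepare_series(fits, parameter, use_nonconverged)
  fit_state_lme(series, value ~ repetition + (1 | subject_id), parameter,
                "repetition")
}

#' Diagnostic-group difference in a day-level parameter
#'
#' Fits `value ~ repetition + diagnosis + (1 | subject)`. Diagnosis is coded
#' control = 0, patient = 1 by default (`coding = "control0"`); flipping the
#' coding negates the estimate exactly, so the coding is carried in the
#' result's metadata.
#'
#' @inheritParams fit_repetition_model
#' @param coding `"control0"` (control = 0, patient = 1) or `"patient0"`.
#' @export
fit_group_model <- function(fits, parameter, coding = c("control0",
                                                        "patient0"),
                            use_nonconverged = FALSE) {
  coding <- match.arg(coding)
  series <- prepare_series(fits, parameter, use_nonconverged)
  series$diagnosis <- code_diagnosis(series$group, coding)
  fit_state_lme(series, value ~ repetition + diagnosis + (1 | subject_id),
                parameter, "group", coding)
}

#' Within- and between-person mood effects on a day-level parameter
#'
#' Decomposes each subject's daily composite mood into a person mean
#' (between-person, grand-mean-centered) and the day's deviation from that
#' mean (within-person centering), and fits
#' `value ~ repetition + diagnosis + mood_within + mood_between +
#' diagnosis:mood_within + diagnosis:mood_between + (1 | subject)`.
#' Only days with both a mood composite and a fitted parameter enter
#' (complete-case; missing days are censored). A positive `mood_within`
#' coefficient for gain risk tolerance means subjects tolerate more risk on
#' days of better-than-usual mood.
#'
#' @inheritParams fit_group_model
#' @param mood_days Day-level mood table from [build_mood_days()].
#' @export
fit_mood_model <- function(fits, mood_days, parameter,
                           coding = c("control0", "patient0"),
                           use_nonconverged = FALSE) {
  coding <- match.arg(coding)
  series <- prepare_series(fits, parameter, use_nonconverged)
  series <- merge(series, mood_days[, c("subject_id", "day", "composite")],
                  by = c("subject_id", "day"))
  series <- series[complete.cases(series[c("value", "composite")]), ,
                   drop = FALSE]
  person_mean <- stats::ave(series$composite, series$subject_id)
  series$mood_within <- series$composite - person_mean
  series$mood_between <- person_mean - mean(unique(
    data.frame(series$subject_id, person_mean))[, 2])
  series$diagnosis <- code_diagnosis(series$group, coding)
  fit_state_lme(
    series,
    value ~ repetition + diagnosis + mood_within + mood_between +
      diagnosis:mood_within + diagnosis:mood_between + (1 | subject_id),
    parameter, "mood", coding)
}
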