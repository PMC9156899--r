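# Shared fixture builders: simulate one subject-day of choices from known
# parameters on the exact task trial sets.

simulate_risk_day <- function(alpha, beta, gamma, condition = "gain",
                              seed = 1, n_trials = NULL) {
  trials <- risk_trials(condition, seed = seed)
  if (!is.null(n_trials)) {
    # resample the trial set to the requested length (for trial-count
    # sweeps: 27 = half task, 108 = double task)
    idx <- with_test_seed(seed + 17, {
      rep(seq_len(nrow(trials)), length.out = max(n_trials, nrow(trials)))
    })[seq_len(n_trials)]
    trials <- trials[idx, , drop = FALSE]
    trials$trial_index <- seq_len(nrow(trials))
  }
  pr <- daypref:::risk_choice_prob(trials, alpha, beta, gamma)
  trials$choice <- with_test_seed(seed, rbinom(nrow(trials), 1, pr))
  trials
}

simulate_itc_day <- function(kappa, gamma, convention = "immediate0",
                             seed = 1) {
  trials <- itc_trials(convention, seed = seed)
  pr <- daypref:::itc_choice_prob(trials, kappa, gamma)
  trials$choice <- with_test_seed(seed, rbinom(nrow(trials), 1, pr))
  trials
}

with_test_seed <- function(seed, code) daypref:::with_seed(seed, code)

# balanced panel with known between/within structure, for ICC identities
balanced_panel <- function(n_subjects, n_days, between_sd, within_sd,
                           seed = 1) {
  with_test_seed(seed, {
    mu <- rnorm(n_subjects, 0, between_sd)
    data.frame(
      subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = n_days),
      day = rep(seq_len(n_days), n_subjects),
      value = rep(mu, each = n_days) + rnorm(n_subjects * n_days, 0,
                                             within_sd)
    )
  })
}
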