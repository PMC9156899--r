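small_config <- function(...) {
  cohort_config(n_patients = 6, n_controls = 6, n_days = 10, ...)
}

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(compliance = c(patient = 1.2, control = 0.8)),
               "compliance")
  expect_error(cohort_config(mood_ar = 1), "mood_ar")
  expect_error(cohort_config(within_sd = c(risk_tol_gain = -1,
                                           risk_tol_loss = 0.6,
                                           amb_tol_gain = 0.8,
                                           amb_tol_loss = 0.8,
                                           log_kappa = 0.8)), "deviations")
  expect_error(cohort_config(nonsense = 1), "unknown config fields")
})

test_that("simulation is fully deterministic given the seed", {
  a <- simulate_cohort(small_config(seed = 5))
  b <- simulate_cohort(small_config(seed = 5))
  expect_identical(a$choices, b$choices)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(a$truth, c$truth))
})

test_that("compliance thinning matches the configured group rates", {
  # ~10,000 prompt opportunities per group
  cfg <- cohort_config(n_patients = 60, n_controls = 60, n_days = 28,
                       seed = 2)
  truth <- simulate_cohort(cfg, choices = FALSE)$truth
  done <- with(truth, c(completed_risk_gain, completed_risk_loss,
                        completed_itc))
  grp <- rep(truth$group, 3)
  expect_equal(mean(done[grp == "patient"]), 0.5414, tolerance = 0.02 / 0.54)
  expect_equal(mean(done[grp == "control"]), 0.8084, tolerance = 0.02 / 0.81)
})

test_that("patients show the configured offset in mean log discount rate", {
  cfg <- cohort_config(seed = 3, repetition_drift = c(
    risk_tol_gain = 0, risk_tol_loss = 0, amb_tol_gain = 0,
    amb_tol_loss = 0, log_kappa = 0))
  offs <- vapply(1:5, function(s) {
    cfg$seed <- s
    truth <- simulate_cohort(cfg, choices = FALSE)$truth
    mean(truth$log_kappa[truth$group == "patient"]) -
      mean(truth$log_kappa[truth$group == "control"])
  }, numeric(1))
  expect_equal(mean(offs), 2.17, tolerance = 0.35 / 2.17)
})

test_that("zero within-person variance gives constant days and ICC 1", {
  cfg <- small_config(
    seed = 4,
    within_sd = c(risk_tol_gain = 0, risk_tol_loss = 0, amb_tol_gain = 0,
                  amb_tol_loss = 0, log_kappa = 0),
    repetition_drift = c(risk_tol_gain = 0, risk_tol_loss = 0,
                         amb_tol_gain = 0, amb_tol_loss = 0, log_kappa = 0),
    mood_within_effect = 0)
  truth <- simulate_cohort(cfg, choices = FALSE)$truth
  spread <- tapply(truth$log_kappa, truth$subject_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_equal(truth_icc(truth, "log_kappa"), 1)
  expect_equal(truth_icc(truth, "amb_tol_gain"), 1)
})

test_that("generator hits a configured between/within variance ratio", {
  # between SD = within SD => ICC 1/2; and a targeted 0.67 for log kappa
  base <- list(group_offset_log_kappa = 0, mood_within_effect = 0,
               repetition_drift = c(risk_tol_gain = 0, risk_tol_loss = 0,
                                    amb_tol_gain = 0, amb_tol_loss = 0,
                                    log_kappa = 0))
  cfg_half <- do.call(cohort_config, c(base, list(
    seed = 8,
    within_sd = c(risk_tol_gain = 0.6, risk_tol_loss = 0.6,
                  amb_tol_gain = 0.8, amb_tol_loss = 0.8, log_kappa = 0.8),
    between_sd = c(risk_tol_gain = 0.6, risk_tol_loss = 0.6,
                   amb_tol_gain = 0.8, amb_tol_loss = 0.8, log_kappa = 0.8))))
  icc_half <- mean(vapply(1:5, function(s) {
    cfg_half$seed <- s
    truth_icc(simulate_cohort(cfg_half, choices = FALSE)$truth, "log_kappa")
  }, numeric(1)))
  expect_equal(icc_half, 0.5, tolerance = 0.03 / 0.5)

  # one 44 x 28 grid carries ~0.05 sampling SD in the ICC estimate, so the
  # targeting check averages 20 replicate grids
  cfg_67 <- do.call(cohort_config, c(base, list(seed = 9)))
  icc_67 <- mean(vapply(1:20, function(s) {
    cfg_67$seed <- s
    truth_icc(simulate_cohort(cfg_67, choices = FALSE)$truth, "log_kappa")
  }, numeric(1)))
  expect_equal(icc_67, 0.67, tolerance = 0.03 / 0.67)
})

test_that("mood ratings are anticorrelated and reproduce the latent composite", {
  coh <- simulate_cohort(small_config(seed = 10), choices = FALSE)
  expect_lt(cor(coh$ratings$positive, coh$ratings$negative), -0.4)
  mood <- build_mood_days(coh$ratings)
  joined <- merge(mood, coh$truth[, c("subject_id", "day", "mood_latent")])
  # composite equals latent mood except where ratings were clamped at 0/100
  interior <- joined$composite > 5 & joined$composite < 95
  expect_gt(cor(joined$composite, joined$mood_latent), 0.95)
  expect_lt(median(abs(joined$composite - joined$mood_latent)[interior]),
            1e-8)
})

test_that("fitting simulated choices recovers the variance structure", {
  flat <- c(risk_tol_gain = 0, risk_tol_loss = 0, amb_tol_gain = 0,
            amb_tol_loss = 0, log_kappa = 0)
  cfg <- cohort_config(seed = 91, n_patients = 8, n_controls = 8,
                       n_days = 10, repetition_drift = flat)
  coh <- simulate_cohort(cfg)
  fits <- fit_days(coh$choices, seed = 9)
  fitted_icc <- icc_table(fits)
  fitted <- setNames(fitted_icc$icc, fitted_icc$parameter)
  truth <- vapply(names(fitted), function(p) truth_icc(coh$truth, p),
                  numeric(1))
  # discounting is the most stable parameter end-to-end
  expect_equal(names(which.max(fitted)), "log_kappa")
  # per-day estimation noise adds within-person variance, so every fitted
  # ICC is attenuated relative to the latent one from the same study
  expect_true(all(fitted <= truth + 0.05))
})

test_that("simulated choices follow the generating preferences", {
  cfg <- small_config(seed = 12)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$choices$choice %in% 0:1))
  # steeper discounters should choose the delayed option less often
  itc <- coh$choices[coh$choices$task == "itc", ]
  rate <- tapply(itc$choice, itc$subject_id, mean)
  lk <- tapply(coh$truth$log_kappa, coh$truth$subject_id, mean)
  common <- intersect(names(rate), names(lk))
  expect_lt(cor(lk[common], rate[common], method = "spearman"), -0.5)
})
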