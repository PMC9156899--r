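test_that("an expected-value maximizer is recovered as alpha ~ 1, beta ~ 0", {
  trials <- risk_trials("gain", seed = 2)
  big <- trials[rep(seq_len(nrow(trials)), 4), ]  # many trials
  ev <- daypref:::clamp(big$p - 0 * big$A / 2, 0, 1) * big$v
  big$choice <- as.integer(ev > 0.50)
  fit <- fit_risk_day(big, seed = 1)
  expect_equal(fit$alpha, 1, tolerance = 0.15)
  expect_equal(fit$beta, 0, tolerance = 0.3)
})

test_that("simulate-and-refit recovers risk parameters within calibration", {
  # fixed-seed instance at the reference generating values
  day <- simulate_risk_day(alpha = 1, beta = 0, gamma = 5, seed = 11)
  fit <- fit_risk_day(day, seed = 1)
  expect_gte(fit$alpha, 0.7)
  expect_lte(fit$alpha, 1.4)
})

test_that("simulate-and-refit recovers the discount rate within a factor 2", {
  day <- simulate_itc_day(kappa = 0.05, gamma = 2, seed = 7)
  fit <- fit_itc_day(day, seed = 1)
  expect_gte(fit$kappa, 0.025)
  expect_lte(fit$kappa, 0.1)
})

test_that("an always-delayed chooser hits the lower kappa bound", {
  day <- itc_trials(seed = 1)
  day$choice <- 1
  fit <- fit_itc_day(day, seed = 1)
  expect_equal(fit$kappa, 1e-4)
  expect_false(fit$converged)   # degenerate day is flagged
})

test_that("fitted likelihood never falls below the grid-oracle optimum", {
  with_test_seed(99, {
    for (r in 1:5) {
      day <- simulate_risk_day(runif(1, 0.3, 2.5), runif(1, -2, 2),
                               exp(runif(1, log(0.5), log(6))),
                               condition = sample(c("gain", "loss"), 1),
                               seed = 400 + r)
      fit <- fit_risk_day(day, seed = r)
      oracle <- grid_oracle(day, "risk")
      expect_lte(fit$nll, oracle$nll + 1e-6)
      day2 <- simulate_itc_day(exp(runif(1, log(0.002), log(0.5))),
                               exp(runif(1, log(0.5), log(6))),
                               seed = 500 + r)
      fit2 <- fit_itc_day(day2, seed = r)
      oracle2 <- grid_oracle(day2, "itc")
      expect_lte(fit2$nll, oracle2$nll + 1e-6)
    }
  })
})

test_that("estimates respect the printed bounds and BIC is consistent", {
  day <- simulate_risk_day(2, 1, 2, seed = 3)
  fit <- fit_risk_day(day, seed = 2)
  expect_gte(fit$alpha, 0)
  expect_lte(fit$alpha, 10)
  expect_gte(fit$beta, -5)
  expect_lte(fit$beta, 5)
  expect_equal(fit$bic, 3 * log(fit$n_trials) + 2 * fit$nll,
               tolerance = 1e-12)
  day2 <- simulate_itc_day(0.02, 2, seed = 3)
  fit2 <- fit_itc_day(day2, seed = 2)
  expect_gte(fit2$kappa, 1e-4)
  expect_lte(fit2$kappa, 1)
  expect_equal(fit2$bic, 2 * log(fit2$n_trials) + 2 * fit2$nll,
               tolerance = 1e-12)
})

test_that("refitting with the same seed is bit-reproducible", {
  day <- simulate_risk_day(1.3, -0.5, 2, seed = 9)
  expect_identical(fit_risk_day(day, seed = 4), fit_risk_day(day, seed = 4))
  day2 <- simulate_itc_day(0.08, 2, seed = 9)
  expect_identical(fit_itc_day(day2, seed = 4), fit_itc_day(day2, seed = 4))
})

test_that("short days are censored and empty input errors", {
  day <- simulate_risk_day(1, 0, 2, seed = 5)[1:10, ]
  expect_warning(out <- fit_risk_day(day, seed = 1), "min_trials")
  expect_null(out)
  expect_error(fit_risk_day(day[0, ]))
})

make_itc_study <- function(convention, kappa, seed, n_days = 6, gamma = 3) {
  do.call(rbind, lapply(seq_len(n_days), function(d) {
    day <- simulate_itc_day(kappa, gamma, convention = convention,
                            seed = seed * 100 + d)
    cbind(subject_id = "S01", group = "control", day = d, task = "itc", day)
  }))
}

test_that("steep immediate0 discounters are identified by summed BIC", {
  # only discount rates above 1/8 per day are outside the reach of the
  # immediate7 coding, so identification is tested in that regime
  cmp0 <- compare_delay_conventions(make_itc_study("immediate0", 0.3, 7),
                                    seed = 1)
  expect_equal(cmp0$winner, "immediate0")
  expect_lt(cmp0$summed_bic[["immediate0"]], cmp0$summed_bic[["immediate7"]])
  expect_equal(nrow(cmp0$table), 12)  # 6 days x 2 conventions
})

test_that("the immediate7 coding is a rescaled submodel of immediate0", {
  # 1 + 7k(1+w) = (1+7k) (1 + 7 k/(1+7k) w): any immediate7 model is an
  # immediate0 model with kappa/(1+7kappa) and gamma scaled by 1/(1+7kappa),
  # so immediate7-generated data never fit immediate0 worse, and the
  # comparison resolves the tie toward immediate0
  for (kappa in c(0.02, 0.3)) {
    study <- compare_delay_conventions(
      make_itc_study("immediate7", kappa, 8), seed = 1)
    per_day <- tapply(study$table$nll, study$table$convention, sum)
    expect_lte(per_day[["immediate0"]], per_day[["immediate7"]] + 1e-4)
    expect_equal(study$winner, "immediate0")
  }
  # the equivalence in closed form: identical likelihoods trial by trial
  trials <- itc_trials("immediate7")
  kp <- 0.12
  g <- 2
  mapped_k <- kp / (1 + 7 * kp)
  mapped_g <- g / (1 + 7 * kp)
  p7 <- daypref:::itc_choice_prob(trials, kp, g)
  p0 <- daypref:::itc_choice_prob(daypref:::recode_delays(trials,
                                                          "immediate0"),
                                  mapped_k, mapped_g)
  expect_equal(p0, p7, tolerance = 1e-12)
})
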