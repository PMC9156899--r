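test_that("ICC identities hold on constructed series", {
  # distinct constant values per subject: all variation is between-person
  const <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 5),
                      value = rep(c(1, 2, 3, 4), each = 5))
  expect_equal(compute_icc(const)$icc, 1, tolerance = 1e-6)
  # i.i.d. values with no subject structure: ICC ~ 0
  iid <- balanced_panel(40, 20, between_sd = 0, within_sd = 1, seed = 2)
  expect_lt(compute_icc(iid)$icc, 0.05)
  expect_true(compute_icc(iid)$singular ||
                compute_icc(iid)$sigma2_between < 0.05)
  # equal components: ICC ~ 1/2 on 44 x 28 grids (averaged over panels;
  # a single panel's ICC has sampling SD ~ 0.06)
  eq_icc <- mean(vapply(3:7, function(s) {
    compute_icc(balanced_panel(44, 28, between_sd = 1, within_sd = 1,
                               seed = s))$icc
  }, numeric(1)))
  expect_equal(eq_icc, 0.5, tolerance = 0.03 / 0.5)
})

test_that("REML and ANOVA-moment estimators agree on balanced panels", {
  panel <- balanced_panel(30, 12, between_sd = 0.8, within_sd = 1.1,
                          seed = 4)
  reml <- compute_icc(panel)
  mom <- icc_anova(panel$subject_id, panel$value)
  # REML equals the moment estimator exactly on balanced complete one-way
  # layouts (interior solutions)
  expect_equal(reml$icc, mom$icc, tolerance = 1e-6)
  expect_equal(reml$sigma2_between, mom$sigma2_between, tolerance = 1e-6)
  expect_equal(reml$sigma2_within, mom$sigma2_within, tolerance = 1e-6)
})

test_that("ICC is invariant to affine rescaling", {
  panel <- balanced_panel(20, 10, 0.7, 1, seed = 5)
  base <- compute_icc(panel)$icc
  panel$value <- 3.2 * panel$value - 17
  expect_equal(compute_icc(panel)$icc, base, tolerance = 1e-6)
})

test_that("week-mean down-sampling averages available days per week", {
  full <- data.frame(subject_id = "S01", day = 1:28, value = 1:28)
  wk <- downsample_week_mean(full)
  expect_equal(nrow(wk), 4)
  expect_equal(wk$value, c(mean(1:7), mean(8:14), mean(15:21), mean(22:28)))
  # a subject observed only in week 2 contributes one timepoint
  sparse <- data.frame(subject_id = "S02", day = c(9, 11), value = c(2, 4))
  wk2 <- downsample_week_mean(sparse)
  expect_equal(nrow(wk2), 1)
  expect_equal(wk2$value, 3)
})

test_that("week-averaging raises ICC by roughly the analytic factor", {
  # independent day noise: averaging 7 days shrinks within variance ~ 1/7
  panel <- balanced_panel(44, 28, between_sd = 0.7, within_sd = 1, seed = 6)
  day_icc <- compute_icc(panel)$icc
  wk <- downsample_week_mean(panel)
  wk_icc <- compute_icc(wk)$icc
  expect_gt(wk_icc, day_icc)
  predicted <- 0.49 / (0.49 + 1 / 7)
  expect_equal(wk_icc, predicted, tolerance = 0.08 / predicted)
})

test_that("random-day selection respects the spacing constraint", {
  full <- data.frame(subject_id = "S01", day = 1:28, value = rnorm(28))
  sel <- downsample_random_days(full, seed = 1)
  expect_equal(nrow(sel), 4)
  expect_true(all(diff(sort(sel$day)) >= 4))
  expect_identical(downsample_random_days(full, seed = 1),
                   downsample_random_days(full, seed = 1))
  expect_false(identical(downsample_random_days(full, seed = 2)$day,
                         downsample_random_days(full, seed = 3)$day))
})

test_that("random-day selection is uniform over the eligible combinations", {
  # one available day pattern small enough to enumerate: days 1,4,7 per week
  avail <- c(1, 4, 7, 8, 11, 14, 15, 18, 21, 22, 25, 28)
  series <- data.frame(subject_id = "S01", day = avail, value = 0)
  eligible <- expand.grid(w1 = c(1, 4, 7), w2 = c(8, 11, 14),
                          w3 = c(15, 18, 21), w4 = c(22, 25, 28))
  ok <- apply(eligible, 1, function(d) all(diff(sort(d)) >= 4))
  eligible <- eligible[ok, ]
  picks <- vapply(1:2000, function(s) {
    paste(sort(downsample_random_days(series, seed = s)$day), collapse = "-")
  }, character(1))
  keys <- apply(eligible, 1, function(d) paste(sort(d), collapse = "-"))
  expect_setequal(unique(picks), keys)
  # roughly uniform coverage
  freq <- table(picks)
  expect_gt(min(freq) / max(freq), 0.4)
})

test_that("correlation matrices have unit diagonal and expected structure", {
  cfg <- cohort_config(n_patients = 10, n_controls = 10, n_days = 12,
                       seed = 13, mood_within_effect = 0)
  truth <- simulate_cohort(cfg, choices = FALSE)$truth
  # build a pseudo-fit table straight from the truth (no estimation noise)
  fits <- truth_as_fits(truth)
  cm <- correlation_matrices(fits)
  # same parameter, same day is a unit correlation by construction
  wide <- daypref:::reshape_days(
    data.frame(subject_id = truth$subject_id, day = truth$day,
               x = truth$log_kappa), "x", sort(unique(truth$day)))
  expect_equal(cor(wide[, 1], wide[, 1]), 1)
  # parameters are generated independently: small between-parameter R
  expect_lt(mean(abs(cm$summary$mean_r[cm$summary$type == "between"])), 0.15)
  # stable parameters: test-retest exceeds between-parameter correlations
  expect_gt(mean(cm$summary$mean_r[cm$summary$type == "retest"]),
            mean(cm$summary$mean_r[cm$summary$type == "between"]))
})
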