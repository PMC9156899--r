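# Per-subject-per-day maximum-likelihood estimation of the choice-model
# parameters, a brute-force grid oracle used for verification, and the BIC
# comparison of the two intertemporal delay conventions.
#
# Optimization runs in an unconstrained transformed space: alpha, beta and
# log(kappa) are logit-scaled within their bounds and gamma is log-logit
# scaled within [0.001, 50]. Nelder-Mead with multiple quasi-random starts
# (plus the best points of a coarse pre-scan) handles the multimodality the
# likelihood exhibits in gamma.

# logit-bounded reparameterization ---------------------------------------

to_unit <- function(x, lo, hi) (x - lo) / (hi - lo)
from_unit <- function(u, lo, hi) lo + u * (hi - lo)

box_transform <- function(theta, lo, hi) from_unit(plogis(theta), lo, hi)
box_untransform <- function(x, lo, hi) {
  qlogis(clamp(to_unit(x, lo, hi), 1e-8, 1 - 1e-8))
}

risk_natural <- function(theta) {
  c(alpha = box_transform(theta[1], ALPHA_BOUNDS[1], ALPHA_BOUNDS[2]),
    beta = box_transform(theta[2], BETA_BOUNDS[1], BETA_BOUNDS[2]),
    gamma = exp(box_transform(theta[3], log(GAMMA_BOUNDS[1]),
                              log(GAMMA_BOUNDS[2]))))
}

itc_natural <- function(theta) {
  c(kappa = exp(box_transform(theta[1], log(KAPPA_BOUNDS[1]),
                              log(KAPPA_BOUNDS[2]))),
    gamma = exp(box_transform(theta[2], log(GAMMA_BOUNDS[1]),
                              log(GAMMA_BOUNDS[2]))))
}

# negative log-likelihoods ------------------------------------------------

risk_nll <- function(alpha, beta, gamma, trials, choice) {
  lp1 <- risk_choice_prob(trials, alpha, beta, gamma, log.p = TRUE)
  eu_lottery <- expected_utility(trials$v, trials$p, trials$A, alpha, beta)
  eu_safe <- expected_utility(trials$guaranteed, 1, 0, alpha, beta)
  lp0 <- choice_prob(eu_safe, eu_lottery, gamma, log.p = TRUE)
  -sum(ifelse(choice == 1, lp1, lp0))
}

itc_nll <- function(kappa, gamma, trials, choice) {
  u_del <- discounted_utility(trials$v_delayed, trials$d_delayed, kappa)
  u_imm <- discounted_utility(trials$v_immediate, trials$d_immediate, kappa)
  lp1 <- choice_prob(u_del, u_imm, gamma, log.p = TRUE)
  lp0 <- choice_prob(u_imm, u_del, gamma, log.p = TRUE)
  -sum(ifelse(choice == 1, lp1, lp0))
}

# vectorized likelihood scans ---------------------------------------------

# Negative log-likelihood over a lattice of natural parameters, evaluated
# with matrix operations. Returns the `top_k` best points. Shared by the
# exhaustive testing oracle (dense lattice) and the fitting pre-scan
# (coarse lattice seeding the local optimizer).
risk_nll_scan <- function(records, choice, alphas, betas, gammas,
                          top_k = 1L) {
  grid <- expand.grid(alpha = alphas, beta = betas)
  vpow <- outer(records$v, grid$alpha, function(v, a) sign(v) * abs(v)^a)
  gpow <- outer(records$guaranteed, grid$alpha,
                function(v, a) sign(v) * abs(v)^a)
  peff <- clamp(outer(records$A, grid$beta, function(A, b) -b * A / 2) +
                  records$p, 0, 1)
  du <- peff * vpow - gpow
  sgn <- ifelse(choice == 1, 1, -1)
  out <- do.call(rbind, lapply(gammas, function(g) {
    nll <- -colSums(plogis(g * sgn * du, log.p = TRUE))
    keep <- order(nll)[seq_len(top_k)]
    data.frame(alpha = grid$alpha[keep], beta = grid$beta[keep], gamma = g,
               nll = nll[keep])
  }))
  out[order(out$nll)[seq_len(top_k)], , drop = FALSE]
}

itc_nll_scan <- function(records, choice, kappas, gammas, top_k = 1L) {
  u_imm <- outer(seq_len(nrow(records)), kappas, function(i, k) {
    records$v_immediate[i] / (1 + k * records$d_immediate[i])
  })
  u_del <- outer(seq_len(nrow(records)), kappas, function(i, k) {
    records$v_delayed[i] / (1 + k * records$d_delayed[i])
  })
  du <- u_del - u_imm
  sgn <- ifelse(choice == 1, 1, -1)
  out <- do.call(rbind, lapply(gammas, function(g) {
    nll <- -colSums(plogis(g * sgn * du, log.p = TRUE))
    keep <- order(nll)[seq_len(top_k)]
    data.frame(kappa = kappas[keep], gamma = g, nll = nll[keep])
  }))
  out[order(out$nll)[seq_len(top_k)], , drop = FALSE]
}

gamma_lattice <- function(n) {
  exp(seq(log(GAMMA_BOUNDS[1]), log(GAMMA_BOUNDS[2]), length.out = n))
}

# multi-start driver ------------------------------------------------------

# Minimize fn (on the transformed scale) from a fixed set of lattice-derived
# starting points, a neutral start, and seeded random fills. The likelihood
# is multimodal in gamma, so the deterministic lattice seeds matter.
multistart_optim <- function(fn, n_par, neutral, lattice_starts, seed,
                             n_random = 4) {
  fill <- with_seed(seed,
                    matrix(runif(n_random * n_par, -3, 3), ncol = n_par))
  starts <- rbind(neutral, lattice_starts, fill)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- optim(starts[i, ], fn, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  best$n_starts <- nrow(starts)
  best
}

# Snap estimates that converged against a box edge onto the bound itself,
# so boundary solutions (e.g. always-delayed choosers at kappa = 0.0001)
# are reported exactly.
snap_bound <- function(x, lo, hi, log_scale = FALSE, tol = 1e-3) {
  if (log_scale) {
    if (log(x) - log(lo) < tol * (log(hi) - log(lo))) return(lo)
    if (log(hi) - log(x) < tol * (log(hi) - log(lo))) return(hi)
  } else {
    if (x - lo < tol * (hi - lo)) return(lo)
    if (hi - x < tol * (hi - lo)) return(hi)
  }
  x
}

at_bound <- function(x, lo, hi, log_scale = FALSE) {
  identical(snap_bound(x, lo, hi, log_scale), lo) ||
    identical(snap_bound(x, lo, hi, log_scale), hi)
}

#' Fit the risk/ambiguity model to one subject-day of choices
#'
#' Maximizes the Bernoulli likelihood of the observed lottery-vs-guaranteed
#' choices under the power-utility model with logistic choice, over
#' `alpha` in \[0, 10\], `beta` in \[-5, 5\] and `gamma` in \[0.001, 50\]
#' (log scale), using bounded multi-start Nelder-Mead. Days on which every
#' choice was identical are fit but flagged `converged = FALSE`, as are fits
#' ending on a parameter bound; such days are excluded from downstream mixed
#' models by default.
#'
#' @param records Data.frame of one subject-day-condition: trial columns of
#'   [risk_trials()] plus `choice` (1 = lottery).
#' @param seed Integer seed for the optimizer restarts.
#' @param min_trials Minimum number of trials required; fewer returns `NULL`
#'   with a warning (the day is censored, not imputed).
#' @return A one-row data.frame (a day fit): `alpha`, `beta`, `gamma`,
#'   reported-scale `risk_tol` and `amb_tol`, `nll`, `bic`, `n_trials`,
#'   `converged`, `n_starts`.
#' @export
fit_risk_day <- function(records, seed = 1, min_trials = 20) {
  stopifnot(nrow(records) >= 1, all(records$choice %in% 0:1))
  condition <- unique(records$condition)
  if (length(condition) != 1) {
    stop("records must come from a single condition (gain or loss)")
  }
  if (nrow(records) < min_trials) {
    warning(sprintf("day excluded: %d trials < min_trials = %d",
                    nrow(records), min_trials))
    return(NULL)
  }
  choice <- records$choice
  fn <- function(theta) {
    p <- risk_natural(theta)
    risk_nll(p[["alpha"]], p[["beta"]], p[["gamma"]], records, choice)
  }
  neutral <- c(box_untransform(1, ALPHA_BOUNDS[1], ALPHA_BOUNDS[2]),
               box_untransform(0, BETA_BOUNDS[1], BETA_BOUNDS[2]),
               box_untransform(log(1), log(GAMMA_BOUNDS[1]),
                               log(GAMMA_BOUNDS[2])))
  scan <- risk_nll_scan(records, choice,
                        alphas = seq(0.05, 9.95, length.out = 12),
                        betas = seq(-4.95, 4.95, length.out = 13),
                        gammas = gamma_lattice(10), top_k = 6L)
  lattice_starts <- cbind(
    box_untransform(scan$alpha, ALPHA_BOUNDS[1], ALPHA_BOUNDS[2]),
    box_untransform(scan$beta, BETA_BOUNDS[1], BETA_BOUNDS[2]),
    box_untransform(log(scan$gamma), log(GAMMA_BOUNDS[1]),
                    log(GAMMA_BOUNDS[2])))
  best <- multistart_optim(fn, 3, neutral, lattice_starts,
                           derive_seed(seed, "fit-risk"))
  est <- risk_natural(best$par)
  alpha <- snap_bound(est[["alpha"]], ALPHA_BOUNDS[1], ALPHA_BOUNDS[2])
  beta <- snap_bound(est[["beta"]], BETA_BOUNDS[1], BETA_BOUNDS[2])
  gamma <- snap_bound(est[["gamma"]], GAMMA_BOUNDS[1], GAMMA_BOUNDS[2],
                      log_scale = TRUE)
  rep_par <- reported_params(alpha = alpha, beta = beta,
                             condition = condition)
  n <- nrow(records)
  degenerate <- length(unique(choice)) == 1
  boundary <- at_bound(alpha, ALPHA_BOUNDS[1], ALPHA_BOUNDS[2]) ||
    at_bound(beta, BETA_BOUNDS[1], BETA_BOUNDS[2]) ||
    at_bound(gamma, GAMMA_BOUNDS[1], GAMMA_BOUNDS[2], log_scale = TRUE)
  data.frame(
    alpha = alpha, beta = beta, gamma = gamma,
    risk_tol = rep_par$risk_tol, amb_tol = rep_par$amb_tol,
    nll = best$value, bic = 3 * log(n) + 2 * best$value,
    n_trials = n,
    converged = best$convergence == 0 && !degenerate && !boundary,
    n_starts = best$n_starts
  )
}

#' Fit the hyperbolic discounting model to one subject-day of choices
#'
#' Maximizes the Bernoulli likelihood of delayed-vs-immediate choices under
#' linear-utility hyperbolic discounting with logistic choice, over `kappa`
#' in \[0.0001, 1\] (log scale) and `gamma` in \[0.001, 50\] (log scale).
#' Delays are recoded from the trial's week index according to `convention`
#' before fitting, so the same records can be fit under either delay coding.
#'
#' @param records Data.frame of one subject-day: trial columns of
#'   [itc_trials()] plus `choice` (1 = delayed).
#' @param convention `"immediate0"` (sooner option at 0 days, delays 7/14/21)
#'   or `"immediate7"` (sooner option at 7 days, delays 14/21/28).
#' @inheritParams fit_risk_day
#' @return A one-row data.frame: `kappa`, `gamma`, `log_kappa`, `nll`, `bic`,
#'   `n_trials`, `converged`, `n_starts`.
#' @export
fit_itc_day <- function(records, convention = c("immediate0", "immediate7"),
                        seed = 1, min_trials = 20) {
  convention <- match.arg(convention)
  stopifnot(nrow(records) >= 1, all(records$choice %in% 0:1))
  if (nrow(records) < min_trials) {
    warning(sprintf("day excluded: %d trials < min_trials = %d",
                    nrow(records), min_trials))
    return(NULL)
  }
  records <- recode_delays(records, convention)
  choice <- records$choice
  fn <- function(theta) {
    p <- itc_natural(theta)
    itc_nll(p[["kappa"]], p[["gamma"]], records, choice)
  }
  neutral <- c(box_untransform(log(0.01), log(KAPPA_BOUNDS[1]),
                               log(KAPPA_BOUNDS[2])),
               box_untransform(log(1), log(GAMMA_BOUNDS[1]),
                               log(GAMMA_BOUNDS[2])))
  scan <- itc_nll_scan(records, choice,
                       kappas = exp(seq(log(KAPPA_BOUNDS[1]), 0,
                                        length.out = 15)),
                       gammas = gamma_lattice(10), top_k = 5L)
  lattice_starts <- cbind(
    box_untransform(log(scan$kappa), log(KAPPA_BOUNDS[1]),
                    log(KAPPA_BOUNDS[2])),
    box_untransform(log(scan$gamma), log(GAMMA_BOUNDS[1]),
                    log(GAMMA_BOUNDS[2])))
  best <- multistart_optim(fn, 2, neutral, lattice_starts,
                           derive_seed(seed, "fit-itc"))
  est <- itc_natural(best$par)
  kappa <- snap_bound(est[["kappa"]], KAPPA_BOUNDS[1], KAPPA_BOUNDS[2],
                      log_scale = TRUE)
  gamma <- snap_bound(est[["gamma"]], GAMMA_BOUNDS[1], GAMMA_BOUNDS[2],
                      log_scale = TRUE)
  n <- nrow(records)
  degenerate <- length(unique(choice)) == 1
  boundary <- at_bound(kappa, KAPPA_BOUNDS[1], KAPPA_BOUNDS[2], TRUE) ||
    at_bound(gamma, GAMMA_BOUNDS[1], GAMMA_BOUNDS[2], TRUE)
  data.frame(
    kappa = kappa, gamma = gamma, log_kappa = log(kappa),
    nll = best$value, bic = 2 * log(n) + 2 * best$value,
    n_trials = n,
    converged = best$convergence == 0 && !degenerate && !boundary,
    n_starts = best$n_starts
  )
}

# Recode immediate/delayed delays from the trial's week index under a delay
# convention; robust to records generated under the other convention.
recode_delays <- function(records, convention) {
  week <- round((records$d_delayed - records$d_immediate) / 7)
  stopifnot(all(week %in% 1:3))
  d0 <- if (convention == "immediate0") 0L else 7L
  records$d_immediate <- d0
  records$d_delayed <- d0 + 7L * week
  records
}

#' Fit all subject-days in a long choice table
#'
#' Splits a choice-record table by subject, day and task and fits the
#' matching model to each cell. Days with fewer than `min_trials` records are
#' censored (dropped with a warning).
#'
#' @param choices Long data.frame of choice records (see [read_choices()] for
#'   the schema).
#' @param convention Delay convention for intertemporal fits.
#' @inheritParams fit_risk_day
#' @return A day-fit table: one row per subject-day-task with the columns of
#'   [fit_risk_day()] / [fit_itc_day()] plus `subject_id`, `group`, `day`,
#'   `task`.
#' @export
fit_days <- function(choices, convention = "immediate0", seed = 1,
                     min_trials = 20) {
  key <- interaction(choices$subject_id, choices$day, choices$task,
                     drop = TRUE)
  parts <- split(choices, key)
  rows <- lapply(parts, function(part) {
    task <- part$task[1]
    cell_seed <- derive_seed(seed, part$subject_id[1], part$day[1], task)
    fit <- if (task == "itc") {
      fit_itc_day(part, convention = convention, seed = cell_seed,
                  min_trials = min_trials)
    } else {
      part$condition <- sub("risk-", "", task)
      fit_risk_day(part, seed = cell_seed, min_trials = min_trials)
    }
    if (is.null(fit)) return(NULL)
    meta <- data.frame(subject_id = part$subject_id[1],
                       group = part$group[1], day = part$day[1], task = task)
    merge_fit_row(meta, fit)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(empty_fits())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$day, out$task), , drop = FALSE]
}

FIT_COLUMNS <- c("subject_id", "group", "day", "task", "alpha", "beta",
                 "kappa", "gamma", "risk_tol", "amb_tol", "log_kappa",
                 "nll", "bic", "n_trials", "converged", "n_starts")

merge_fit_row <- function(meta, fit) {
  row <- cbind(meta, fit)
  for (col in setdiff(FIT_COLUMNS, names(row))) row[[col]] <- NA_real_
  row[FIT_COLUMNS]
}

empty_fits <- function() {
  out <- data.frame(subject_id = character(), group = character(),
                    day = integer(), task = character())
  for (col in setdiff(FIT_COLUMNS, names(out))) out[[col]] <- numeric()
  out$converged <- logical()
  out
}

#' Exhaustive grid evaluation of the day likelihood (testing oracle)
#'
#' Evaluates the negative log-likelihood over a dense grid spanning the full
#' parameter box and returns the best grid point. Intended as an independent
#' check on the bounded optimizer, not for routine fitting.
#'
#' @param records One subject-day of choice records (risk or intertemporal
#'   schema).
#' @param model `"risk"` or `"itc"`.
#' @param resolution Named list overriding grid sizes: `n_alpha`, `n_beta`,
#'   `n_kappa` and `n_gamma`.
#' @return A list with the best-on-grid natural parameters and `nll`.
#' @export
grid_oracle <- function(records, model = c("risk", "itc"),
                        resolution = list()) {
  model <- match.arg(model)
  res <- utils::modifyList(
    list(n_alpha = 50, n_beta = 50, n_kappa = 50, n_gamma = 20), resolution)
  gammas <- gamma_lattice(res$n_gamma)
  choice <- records$choice
  if (model == "risk") {
    best <- risk_nll_scan(
      records, choice,
      alphas = seq(ALPHA_BOUNDS[1], ALPHA_BOUNDS[2],
                   length.out = res$n_alpha),
      betas = seq(BETA_BOUNDS[1], BETA_BOUNDS[2], length.out = res$n_beta),
      gammas = gammas)
    list(alpha = best$alpha, beta = best$beta, gamma = best$gamma,
         nll = best$nll)
  } else {
    best <- itc_nll_scan(
      records, choice,
      kappas = exp(seq(log(KAPPA_BOUNDS[1]), log(KAPPA_BOUNDS[2]),
                       length.out = res$n_kappa)),
      gammas = gammas)
    list(kappa = best$kappa, gamma = best$gamma, nll = best$nll)
  }
}

#' Compare the two intertemporal delay conventions by BIC
#'
#' Fits every subject-day of intertemporal choices under both delay codings
#' and totals the BIC. The convention with the smaller summed BIC wins; exact
#' ties go to `"immediate0"` (the as-soon-as-possible reading).
#'
#' @param choices Long choice-record table containing `task == "itc"` rows.
#' @inheritParams fit_days
#' @param tie_tol Summed-BIC differences smaller than this are treated as a
#'   tie (the two codings can coincide exactly up to optimizer tolerance, so
#'   exact-zero ties are unobservable numerically).
#' @return A list: `table` (per subject-day BIC under each convention),
#'   `summed_bic` (named length-2 vector) and `winner`.
#' @export
compare_delay_conventions <- function(choices, seed = 1, min_trials = 20,
                                      tie_tol = 1e-3) {
  itc <- choices[choices$task == "itc", , drop = FALSE]
  if (nrow(itc) == 0) stop("no intertemporal choice records")
  fits <- lapply(c("immediate0", "immediate7"), function(conv) {
    f <- fit_days(itc, convention = conv, seed = seed,
                  min_trials = min_trials)
    f$convention <- conv
    f
  })
  tab <- do.call(rbind, fits)[, c("subject_id", "day", "convention",
                                  "bic", "nll", "n_trials")]
  summed <- tapply(tab$bic, tab$convention, sum)
  winner <- if (summed[["immediate7"]] < summed[["immediate0"]] - tie_tol) {
    "immediate7"
  } else {
    "immediate0"
  }
  list(table = tab, summed_bic = c(summed), winner = winner)
}
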