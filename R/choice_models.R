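# Utility models and logistic choice rules for the two tasks, plus the
# transforms between native parameters (alpha, beta, kappa) and the
# interpretable reported scale.

ALPHA_BOUNDS <- c(0, 10)
BETA_BOUNDS <- c(-5, 5)
KAPPA_BOUNDS <- c(1e-4, 1)
GAMMA_BOUNDS <- c(1e-3, 50)

# sign-preserving power: |v|^alpha with the sign of v restored, so the loss
# domain uses the same curvature parameter as gains.
signed_power <- function(v, alpha) sign(v) * abs(v)^alpha

#' Expected utility of a risky or ambiguous lottery
#'
#' Power-utility valuation with a linear ambiguity penalty: the effective win
#' probability is `p - beta * A / 2` (clamped to \[0, 1\]) and the value is
#' raised to `alpha`, with the sign of `v` preserved so losses are valued
#' symmetrically. The guaranteed option is the degenerate case `p = 1, A = 0`.
#' `alpha = 1` is risk neutrality (expected-value maximization); `beta = 0` is
#' ambiguity neutrality.
#'
#' @param v Outcome value in dollars (sign-bearing).
#' @param p Stated win (or loss) probability.
#' @param A Occluded fraction of the probability scale (0 on known-risk
#'   trials).
#' @param alpha Risk tolerance curvature, in \[0, 10\].
#' @param beta Ambiguity attitude, in \[-5, 5\].
#' @return Expected utility (vectorized over arguments).
#' @examples
#' expected_utility(6.60, p = 0.25, A = 0, alpha = 1, beta = 0) # 1.65
#' @export
expected_utility <- function(v, p, A, alpha, beta) {
  clamp(p - beta * A / 2, 0, 1) * signed_power(v, alpha)
}

#' Discounted utility of a delayed reward
#'
#' Linear-utility hyperbolic discounting: `v / (1 + kappa * d)` with the delay
#' `d` in days and discount rate `kappa` in \[0.0001, 1\] per day.
#'
#' @param v Reward in dollars (> 0).
#' @param d Delay in days (>= 0).
#' @param kappa Hyperbolic discount rate per day.
#' @return Discounted utility (vectorized).
#' @examples
#' discounted_utility(6.60, d = 7, kappa = 0.1) # 6.60 / 1.7
#' @export
discounted_utility <- function(v, d, kappa) {
  v / (1 + kappa * d)
}

#' Logistic (softmax) choice probability
#'
#' Probability of choosing the first option given the utility difference and
#' a choice-stochasticity (inverse temperature) parameter `gamma`:
#' `1 / (1 + exp(-gamma * (u1 - u2)))`. Used both for lottery-vs-guaranteed
#' and delayed-vs-immediate choices.
#'
#' @param u1,u2 Utilities of the focal and reference option.
#' @param gamma Choice stochasticity (> 0); large `gamma` approaches
#'   deterministic utility maximization.
#' @param log.p Return log probability.
#' @return Choice probability in (0, 1) for finite inputs.
#' @examples
#' choice_prob(1.65, 0.50, gamma = 1)
#' @export
choice_prob <- function(u1, u2, gamma, log.p = FALSE) {
  plogis(gamma * (u1 - u2), log.p = log.p)
}

#' @rdname choice_prob
#' @export
prob_choose_lottery <- function(u1, u2, gamma) choice_prob(u1, u2, gamma)

#' @rdname choice_prob
#' @export
prob_choose_delayed <- function(u1, u2, gamma) choice_prob(u1, u2, gamma)

# Probability of choosing the lottery on risk-task trials, vectorized over a
# trial table. The guaranteed option is evaluated in the same utility space
# as a degenerate lottery (p = 1, A = 0).
risk_choice_prob <- function(trials, alpha, beta, gamma, log.p = FALSE) {
  eu_lottery <- expected_utility(trials$v, trials$p, trials$A, alpha, beta)
  eu_safe <- expected_utility(trials$guaranteed, 1, 0, alpha, beta)
  choice_prob(eu_lottery, eu_safe, gamma, log.p = log.p)
}

itc_choice_prob <- function(trials, kappa, gamma, log.p = FALSE) {
  u_del <- discounted_utility(trials$v_delayed, trials$d_delayed, kappa)
  u_imm <- discounted_utility(trials$v_immediate, trials$d_immediate, kappa)
  choice_prob(u_del, u_imm, gamma, log.p = log.p)
}

#' Convert native model parameters to the reported preference scale
#'
#' Preferences are reported on scales where 0 is neutrality and larger values
#' mean more tolerance: risk tolerance is `alpha - 1` in gains and `1 - alpha`
#' in losses; ambiguity tolerance is `-beta` in gains and `beta` in losses;
#' the discount rate is reported as `log(kappa)` (higher = steeper
#' discounting). [native_params()] is the exact inverse.
#'
#' @param alpha,beta Risk-task parameters (used when `condition` is `"gain"`
#'   or `"loss"`).
#' @param kappa Discount rate (used when `condition = "none"`).
#' @param condition `"gain"`, `"loss"`, or `"none"` for the intertemporal
#'   task.
#' @return A named list with `risk_tol` and `amb_tol`, or `log_kappa`.
#' @examples
#' reported_params(alpha = 1, beta = 0, condition = "gain")
#' @export
reported_params <- function(alpha = NULL, beta = NULL, kappa = NULL,
                            condition = c("gain", "loss", "none")) {
  condition <- match.arg(condition)
  if (condition == "none") {
    return(list(log_kappa = log(kappa)))
  }
  if (condition == "gain") {
    list(risk_tol = alpha - 1, amb_tol = -beta)
  } else {
    list(risk_tol = 1 - alpha, amb_tol = beta)
  }
}

#' @rdname reported_params
#' @param risk_tol,amb_tol,log_kappa Reported-scale values to invert.
#' @export
native_params <- function(risk_tol = NULL, amb_tol = NULL, log_kappa = NULL,
                          condition = c("gain", "loss", "none")) {
  condition <- match.arg(condition)
  if (condition == "none") {
    return(list(kappa = exp(log_kappa)))
  }
  if (condition == "gain") {
    list(alpha = risk_tol + 1, beta = -amb_tol)
  } else {
    list(alpha = 1 - risk_tol, beta = amb_tol)
  }
}
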