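# Trial-set generation for the two EMA economic tasks and the
# bonus-realization (incentive) scheme.

# Printed design constants, in cents. The lottery value set is shared by the
# gain and loss conditions (loss negates everything, including the guaranteed
# option).
RISK_VALUES_CENTS <- c(60L, 80L, 120L, 180L, 260L, 390L, 440L, 660L)
RISK_PROBS <- c(0.25, 0.50, 0.75)
RISK_AMBIGUITY <- c(0.24, 0.50, 0.74)
RISK_GUARANTEED_CENTS <- 50L
BONUS_CAP <- 6.60
# Ambiguity trials show an occluder centered on the probability scale, so the
# nominal win probability carried by the trial is 0.50 and the occluded
# fraction A straddles it.
AMBIGUITY_NOMINAL_P <- 0.50

ITC_GRID_CENTS <- list(
  `20`  = c(70L, 120L, 220L, 420L, 660L),
  `50`  = c(100L, 150L, 250L, 450L, 650L),
  `150` = c(200L, 250L, 350L, 550L, 650L)
)
ITC_DELAYS_WEEKS <- 1:3

#' Generate the risk/ambiguity task trial set
#'
#' Builds the 54-trial monetary lottery task for one condition: 27 known-risk
#' trials (win probability stated) and 27 ambiguity trials (a fraction `A` of
#' the probability scale occluded, centered on 0.50). Every trial offers a
#' guaranteed $0.50 against a lottery paying `v` or $0. The printed design
#' crosses 8 lottery values with 3 probabilities and 3 ambiguity levels
#' (48 offers); the remaining 6 trials repeat one value level (by default the
#' $0.60 near-guaranteed anchor) once per probability and ambiguity level.
#' The loss condition is the exact sign mirror of the gain condition: all
#' values, including the guaranteed option, are negated.
#'
#' @param condition `"gain"` or `"loss"`.
#' @param seed Integer used only to shuffle trial order; the trial multiset is
#'   identical across seeds. `NULL` leaves the order unshuffled.
#' @param repeat_value Dollar value (positive, from the printed value set)
#'   repeated to fill the 54-trial count.
#' @return A data.frame of 54 rows with columns `condition`, `trial_index`,
#'   `guaranteed`, `v`, `p`, `A` (dollars; `A` is the occluded probability
#'   fraction, 0 on known-risk trials).
#' @examples
#' head(risk_trials("gain", seed = 1))
#' @export
risk_trials <- function(condition = c("gain", "loss"), seed = NULL,
                        repeat_value = 0.60) {
  condition <- match.arg(condition)
  rep_cents <- cents(repeat_value)
  if (!rep_cents %in% RISK_VALUES_CENTS) {
    stop("`repeat_value` must be one of the printed lottery values")
  }
  risk <- expand.grid(v_cents = RISK_VALUES_CENTS, p = RISK_PROBS, A = 0)
  risk <- rbind(risk, data.frame(v_cents = rep_cents, p = RISK_PROBS, A = 0))
  amb <- expand.grid(v_cents = RISK_VALUES_CENTS, p = AMBIGUITY_NOMINAL_P,
                     A = RISK_AMBIGUITY)
  amb <- rbind(amb, data.frame(v_cents = rep_cents, p = AMBIGUITY_NOMINAL_P,
                               A = RISK_AMBIGUITY))
  trials <- rbind(risk, amb)
  sgn <- if (condition == "gain") 1 else -1
  out <- data.frame(
    condition = condition,
    trial_index = seq_len(nrow(trials)),
    guaranteed = sgn * dollars(RISK_GUARANTEED_CENTS),
    v = sgn * dollars(trials$v_cents),
    p = trials$p,
    A = trials$A
  )
  if (!is.null(seed)) {
    ord <- with_seed(derive_seed(seed, "risk", condition),
                     sample.int(nrow(out)))
    out <- out[ord, ]
    out$trial_index <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  out
}

#' Generate the intertemporal choice task trial set
#'
#' Builds the 45-trial smaller-sooner vs. larger-later task: 3 immediate
#' amounts ($0.20, $0.50, $1.50) crossed with 5 delayed amounts each (the
#' printed grid) and 3 delays of one to three weeks. The delayed amount always
#' exceeds the immediate amount by at least $0.50. Because the sooner reward
#' was actually paid at the end of the current week, two delay conventions are
#' supported: `"immediate0"` codes the sooner option as 0 days with delays of
#' 7/14/21 days; `"immediate7"` codes it as 7 days with delays of 14/21/28.
#'
#' @param convention `"immediate0"` or `"immediate7"`.
#' @param seed Integer used only to shuffle trial order; `NULL` leaves the
#'   enumeration order.
#' @return A data.frame of 45 rows with columns `trial_index`, `v_immediate`,
#'   `v_delayed` (dollars) and `d_immediate`, `d_delayed` (days).
#' @examples
#' head(itc_trials("immediate0", seed = 1))
#' @export
itc_trials <- function(convention = c("immediate0", "immediate7"),
                       seed = NULL) {
  convention <- match.arg(convention)
  d0 <- if (convention == "immediate0") 0L else 7L
  rows <- do.call(rbind, lapply(names(ITC_GRID_CENTS), function(vi) {
    expand.grid(v_immediate_cents = as.integer(vi),
                v_delayed_cents = ITC_GRID_CENTS[[vi]],
                week = ITC_DELAYS_WEEKS)
  }))
  out <- data.frame(
    trial_index = seq_len(nrow(rows)),
    v_immediate = dollars(rows$v_immediate_cents),
    v_delayed = dollars(rows$v_delayed_cents),
    d_immediate = d0,
    d_delayed = d0 + 7L * rows$week
  )
  if (!is.null(seed)) {
    ord <- with_seed(derive_seed(seed, "itc", convention),
                     sample.int(nrow(out)))
    out <- out[ord, ]
    out$trial_index <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  out
}

#' Realize the daily bonus from one day's completed tasks
#'
#' Implements the incentive scheme: one completed task prompt is selected
#' uniformly at random, then one trial within it, and the choice made on that
#' trial determines the bonus, capped at $6.60. A gain trial pays $0.50 if the
#' guaranteed option was taken, otherwise the lottery is played at its win
#' probability (ambiguous lotteries resolve at the nominal 0.50). A loss trial
#' realizes the loss the same way and pays $6.60 minus the realized loss
#' magnitude. An intertemporal trial pays the chosen amount.
#'
#' @param day_choices A data.frame of one day's choice records: columns `task`
#'   (`"risk-gain"`, `"risk-loss"` or `"itc"`), `choice` (1 = lottery/delayed,
#'   0 = guaranteed/immediate) and the trial columns of [risk_trials()] /
#'   [itc_trials()].
#' @param seed Integer seed for task/trial selection and lottery resolution.
#' @return A one-row data.frame with `source_task`, `trial_index` and
#'   `realized_amount` (dollars in \[0, 6.60\]), or, for a day with no
#'   completed task, a zero-row frame (no bonus).
#' @export
realize_bonus <- function(day_choices, seed = NULL) {
  empty <- data.frame(source_task = character(), trial_index = integer(),
                      realized_amount = numeric())
  if (is.null(day_choices) || nrow(day_choices) == 0) {
    return(empty)
  }
  with_seed(seed, {
    tasks <- unique(day_choices$task)
    task <- tasks[sample.int(length(tasks), 1L)]
    rows <- day_choices[day_choices$task == task, , drop = FALSE]
    row <- rows[sample.int(nrow(rows), 1L), , drop = FALSE]
    amount <- if (task == "itc") {
      if (row$choice == 1) row$v_delayed else row$v_immediate
    } else {
      outcome <- if (row$choice == 1) {
        if (runif(1) < row$p) abs(row$v) else 0
      } else {
        abs(row$guaranteed)
      }
      if (task == "risk-gain") outcome else BONUS_CAP - outcome
    }
    data.frame(source_task = task, trial_index = row$trial_index,
               realized_amount = clamp(amount, 0, BONUS_CAP))
  })
}
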