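# Between- vs within-person variance decomposition of day-level parameters:
# ICC from unconditional random-intercept mixed models, week-level
# down-sampling, and day-wise correlation matrices.

# Map a day-fit table to the canonical (subject, day, value) series for one
# reported-scale parameter.
PARAM_SOURCE <- list(
  risk_tol_gain = list(task = "risk-gain", column = "risk_tol"),
  risk_tol_loss = list(task = "risk-loss", column = "risk_tol"),
  amb_tol_gain = list(task = "risk-gain", column = "amb_tol"),
  amb_tol_loss = list(task = "risk-loss", column = "amb_tol"),
  log_kappa = list(task = "itc", column = "log_kappa")
)

#' Extract a day-level parameter series from a day-fit table
#'
#' @param fits Day-fit table from [fit_days()].
#' @param parameter One of the five reported-scale parameters
#'   (`"risk_tol_gain"`, `"risk_tol_loss"`, `"amb_tol_gain"`,
#'   `"amb_tol_loss"`, `"log_kappa"`).
#' @param use_nonconverged Include day fits flagged non-converged (boundary
#'   or degenerate days). Excluded by default.
#' @return Data.frame with `subject_id`, `group`, `day`, `value`.
#' @export
parameter_series <- function(fits, parameter = names(PARAM_SOURCE),
                             use_nonconverged = FALSE) {
  parameter <- match.arg(parameter)
  src <- PARAM_SOURCE[[parameter]]
  rows <- fits[fits$task == src$task, , drop = FALSE]
  if (!use_nonconverged && "converged" %in% names(rows)) {
    rows <- rows[rows$converged, , drop = FALSE]
  }
  out <- data.frame(subject_id = rows$subject_id, group = rows$group,
                    day = rows$day, value = rows[[src$column]])
  out[!is.na(out$value), , drop = FALSE]
}

# Closed-form one-way random-effects ANOVA (moment) estimator of the
# variance components, with the standard unbalanced-design correction.
# Retained as the independent cross-check on the REML fit.
#' @rdname compute_icc
#' @param subject,value Vectors of subject labels and observed values.
#' @export
icc_anova <- function(subject, value) {
  subject <- as.character(subject)
  n_i <- tapply(value, subject, length)
  a <- length(n_i)
  n_tot <- sum(n_i)
  grand <- mean(value)
  means <- tapply(value, subject, mean)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((value - means[subject])^2)
  ms_between <- ss_between / (a - 1)
  ms_within <- ss_within / (n_tot - a)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (a - 1)
  sigma2_within <- ms_within
  sigma2_between <- max(0, (ms_between - ms_within) / n0)
  list(sigma2_between = sigma2_between, sigma2_within = sigma2_within,
       icc = sigma2_between / (sigma2_between + sigma2_within))
}

#' Intraclass correlation of a day-level parameter series
#'
#' Fits the unconditional random-intercept model `value ~ 1 + (1 | subject)`
#' by REML and returns the between-person and within-person (residual)
#' variance components and their intraclass correlation
#' `ICC = sigma2_between / (sigma2_between + sigma2_within)`. 1 - ICC is the
#' share of variation attributable to day-to-day (within-person) change.
#' Missing days are simply absent (censored).
#'
#' @param data Either a day-fit table (give `parameter`) or a series with
#'   columns `subject_id` and `value` (e.g. from [parameter_series()] or a
#'   down-sampling function).
#' @inheritParams parameter_series
#' @param grouping Restrict to `"patients"` or `"controls"` (requires a
#'   `group` column), or use `"all"` subjects.
#' @return A one-row data.frame of class `daypref_icc`: `parameter`,
#'   `grouping`, `sigma2_between`, `sigma2_within`, `icc`, `n_subjects`,
#'   `n_observations`, `singular`.
#' @export
compute_icc <- function(data, parameter = NULL,
                        grouping = c("all", "patients", "controls"),
                        use_nonconverged = FALSE) {
  grouping <- match.arg(grouping)
  series <- if (!is.null(parameter)) {
    parameter_series(data, parameter, use_nonconverged = use_nonconverged)
  } else {
    data
  }
  if (grouping != "all") {
    grp <- if (grouping == "patients") "patient" else "control"
    series <- series[series$group == grp, , drop = FALSE]
  }
  series <- series[!is.na(series$value), , drop = FALSE]
  n_per <- table(series$subject_id)
  n_per <- n_per[n_per > 0]
  if (length(n_per) < 2 || sum(n_per >= 2) < 2) {
    stop("ICC requires >= 2 subjects with >= 2 observations each")
  }
  fit <- tryCatch(
    lme4::lmer(value ~ 1 + (1 | subject_id), data = series, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate layouts (e.g. zero residual variance) break the REML fit;
    # the moment estimator still has a well-defined answer
    mom <- icc_anova(series$subject_id, series$value)
    s2_b <- mom$sigma2_between
    s2_w <- mom$sigma2_within
    singular <- s2_b == 0
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2_b <- vc$vcov[vc$grp == "subject_id"]
    s2_w <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit)
  }
  icc <- if (s2_b + s2_w == 0) 0 else s2_b / (s2_b + s2_w)
  out <- data.frame(
    parameter = if (is.null(parameter)) NA_character_ else parameter,
    grouping = grouping,
    sigma2_between = s2_b, sigma2_within = s2_w, icc = icc,
    n_subjects = length(n_per), n_observations = nrow(series),
    singular = singular
  )
  class(out) <- c("daypref_icc", class(out))
  out
}

#' ICC table for all five parameters
#'
#' @inheritParams compute_icc
#' @param fits Day-fit table from [fit_days()].
#' @return Row-bound [compute_icc()] results for every parameter.
#' @export
icc_table <- function(fits, grouping = "all", use_nonconverged = FALSE) {
  out <- do.call(rbind, lapply(names(PARAM_SOURCE), function(p) {
    compute_icc(fits, p, grouping = grouping,
                use_nonconverged = use_nonconverged)
  }))
  rownames(out) <- NULL
  out
}

week_of_day <- function(day) (as.integer(day) - 1L) %/% 7L + 1L

#' Down-sample a day series to weekly means
#'
#' Collapses the (up to) 28 daily values to 4 timepoints by averaging all
#' values a subject provided in each week (days 1-7, 8-14, 15-21, 22-28).
#' Weeks with no data are absent.
#'
#' @param series Data.frame with `subject_id`, `day`, `value` (and
#'   optionally `group`).
#' @return Data.frame with `subject_id`, (`group`,) `week`, `value`.
#' @export
downsample_week_mean <- function(series) {
  series$week <- week_of_day(series$day)
  keys <- c("subject_id", intersect("group", names(series)), "week")
  out <- aggregate(series["value"], series[keys], mean)
  out[order(out$subject_id, out$week), , drop = FALSE]
}

#' Down-sample a day series to one random day per week
#'
#' Selects one available day per week per subject such that consecutively
#' selected days are at least `min_gap` days apart, emulating sparse
#' lab-style sampling. Selection is uniform over the eligible day
#' combinations (rejection resampling); weeks that cannot satisfy the
#' constraint for a subject are dropped for that subject. With
#' `rule = "allpairs"` the gap constraint applies to every pair of selected
#' days instead of consecutive ones.
#'
#' @inheritParams downsample_week_mean
#' @param seed Integer seed making the selection reproducible.
#' @param min_gap Minimum spacing in days (default 4).
#' @param rule `"consecutive"` (default) or `"allpairs"`.
#' @param max_tries Rejection-sampling budget before falling back to a
#'   greedy sequential selection.
#' @return Data.frame with `subject_id`, (`group`,) `week`, `day`, `value`.
#' @export
downsample_random_days <- function(series, seed = 1, min_gap = 4,
                                   rule = c("consecutive", "allpairs"),
                                   max_tries = 1000) {
  rule <- match.arg(rule)
  series$week <- week_of_day(series$day)
  parts <- split(series, series$subject_id)
  gaps_ok <- function(days) {
    d <- sort(days)
    if (rule == "consecutive") all(diff(d) >= min_gap)
    else all(outer(d, d, function(a, b) abs(a - b))[lower.tri(diag(length(d)))] >= min_gap)
  }
  out <- with_seed(derive_seed(seed, "downsample"), {
    lapply(parts, function(part) {
      weeks <- split(part, part$week)
      if (length(weeks) == 0) return(NULL)
      pick <- NULL
      for (i in seq_len(max_tries)) {
        cand <- vapply(weeks, function(w) {
          w$day[sample.int(nrow(w), 1L)]
        }, numeric(1))
        if (gaps_ok(cand)) {
          pick <- cand
          break
        }
      }
      if (is.null(pick)) {
        # greedy fallback: walk the weeks, keep days satisfying the gap,
        # drop weeks with no eligible day
        pick <- numeric(0)
        for (w in weeks) {
          ok <- if (length(pick) == 0) w$day else
            w$day[vapply(w$day, function(d) gaps_ok(c(pick, d)), logical(1))]
          if (length(ok)) pick <- c(pick, ok[sample.int(length(ok), 1L)])
        }
        if (length(pick) == 0) return(NULL)
      }
      rows <- part[part$day %in% pick, , drop = FALSE]
      rows[order(rows$day), , drop = FALSE]
    })
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Day-wise correlation structure of the task parameters
#'
#' Computes (i) between-parameter correlations across subjects separately for
#' each study day, and (ii) within-parameter test-retest correlations across
#' subjects for every pair of days, with pairwise-complete handling of
#' missing days. Summaries give the mean and SD of each parameter pair's
#' day-wise correlations.
#'
#' @param fits Day-fit table from [fit_days()].
#' @param min_n Minimum number of complete subject pairs for a correlation
#'   to be computed (default 5).
#' @inheritParams parameter_series
#' @return A list of class `daypref_cormat`: `between` (long data.frame:
#'   `day`, `param1`, `param2`, `r`, `n`), `retest` (`parameter`, `day1`,
#'   `day2`, `r`, `n`), and `summary` (per pair mean/SD).
#' @export
correlation_matrices <- function(fits, min_n = 5, use_nonconverged = FALSE) {
  params <- names(PARAM_SOURCE)
  wide <- NULL
  for (p in params) {
    s <- parameter_series(fits, p, use_nonconverged = use_nonconverged)
    s <- s[, c("subject_id", "day", "value")]
    names(s)[3] <- p
    wide <- if (is.null(wide)) s else
      merge(wide, s, by = c("subject_id", "day"), all = TRUE)
  }
  pairs <- utils::combn(params, 2)
  between <- do.call(rbind, lapply(sort(unique(wide$day)), function(d) {
    slice <- wide[wide$day == d, , drop = FALSE]
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      x <- slice[[pairs[1, j]]]
      y <- slice[[pairs[2, j]]]
      ok <- complete.cases(x, y)
      if (sum(ok) < min_n) return(NULL)
      data.frame(day = d, param1 = pairs[1, j], param2 = pairs[2, j],
                 r = cor(x[ok], y[ok]), n = sum(ok))
    }))
  }))
  days <- sort(unique(wide$day))
  retest <- do.call(rbind, lapply(params, function(p) {
    mat <- reshape_days(wide, p, days)
    do.call(rbind, lapply(seq_along(days), function(i) {
      if (i == length(days)) return(NULL)
      do.call(rbind, lapply(seq(i + 1, length(days)), function(j) {
        ok <- complete.cases(mat[, i], mat[, j])
        if (sum(ok) < min_n) return(NULL)
        data.frame(parameter = p, day1 = days[i], day2 = days[j],
                   r = cor(mat[ok, i], mat[ok, j]), n = sum(ok))
      }))
    }))
  }))
  summary <- rbind(
    if (!is.null(between))
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        r <- between$r[between$param1 == pairs[1, j] &
                         between$param2 == pairs[2, j]]
        if (!length(r)) return(NULL)
        data.frame(type = "between", param1 = pairs[1, j],
                   param2 = pairs[2, j], mean_r = mean(r), sd_r = sd(r),
                   n_cells = length(r))
      })),
    if (!is.null(retest))
      do.call(rbind, lapply(params, function(p) {
        r <- retest$r[retest$parameter == p]
        if (!length(r)) return(NULL)
        data.frame(type = "retest", param1 = p, param2 = p,
                   mean_r = mean(r), sd_r = sd(r), n_cells = length(r))
      }))
  )
  structure(list(between = between, retest = retest, summary = summary),
            class = "daypref_cormat")
}

reshape_days <- function(wide, parameter, days) {
  subjects <- sort(unique(wide$subject_id))
  mat <- matrix(NA_real_, nrow = length(subjects), ncol = length(days),
                dimnames = list(subjects, days))
  mat[cbind(match(wide$subject_id, subjects), match(wide$day, days))] <-
    wide[[parameter]]
  mat
}

#' @export
print.daypref_cormat <- function(x, ...) {
  cat("Day-wise parameter correlations\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
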