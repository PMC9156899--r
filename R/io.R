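# CSV readers/writers for the table schemas, with row-level validation.
# Dialect: UTF-8, comma-separated, header row, dot decimal; money is written
# in dollars with two decimals (exact in cents internally).

money_cols <- c("guaranteed", "v", "v_immediate", "v_delayed",
                "realized_amount")

format_money <- function(df) {
  for (col in intersect(money_cols, names(df))) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA,
                        sprintf("%.2f", df[[col]]))
  }
  df
}

#' Read and validate a choice-record table
#'
#' Expects the long trial-level schema: `subject_id`, `group`, `day`, `task`,
#' `condition`, `trial_index`, `guaranteed`, `v`, `p`, `A`, `v_immediate`,
#' `v_delayed`, `d_immediate`, `d_delayed`, `choice`. Schema violations
#' (missing columns, probabilities outside \[0, 1\], non-binary choices) are
#' reported with the offending row numbers. An empty file yields an empty
#' table with a warning.
#'
#' @param path CSV file path.
#' @return Validated data.frame of choice records.
#' @export
read_choices <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty choice file: ", path)
    return(df)
  }
  required <- c("subject_id", "day", "task", "choice")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  problems <- character(0)
  bad_choice <- which(!df$choice %in% 0:1)
  if (length(bad_choice)) {
    problems <- c(problems, paste0("non-binary choice in rows: ",
                                   paste(head(bad_choice, 10),
                                         collapse = ", ")))
  }
  if ("p" %in% names(df)) {
    bad_p <- which(!is.na(df$p) & (df$p < 0 | df$p > 1))
    if (length(bad_p)) {
      problems <- c(problems, paste0("probability outside [0,1] in rows: ",
                                     paste(head(bad_p, 10), collapse = ", ")))
    }
  }
  if ("A" %in% names(df)) {
    bad_a <- which(!is.na(df$A) & (df$A < 0 | df$A > 1))
    if (length(bad_a)) {
      problems <- c(problems, paste0("ambiguity outside [0,1] in rows: ",
                                     paste(head(bad_a, 10), collapse = ", ")))
    }
  }
  bad_task <- which(!df$task %in% c("risk-gain", "risk-loss", "itc"))
  if (length(bad_task)) {
    problems <- c(problems, paste0("unknown task in rows: ",
                                   paste(head(bad_task, 10), collapse = ", ")))
  }
  if (length(problems)) {
    stop("choice file validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  df
}

#' @rdname read_choices
#' @param choices Choice-record data.frame to write.
#' @export
write_choices <- function(choices, path) {
  write.csv(format_money(choices), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a momentary-ratings table
#'
#' Schema: `subject_id`, `group`, `day`, `prompt_index`, `positive`,
#' `negative` with ratings in \[0, 100\].
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty ratings file: ", path)
    return(df)
  }
  required <- c("subject_id", "day", "positive", "negative")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("positive", "negative")) {
    bad <- which(df[[col]] < 0 | df[[col]] > 100)
    if (length(bad)) {
      stop(sprintf("%s rating outside [0,100] in rows: %s", col,
                   paste(head(bad, 10), collapse = ", ")))
    }
  }
  df
}

#' @rdname read_ratings
#' @param ratings Ratings data.frame to write.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write a day-fit table
#'
#' One row per subject-day-task with the estimates, reported transforms and
#' fit diagnostics produced by [fit_days()].
#'
#' @param path CSV file path.
#' @return Data.frame of day fits.
#' @export
read_fits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("converged" %in% names(df)) df$converged <- as.logical(df$converged)
  df
}

#' @rdname read_fits
#' @param fits Day-fit data.frame to write.
#' @export
write_fits <- function(fits, path) {
  write.csv(fits, path, row.names = FALSE, na = "")
  invisible(path)
}
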