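# Weekly program-goal evaluation, cohort event rates and process-evaluation
# indicators.
#
# The program goal: all three daily subobjectives met on at least 30% of the
# wearing days within an ISO calendar week (Monday-Sunday, weekends
# included). The proportion of participants meeting the goal is the event
# rate; at baseline it is the control event rate (CER) that enters the
# number-needed-to-treat computation in the trial-design module.

#' Evaluate the weekly program goal for one participant-week
#'
#' Only valid wearing days count as "wearing days". The goal is met when the
#' fraction of those days with all three subobjectives achieved is at least
#' `goal_proportion` (inclusive). A week with fewer than `min_valid_days`
#' valid days is not evaluable and its `goal_met` is `NA`, never silently
#' `FALSE`.
#'
#' Day-level flags are taken from the summaries as computed by
#' [summarize_day()]; only `goal_proportion` is read from `thresholds` here.
#'
#' @param days day-summary rows for one participant and one ISO week.
#' @param thresholds a [thresholds()] object.
#' @param min_valid_days minimum valid wearing days for the week to be
#'   evaluable (at least 1).
#' @return a one-row tibble: `participant_id`, `week_id`, `n_valid_days`,
#'   `n_all_ok`, `proportion`, `goal_met`, `evaluable`.
#' @export
evaluate_week <- function(days, thresholds = sitpattern::thresholds(),
                          min_valid_days = 1L) {
  stopifnot(
    inherits(thresholds, "sit_thresholds"),
    is.numeric(min_valid_days), min_valid_days >= 1L
  )
  if (nrow(days) == 0L) {
    stop("evaluate_week() needs at least one day-summary row", call. = FALSE)
  }
  pid <- unique(days$participant_id)
  wk <- unique(iso_week(days$date))
  if (length(pid) != 1L || length(wk) != 1L) {
    stop("days must belong to one participant and one ISO week", call. = FALSE)
  }
  n_valid <- sum(days$valid_wear)
  n_ok <- sum(days$all_ok & days$valid_wear)
  evaluable <- n_valid >= min_valid_days
  proportion <- if (n_valid > 0L) n_ok / n_valid else NA_real_
  tibble::tibble(
    participant_id = pid,
    week_id = wk,
    n_valid_days = n_valid,
    n_all_ok = n_ok,
    proportion = proportion,
    goal_met = if (evaluable) proportion >= thresholds$goal_proportion else NA,
    evaluable = evaluable
  )
}

#' Evaluate the program goal for every participant-week
#'
#' @param summaries a day-summary tibble covering one or more participants.
#' @inheritParams evaluate_week
#' @return a tibble with one [evaluate_week()] row per participant-week.
#' @export
evaluate_weeks <- function(summaries, thresholds = sitpattern::thresholds(),
                           min_valid_days = 1L) {
  key <- paste(summaries$participant_id, iso_week(summaries$date))
  split(summaries, key) |>
    purrr::map(evaluate_week,
      thresholds = thresholds,
      min_valid_days = min_valid_days
    ) |>
    dplyr::bind_rows() |>
    dplyr::arrange(participant_id, week_id)
}

#' Cohort event rate
#'
#' Aggregates weekly goal results to a participant-level event: the fraction
#' of participants who meet the program goal over their evaluable weeks.
#' The aggregation rule over a multi-week window is configurable:
#' \describe{
#'   \item{`all-weeks`}{(default) the goal is met in every evaluable week —
#'     conservative and explicit;}
#'   \item{`any-week`}{met in at least one evaluable week;}
#'   \item{`majority`}{met in more than half of the evaluable weeks.}
#' }
#' Participants without any evaluable week are excluded from the
#' denominator.
#'
#' @param week_results a tibble from [evaluate_weeks()].
#' @param rule participant-level aggregation rule.
#' @return a one-row tibble: `n_participants`, `n_goal_met`, `event_rate`.
#' @export
event_rate <- function(week_results,
                       rule = c("all-weeks", "any-week", "majority")) {
  rule <- match.arg(rule)
  ev <- week_results[week_results$evaluable, ]
  if (nrow(ev) == 0L) {
    stop("no participant has an evaluable week", call. = FALSE)
  }
  agg <- switch(rule,
    "all-weeks" = function(x) all(x),
    "any-week" = function(x) any(x),
    "majority" = function(x) mean(x) > 0.5
  )
  met <- vapply(split(ev$goal_met, ev$participant_id), agg, logical(1))
  tibble::tibble(
    n_participants = length(met),
    n_goal_met = sum(met),
    event_rate = sum(met) / length(met)
  )
}

#' Mean subobjective attainment
#'
#' For each subobjective (and their conjunction), the proportion of valid
#' wearing days on which it was met, computed per participant and averaged
#' across participants, together with the equivalent mean days per week
#' (flag days per observed ISO week, averaged across participants).
#'
#' @param summaries a day-summary tibble.
#' @return a tibble with one row per objective (`sit`, `active`, `sssb`,
#'   `all`): `attainment` and `mean_days_per_week`.
#' @export
mean_subobjective_attainment <- function(summaries) {
  valid <- summaries[summaries$valid_wear, ]
  if (nrow(valid) == 0L) {
    stop("no valid wearing days", call. = FALSE)
  }
  flags <- c(sit = "sit_ok", active = "active_ok", sssb = "sssb_ok", all = "all_ok")
  by_pid <- split(valid, valid$participant_id)
  purrr::imap(flags, function(col, nm) {
    att <- vapply(by_pid, function(d) mean(d[[col]]), numeric(1))
    dpw <- vapply(
      by_pid,
      function(d) sum(d[[col]]) / length(unique(iso_week(d$date))),
      numeric(1)
    )
    tibble::tibble(
      objective = nm,
      attainment = mean(att),
      mean_days_per_week = mean(dpw)
    )
  }) |>
    dplyr::bind_rows()
}

#' Intervention fidelity ratio
#'
#' Messages drawn from the automated pool divided by the total number of
#' messages sent by the coach.
#'
#' @param n_automated count of automated-pool messages.
#' @param n_total total messages sent; must be at least `n_automated` and
#'   positive.
#' @return a fraction in \[0, 1\].
#' @export
fidelity_ratio <- function(n_automated, n_total) {
  stopifnot(
    is.numeric(n_automated), is.numeric(n_total),
    length(n_automated) == 1L, length(n_total) == 1L,
    n_automated >= 0, n_total >= n_automated
  )
  if (n_total == 0) {
    stop("n_total must be positive", call. = FALSE)
  }
  n_automated / n_total
}

#' Wear adherence
#'
#' Mean number of valid wearing days (at least the minimum wear time of
#' data) per ISO week per participant, and the same as a fraction of 7.
#' Participant-weeks present in the summaries but without any valid day
#' count as zero-adherence weeks.
#'
#' @param summaries a day-summary tibble spanning at least one week.
#' @return a one-row tibble: `days_per_week`, `fraction`.
#' @export
wear_adherence <- function(summaries) {
  stopifnot(nrow(summaries) > 0L)
  key <- paste(summaries$participant_id, iso_week(summaries$date))
  per_week <- vapply(
    split(summaries$valid_wear, key), sum, numeric(1)
  )
  dpw <- mean(per_week)
  tibble::tibble(days_per_week = dpw, fraction = dpw / 7)
}

#' Assemble process-evaluation indicators
#'
#' Bundles the process metrics tracked alongside the effect evaluation:
#' coaching fidelity, device-registration adherence, dropout and dose
#' received.
#'
#' @param fidelity fraction from [fidelity_ratio()].
#' @param summaries day summaries used for the wear-adherence indicator.
#' @param n_enrolled participants enrolled.
#' @param n_dropped_out participants lost.
#' @param dose_received fraction of the intervention dose received.
#' @return a one-row tibble with `fidelity`, `mean_valid_days_per_week`,
#'   `dropout_rate`, `dose_received`.
#' @export
process_metrics <- function(fidelity, summaries, n_enrolled, n_dropped_out,
                            dose_received) {
  stopifnot(
    fidelity >= 0, fidelity <= 1,
    n_enrolled > 0, n_dropped_out >= 0, n_dropped_out <= n_enrolled,
    dose_received >= 0, dose_received <= 1
  )
  tibble::tibble(
    fidelity = fidelity,
    mean_valid_days_per_week = wear_adherence(summaries)$days_per_week,
    dropout_rate = n_dropped_out / n_enrolled,
    dose_received = dose_received
  )
}
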