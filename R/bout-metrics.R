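# Bout extraction, the SSSB statistic, day summaries and bout-duration
# profiles.
#
# A bout is a maximal uninterrupted run of one posture state, measured in
# minutes at 0.5-min resolution. The summed squared sitting bouts (SSSB)
# statistic of a day squares the length of every sitting bout and sums the
# squares (units min^2): it penalizes long uninterrupted sitting while being
# insensitive to the same total time accumulated in short bouts.

#' Subobjective and goal thresholds
#'
#' Bundles the configurable thresholds used throughout the day- and
#' week-level evaluation. Defaults encode the program's recommendations:
#' daily sitting strictly below 8 h, standing plus light activity at least
#' 4 h, SSSB strictly below 18.8e3 min^2, a wearing day requires at least
#' 6 h of data, and the weekly goal is all three subobjectives met on at
#' least 30% of wearing days.
#'
#' `sit_max` and `sssb_cutoff` may be `Inf` and `active_min` may be 0, which
#' disables the corresponding subobjective (useful for sensitivity checks).
#'
#' @param sit_max maximum daily sitting, minutes (exclusive bound).
#' @param active_min minimum daily standing + light activity, minutes
#'   (inclusive bound).
#' @param sssb_cutoff SSSB healthy-pattern cutoff, min^2 (exclusive bound).
#' @param min_wear minimum wear time of a valid wearing day, minutes.
#' @param goal_proportion fraction of wearing days per week on which all
#'   three subobjectives must be met (inclusive bound), in (0, 1].
#' @return a list of class `sit_thresholds`.
#' @export
#' @examples
#' thresholds()
#' thresholds(sssb_cutoff = 15000)
thresholds <- function(sit_max = 480, active_min = 240, sssb_cutoff = 18800,
                       min_wear = 360, goal_proportion = 0.30) {
  stopifnot(
    is.numeric(sit_max), length(sit_max) == 1L, sit_max > 0,
    is.numeric(active_min), length(active_min) == 1L, active_min >= 0,
    is.numeric(sssb_cutoff), length(sssb_cutoff) == 1L, sssb_cutoff > 0,
    is.numeric(min_wear), length(min_wear) == 1L, min_wear > 0,
    is.finite(min_wear),
    is.numeric(goal_proportion), length(goal_proportion) == 1L,
    goal_proportion > 0, goal_proportion <= 1
  )
  structure(
    list(
      sit_max = sit_max, active_min = active_min,
      sssb_cutoff = sssb_cutoff, min_wear = min_wear,
      goal_proportion = goal_proportion
    ),
    class = "sit_thresholds"
  )
}

#' Read thresholds from a YAML file
#'
#' The file may set any subset of the five [thresholds()] fields; unset
#' fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a `sit_thresholds` list.
#' @export
thresholds_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(thresholds)))
  if (length(unknown) > 0L) {
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(thresholds, cfg)
}

#' Extract posture bouts from one day
#'
#' Run-length encodes the day's epoch states into maximal runs. `NON_WEAR`
#' epochs terminate the current bout and are excluded from the result; runs
#' are already cut at midnight by day segmentation. The durations of one
#' state's bouts sum exactly to that state's minutes from epoch counts.
#'
#' @param day a day tibble from [split_into_days()].
#' @return a tibble with columns `state` (factor), `start` (`POSIXct`) and
#'   `duration_min` (positive multiples of 0.5).
#' @export
extract_bouts <- function(day) {
  stopifnot(nrow(day) > 0L)
  r <- rle(as.character(day$state))
  start_idx <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values != "NON_WEAR"
  tibble::tibble(
    state = posture_factor(r$values[keep]),
    start = day$timestamp[start_idx[keep]],
    duration_min = r$lengths[keep] * EPOCH_MIN
  )
}

#' Summed squared sitting bouts (SSSB)
#'
#' `sum(durations^2)` in min^2; the empty sequence gives 0. Splitting any
#' bout into two pieces strictly lowers the value ((a+b)^2 > a^2 + b^2), so
#' for a fixed daily sitting total T the statistic ranges from T^2/k (k equal
#' bouts) up to T^2 (one uninterrupted bout).
#'
#' @param durations sitting-bout durations in minutes; all strictly positive.
#' @return SSSB in min^2.
#' @export
#' @examples
#' compute_sssb(c(30, 45, 10))
#' compute_sssb(numeric(0))
compute_sssb <- function(durations) {
  if (length(durations) == 0L) {
    return(0)
  }
  if (!is.numeric(durations) || anyNA(durations) || any(durations <= 0)) {
    stop("bout durations must be strictly positive numbers", call. = FALSE)
  }
  sum(durations^2)
}

#' Summarize one day of posture data
#'
#' Computes wear and per-state minutes from epoch counts, the sitting bouts
#' and their SSSB, and the three daily subobjective flags:
#' \itemize{
#'   \item `sit_ok`: sitting minutes strictly below `sit_max`;
#'   \item `active_ok`: standing + light-activity minutes at least
#'     `active_min`;
#'   \item `sssb_ok`: SSSB strictly below `sssb_cutoff` (a "healthy sitting
#'     pattern" day).
#' }
#' `all_ok` is their conjunction. Flags are only interpretable on days with
#' `valid_wear = TRUE`; they are computed regardless so that threshold
#' sensitivity can be explored.
#'
#' @param day a day tibble.
#' @param thresholds a [thresholds()] object.
#' @return a one-row tibble (`participant_id`, `date`, `wear_min`,
#'   `sit_min`, `stand_min`, `light_min`, `sitting_bouts` list-column,
#'   `sssb`, `sit_ok`, `active_ok`, `sssb_ok`, `all_ok`, `valid_wear`).
#' @export
summarize_day <- function(day, thresholds = sitpattern::thresholds()) {
  stopifnot(inherits(thresholds, "sit_thresholds"), nrow(day) > 0L)
  dates <- unique(as.Date(day$timestamp, tz = "UTC"))
  pid <- unique(day$participant_id)
  if (length(dates) != 1L || length(pid) != 1L) {
    stop("a day summary needs epochs from exactly one participant-date",
      call. = FALSE
    )
  }
  n <- table(day$state)
  sit_min <- EPOCH_MIN * n[["SITTING"]]
  stand_min <- EPOCH_MIN * n[["STANDING"]]
  light_min <- EPOCH_MIN * n[["LIGHT_ACTIVITY"]]
  wear_min <- sit_min + stand_min + light_min

  bouts <- extract_bouts(day)
  sit_bouts <- bouts$duration_min[bouts$state == "SITTING"]
  sssb <- compute_sssb(sit_bouts)

  sit_ok <- sit_min < thresholds$sit_max
  active_ok <- (stand_min + light_min) >= thresholds$active_min
  sssb_ok <- sssb < thresholds$sssb_cutoff

  tibble::tibble(
    participant_id = pid,
    date = dates,
    wear_min = wear_min,
    sit_min = sit_min,
    stand_min = stand_min,
    light_min = light_min,
    sitting_bouts = list(sit_bouts),
    sssb = sssb,
    sit_ok = sit_ok,
    active_ok = active_ok,
    sssb_ok = sssb_ok,
    all_ok = sit_ok && active_ok && sssb_ok,
    valid_wear = wear_min >= thresholds$min_wear
  )
}

#' Summarize every day of a stream (or several streams)
#'
#' @param stream an epoch stream, or a list of them (e.g. one per
#'   participant).
#' @param thresholds a [thresholds()] object.
#' @return a tibble with one [summarize_day()] row per participant-day.
#' @export
summarize_days <- function(stream, thresholds = sitpattern::thresholds()) {
  streams <- if (is.data.frame(stream)) list(stream) else stream
  purrr::map(streams, function(s) {
    purrr::map(split_into_days(s), summarize_day, thresholds = thresholds) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}

#' Median-based SSSB cutoff
#'
#' The healthy/unhealthy cutoff is the median SSSB pooled across all valid
#' person-days (not per participant). With an even number of days the
#' midpoint of the two central order statistics is used.
#'
#' @param summaries a day-summary tibble from [summarize_days()].
#' @return the cutoff in min^2.
#' @export
derive_cutoff <- function(summaries) {
  v <- summaries$sssb[summaries$valid_wear]
  if (length(v) == 0L) {
    stop("no valid wearing days; cannot derive a cutoff", call. = FALSE)
  }
  stats::median(v)
}

#' Bout-duration profile by SSSB stratum
#'
#' For each valid day, every sitting bout contributes its full duration to
#' the bin containing that duration; per-bin totals are then averaged over
#' the days of each stratum (days without any bout in a bin contribute 0).
#' Days are stratified into `healthy` (`sssb_ok`) and `unhealthy` by their
#' SSSB class. Because every bout lands in exactly one bin, the per-stratum
#' bin values sum exactly to that stratum's mean daily sitting time — the
#' area under the profile is the average total daily sitting time.
#'
#' @param summaries a day-summary tibble.
#' @param bin_edges strictly increasing lower bin edges in minutes, starting
#'   at 0; the last bin is unbounded above. Defaults to
#'   `c(0, 10, 20, 30, 45, 60, 90)`.
#' @return a tibble of class `bout_profile` with columns `stratum`,
#'   `bin_lo`, `bin_hi`, `bin` (label) and `mean_min`. An empty stratum is
#'   omitted with a warning.
#' @export
bout_duration_profile <- function(summaries,
                                  bin_edges = c(0, 10, 20, 30, 45, 60, 90)) {
  stopifnot(
    is.numeric(bin_edges), length(bin_edges) >= 1L,
    bin_edges[1] == 0, !is.unsorted(bin_edges, strictly = TRUE)
  )
  valid <- summaries[summaries$valid_wear, ]
  if (nrow(valid) == 0L) {
    stop("no valid wearing days", call. = FALSE)
  }
  edges <- c(bin_edges, Inf)
  n_bins <- length(bin_edges)
  labels <- sprintf(
    "[%g,%s)", bin_edges,
    c(as.character(bin_edges[-1]), "Inf")
  )

  day_bins <- function(durs) {
    out <- numeric(n_bins)
    if (length(durs) > 0L) {
      idx <- findInterval(durs, edges)
      out <- vapply(
        seq_len(n_bins),
        function(b) sum(durs[idx == b]), numeric(1)
      )
    }
    out
  }

  strata <- list(healthy = valid$sssb_ok, unhealthy = !valid$sssb_ok)
  rows <- purrr::imap(strata, function(in_stratum, nm) {
    if (!any(in_stratum)) {
      warning("no valid days in stratum '", nm, "'; stratum omitted",
        call. = FALSE
      )
      return(NULL)
    }
    per_day <- vapply(
      valid$sitting_bouts[in_stratum], day_bins, numeric(n_bins)
    )
    per_day <- matrix(per_day, nrow = n_bins) # vapply drops dim when n_bins=1
    tibble::tibble(
      stratum = nm,
      bin_lo = bin_edges,
      bin_hi = edges[-1],
      bin = labels,
      mean_min = rowMeans(per_day)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bout_profile", class(out))
  out
}

#' Plot a bout-duration profile
#'
#' Grouped bar chart of mean daily sitting minutes per bout-duration bin,
#' one bar colour per SSSB stratum. Requires ggplot2.
#'
#' @param profile a `bout_profile` from [bout_duration_profile()].
#' @return a ggplot object.
#' @export
plot_bout_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bout_profile() requires the ggplot2 package", call. = FALSE)
  }
  profile$bin <- factor(profile$bin, levels = unique(profile$bin))
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = bin, y = mean_min, fill = stratum)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "sitting-bout duration bin (min)",
      y = "mean daily sitting minutes",
      fill = "SSSB stratum"
    ) +
    ggplot2::theme_minimal()
}
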