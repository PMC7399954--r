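# Seeded semi-Markov generator of synthetic posture-epoch streams.
#
# A day is an alternating-renewal (semi-Markov) chain over the three wear
# states: the embedded chain has no self-transitions, and each visit to a
# state dwells for a random duration drawn from that state's bout-duration
# distribution, discretized to 30-s epochs (rounding half-up, minimum one
# epoch). Epochs outside the daily wear window, and entire non-wear days,
# are NON_WEAR. Lognormal dwell times are the default family: their heavy
# right tail produces the occasional very long sitting bout that separates
# unhealthy from healthy sitting patterns.

#' Bout-duration (dwell-time) distribution
#'
#' @param family one of `"lognormal"` (parameters `meanlog`, `sdlog`, on the
#'   log-minute scale), `"gamma"` (`shape`, `rate`, rate per minute) or
#'   `"fixed"` (`minutes`).
#' @param meanlog,sdlog lognormal parameters.
#' @param shape,rate gamma parameters.
#' @param minutes fixed duration in minutes.
#' @return a list of class `dwell_spec`.
#' @export
#' @examples
#' dwell("lognormal", meanlog = log(12), sdlog = 0.7)
#' dwell("fixed", minutes = 30)
dwell <- function(family = c("lognormal", "gamma", "fixed"),
                  meanlog = NULL, sdlog = NULL,
                  shape = NULL, rate = NULL, minutes = NULL) {
  family <- match.arg(family)
  params <- switch(family,
    lognormal = {
      stopifnot(is.numeric(meanlog), is.numeric(sdlog), sdlog >= 0)
      list(meanlog = meanlog, sdlog = sdlog)
    },
    gamma = {
      stopifnot(is.numeric(shape), shape > 0, is.numeric(rate), rate > 0)
      list(shape = shape, rate = rate)
    },
    fixed = {
      stopifnot(is.numeric(minutes), minutes > 0)
      list(minutes = minutes)
    }
  )
  structure(c(list(family = family), params), class = "dwell_spec")
}

dwell_mean <- function(d) {
  switch(d$family,
    lognormal = exp(d$meanlog + d$sdlog^2 / 2),
    gamma = d$shape / d$rate,
    fixed = d$minutes
  )
}

draw_dwell <- function(d, n) {
  switch(d$family,
    lognormal = rlnorm(n, d$meanlog, d$sdlog),
    gamma = rgamma(n, shape = d$shape, rate = d$rate),
    fixed = rep(d$minutes, n)
  )
}

# E[D * 1{D > t}] for a dwell distribution, by numeric integration
dwell_partial_mean <- function(d, t) {
  if (d$family == "fixed") {
    return(if (d$minutes > t) d$minutes else 0)
  }
  dens <- switch(d$family,
    lognormal = function(x) dlnorm(x, d$meanlog, d$sdlog),
    gamma = function(x) dgamma(x, shape = d$shape, rate = d$rate)
  )
  integrate(function(x) x * dens(x), lower = t, upper = Inf,
    rel.tol = 1e-9
  )$value
}

parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-2][0-9]):([0-5][0-9])$", x))[[1]]
  if (length(m) != 3L) stop("wear window times must be 'HH:MM'", call. = FALSE)
  as.integer(m[2]) * 60 + as.integer(m[3])
}

#' Synthetic participant profile
#'
#' Describes how one participant's posture days are generated: per-state
#' bout-duration distributions, the embedded transition matrix over the
#' three wear states, the daily wear window, and how many days per week the
#' monitor is worn (worn days are chosen at random within each week).
#'
#' @param sitting,standing,light [dwell()] specs (minutes).
#' @param transition 3x3 row-stochastic matrix over (SITTING, STANDING,
#'   LIGHT_ACTIVITY) with zero diagonal.
#' @param wear_start,wear_end daily wear window, `"HH:MM"`; the window must
#'   lie within one day and cover at least one epoch.
#' @param wear_days_per_week integer in 1..7.
#' @param label `"healthy"`, `"unhealthy"` or `"custom"`.
#' @return a list of class `sit_profile`.
#' @seealso [preset_profile()] for the calibrated presets.
#' @export
synthetic_profile <- function(sitting, standing, light,
                              transition = default_transition(),
                              wear_start = "08:00", wear_end = "22:00",
                              wear_days_per_week = 5L,
                              label = "custom") {
  stopifnot(
    inherits(sitting, "dwell_spec"), inherits(standing, "dwell_spec"),
    inherits(light, "dwell_spec"),
    is.matrix(transition), all(dim(transition) == c(3L, 3L)),
    all(diag(transition) == 0),
    all(abs(rowSums(transition) - 1) < 1e-9),
    all(transition >= 0),
    wear_days_per_week >= 1L, wear_days_per_week <= 7L
  )
  ws <- parse_clock(wear_start)
  we <- parse_clock(wear_end)
  if (!(ws < we && we <= 1440)) {
    stop("wear window must lie within one day (start < end <= 24:00)",
      call. = FALSE
    )
  }
  if ((we - ws) < EPOCH_MIN) {
    stop("wear window shorter than one epoch", call. = FALSE)
  }
  stopifnot(
    dwell_mean(sitting) > 0, dwell_mean(standing) > 0, dwell_mean(light) > 0
  )
  label <- match.arg(label, c("healthy", "unhealthy", "custom"))
  structure(
    list(
      dwell = list(
        SITTING = sitting, STANDING = standing, LIGHT_ACTIVITY = light
      ),
      transition = transition,
      wear_start_min = ws, wear_end_min = we,
      wear_days_per_week = as.integer(wear_days_per_week),
      label = label
    ),
    class = "sit_profile"
  )
}

#' Default embedded transition matrix
#'
#' From sitting, stand up more often than start moving; from standing or
#' light activity, most transitions return to sitting — the usual desk-work
#' alternation.
#'
#' @return a 3x3 row-stochastic matrix with zero diagonal.
#' @export
default_transition <- function() {
  matrix(
    c(
      0.00, 0.60, 0.40,
      0.75, 0.00, 0.25,
      0.75, 0.25, 0.00
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(WEAR_STATES, WEAR_STATES)
  )
}

#' Calibrated healthy / unhealthy sitting-pattern presets
#'
#' Both presets share the transition structure, a 08:00-22:00 wear window
#' and 5 worn days per week, and are calibrated to identical expected daily
#' sitting time (analytic semi-Markov sitting occupancy 0.565 of the window
#' for both, i.e. about 475 min/day, so days straddle the 480-min
#' subobjective). They differ in where that time accumulates: the healthy
#' preset sits in short bouts (lognormal, median 12 min), the unhealthy
#' preset in long heavy-tailed bouts (median 25 min, sdlog 0.9), so minutes
#' collected in bouts over 90 min differ by more than an order of magnitude
#' (about 7 vs about 140 expected min/day).
#'
#' @param name `"healthy"` or `"unhealthy"`.
#' @return a `sit_profile`.
#' @export
preset_profile <- function(name = c("healthy", "unhealthy")) {
  name <- match.arg(name)
  if (name == "healthy") {
    synthetic_profile(
      sitting = dwell("lognormal", meanlog = log(12), sdlog = 0.7),
      standing = dwell("lognormal", meanlog = log(9.3), sdlog = 0.52),
      light = dwell("lognormal", meanlog = log(5.8), sdlog = 0.5),
      label = "healthy"
    )
  } else {
    synthetic_profile(
      sitting = dwell("lognormal", meanlog = log(25), sdlog = 0.9),
      standing = dwell("lognormal", meanlog = log(23.6), sdlog = 0.65),
      light = dwell("lognormal", meanlog = log(10.5), sdlog = 0.53),
      label = "unhealthy"
    )
  }
}

#' Analytic stationary occupancy of the wear states
#'
#' Stationary distribution `pi` of the embedded chain (left eigenvector),
#' weighted by mean dwell times: `occ_i = pi_i m_i / sum_j pi_j m_j`. This
#' is the long-run fraction of worn time spent in each state, ignoring
#' discretization and window truncation.
#'
#' @param profile a `sit_profile`.
#' @return named numeric vector over the three wear states, summing to 1.
#' @export
stationary_occupancy <- function(profile) {
  P <- profile$transition
  # solve pi P = pi, sum(pi) = 1
  A <- rbind(t(P) - diag(3), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi_emb <- qr.solve(A, b)
  m <- vapply(profile$dwell, dwell_mean, numeric(1))
  occ <- pi_emb * m
  setNames(occ / sum(occ), WEAR_STATES)
}

#' Expected per-day minutes implied by a profile
#'
#' Analytic expectations under the continuous semi-Markov model (before
#' epoch discretization and end-of-window truncation): expected minutes per
#' wear day in each state, and expected sitting minutes accumulated in bouts
#' longer than `long_bout_min`.
#'
#' @param profile a `sit_profile`.
#' @param long_bout_min long-bout threshold in minutes (default 90).
#' @return a list: `window_min`, `sit_min`, `stand_min`, `light_min`,
#'   `long_sit_min`.
#' @export
profile_expected_minutes <- function(profile, long_bout_min = 90) {
  window <- profile$wear_end_min - profile$wear_start_min
  occ <- stationary_occupancy(profile)
  mins <- occ * window
  sit_dwell <- profile$dwell$SITTING
  n_bouts <- mins[["SITTING"]] / dwell_mean(sit_dwell)
  list(
    window_min = window,
    sit_min = mins[["SITTING"]],
    stand_min = mins[["STANDING"]],
    light_min = mins[["LIGHT_ACTIVITY"]],
    long_sit_min = n_bouts * dwell_partial_mean(sit_dwell, long_bout_min)
  )
}

# run the RNG under a local seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# dwell minutes -> epochs: round half-up to the nearest 0.5 min, min 1 epoch
dwell_epochs <- function(minutes) {
  pmax(1L, as.integer(floor(minutes / EPOCH_MIN + 0.5)))
}

#' Generate one synthetic day of posture epochs
#'
#' Simulates the wear window of `date` by the semi-Markov construction and
#' pads the rest of the day (a full 2880-epoch midnight-to-midnight grid)
#' with `NON_WEAR`. The initial state is drawn from the embedded chain's
#' stationary distribution; the final bout is truncated at the window end.
#' Deterministic given `(profile, date, seed)`.
#'
#' @param profile a `sit_profile`.
#' @param date the calendar `Date` to simulate.
#' @param participant_id identifier placed on every epoch.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (and advanced).
#' @param worn if `FALSE`, the whole day is `NON_WEAR` (a non-worn day).
#' @return a day tibble of class `epoch_stream` covering the full day.
#' @export
generate_day <- function(profile, date, participant_id = "sim",
                         seed = NULL, worn = TRUE) {
  stopifnot(inherits(profile, "sit_profile"), inherits(date, "Date"))
  with_seed(seed, {
    n_day <- as.integer(1440 / EPOCH_MIN)
    states <- rep("NON_WEAR", n_day)
    if (worn) {
      i0 <- as.integer(profile$wear_start_min / EPOCH_MIN) + 1L
      i1 <- as.integer(ceiling(profile$wear_end_min / EPOCH_MIN))
      n_window <- i1 - i0 + 1L
      A <- rbind(t(profile$transition) - diag(3), rep(1, 3))
      pi_emb <- qr.solve(A, c(0, 0, 0, 1))
      seq_states <- integer(0)
      cur <- sample.int(3L, 1L, prob = pi_emb)
      while (length(seq_states) < n_window) {
        dmin <- draw_dwell(profile$dwell[[WEAR_STATES[cur]]], 1L)
        seq_states <- c(seq_states, rep(cur, dwell_epochs(dmin)))
        cur <- sample.int(3L, 1L, prob = profile$transition[cur, ])
      }
      states[i0:i1] <- WEAR_STATES[seq_states[seq_len(n_window)]]
    }
    out <- tibble::tibble(
      participant_id = participant_id,
      timestamp = as.POSIXct(format(date), tz = "UTC") +
        seq(0, by = EPOCH_SEC, length.out = n_day),
      state = posture_factor(states)
    )
    class(out) <- c("epoch_stream", class(out))
    out
  })
}

#' Generate a participant's multi-week stream
#'
#' Weeks start on `start_date` (use a Monday to align with ISO weeks). In
#' each week, `wear_days_per_week` worn days are chosen uniformly at random;
#' the remaining days are all-`NON_WEAR`. Per-day sub-seeds are drawn
#' upfront under `seed`, so any single day can be regenerated reproducibly.
#'
#' @param profile a `sit_profile`.
#' @param participant_id identifier.
#' @param start_date first day (a `Date`).
#' @param n_weeks number of 7-day weeks.
#' @param seed integer seed for this participant.
#' @return an `epoch_stream` tibble covering `7 * n_weeks` full days.
#' @export
generate_participant <- function(profile, participant_id, start_date,
                                 n_weeks = 1L, seed = 1L) {
  stopifnot(inherits(profile, "sit_profile"), n_weeks >= 1L)
  n_days <- 7L * n_weeks
  plan <- with_seed(seed, {
    worn <- unlist(lapply(seq_len(n_weeks), function(w) {
      idx <- sample.int(7L, profile$wear_days_per_week)
      seq_len(7L) %in% idx
    }))
    list(worn = worn, day_seeds = sample.int(.Machine$integer.max, n_days))
  })
  days <- lapply(seq_len(n_days), function(i) {
    generate_day(
      profile, start_date + (i - 1L), participant_id,
      seed = plan$day_seeds[i], worn = plan$worn[i]
    )
  })
  out <- dplyr::bind_rows(days)
  class(out) <- c("epoch_stream", class(out))
  out
}

#' Cohort configuration
#'
#' @param n_participants cohort size.
#' @param n_weeks weeks of data per participant.
#' @param mixture fraction of participants on the unhealthy preset (the
#'   count is `round(mixture * n_participants)`); the rest are healthy.
#' @param seed master seed; per-participant sub-seeds are the first
#'   `n_participants` draws of `sample.int(.Machine$integer.max)` under it,
#'   assigned in participant order.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, n_weeks = 1L, mixture = 0.5,
                          seed = 1L) {
  stopifnot(
    n_participants >= 1L, n_weeks >= 1L,
    mixture >= 0, mixture <= 1
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_weeks = as.integer(n_weeks),
      mixture = mixture, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Generates one stream per participant under the healthy/unhealthy preset
#' mixture. When `out_dir` is given, one epoch CSV per participant-week is
#' written (dialect of [write_epoch_stream()]) together with a
#' `manifest.json` recording each participant's true profile label,
#' sub-seed, files, and the preset dwell parameters — the ground truth
#' against which recovery can be checked.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory (created if missing).
#' @param start_date first day; defaults to a Monday so weeks align with
#'   ISO weeks.
#' @return invisibly, a list with `streams` (named list of `epoch_stream`s)
#'   and `manifest` (tibble: `participant_id`, `label`, `seed`).
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            start_date = as.Date("2019-05-06")) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  n_unhealthy <- round(config$mixture * n)
  assign_seeds <- with_seed(config$seed, {
    list(
      labels = sample(rep(
        c("unhealthy", "healthy"),
        c(n_unhealthy, n - n_unhealthy)
      )),
      seeds = sample.int(.Machine$integer.max, n)
    )
  })
  ids <- sprintf("P%03d", seq_len(n))
  profiles <- list(
    healthy = preset_profile("healthy"),
    unhealthy = preset_profile("unhealthy")
  )
  streams <- purrr::map(seq_len(n), function(i) {
    generate_participant(
      profiles[[assign_seeds$labels[i]]], ids[i], start_date,
      n_weeks = config$n_weeks, seed = assign_seeds$seeds[i]
    )
  })
  names(streams) <- ids
  manifest <- tibble::tibble(
    participant_id = ids,
    label = assign_seeds$labels,
    seed = assign_seeds$seeds
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- purrr::map(seq_len(n), function(i) {
      wk_files <- character(config$n_weeks)
      for (w in seq_len(config$n_weeks)) {
        d0 <- start_date + (w - 1L) * 7L
        sel <- streams[[i]][
          as.Date(streams[[i]]$timestamp, tz = "UTC") >= d0 &
            as.Date(streams[[i]]$timestamp, tz = "UTC") < d0 + 7L,
        ]
        wk_files[w] <- file.path(out_dir, sprintf("%s_w%02d.csv", ids[i], w))
        write_epoch_stream(sel, wk_files[w])
      }
      wk_files
    })
    manifest_out <- list(
      config = unclass(config),
      start_date = format(start_date),
      profiles = lapply(profiles, function(p) {
        list(
          label = p$label,
          dwell = lapply(p$dwell, unclass),
          wear_window = c(p$wear_start_min, p$wear_end_min),
          wear_days_per_week = p$wear_days_per_week
        )
      }),
      participants = purrr::map(seq_len(n), function(i) {
        list(
          participant_id = ids[i], label = assign_seeds$labels[i],
          seed = assign_seeds$seeds[i], files = basename(files[[i]])
        )
      })
    )
    jsonlite::write_json(
      manifest_out, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(list(streams = streams, manifest = manifest))
}
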