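# Fixture builders and independent oracles, all generated in code.

PSTATES <- c("SITTING", "STANDING", "LIGHT_ACTIVITY", "NON_WEAR")

# Build a day tibble directly from run-length encoded states.
make_day <- function(states, lengths, date = as.Date("2019-05-01"),
                     start_min = 480, pid = "T01") {
  s <- rep(states, lengths)
  tibble::tibble(
    participant_id = pid,
    timestamp = as.POSIXct(format(date), tz = "UTC") + start_min * 60 +
      seq(0, by = 30, length.out = length(s)),
    state = factor(s, levels = PSTATES)
  )
}

# Minimal day-summary rows for goal-evaluation tests.
make_summaries <- function(pid, dates, all_ok, valid = TRUE,
                           sit_ok = all_ok, active_ok = all_ok,
                           sssb_ok = all_ok, sssb = 1000) {
  n <- length(dates)
  tibble::tibble(
    participant_id = pid,
    date = dates,
    sssb = rep_len(sssb, n),
    sit_ok = rep_len(sit_ok, n),
    active_ok = rep_len(active_ok, n),
    sssb_ok = rep_len(sssb_ok, n),
    all_ok = rep_len(all_ok, n),
    valid_wear = rep_len(valid, n)
  )
}

# Write an epoch CSV from raw data lines (header added).
epoch_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("participant_id,timestamp,state", lines), path)
  path
}

# Independent epoch-level SSSB oracle: walk the raw epochs, count runs of
# SITTING, square and sum. Deliberately avoids rle()/extract_bouts().
sssb_brute <- function(day) {
  s <- as.character(day$state)
  total <- 0
  run <- 0L
  for (x in s) {
    if (x == "SITTING") {
      run <- run + 1L
    } else {
      if (run > 0L) total <- total + (run * 0.5)^2
      run <- 0L
    }
  }
  if (run > 0L) total <- total + (run * 0.5)^2
  total
}

# A generated day alternating between the two presets.
preset_day <- function(i, seed = 1000L) {
  prof <- preset_profile(if (i %% 2 == 0) "healthy" else "unhealthy")
  generate_day(prof, as.Date("2019-05-06") + (i %% 7), seed = seed + i)
}

# All compositions of n_epochs epochs into k positive parts (bout grids).
compositions <- function(n_epochs, k) {
  if (k == 1L) {
    return(matrix(n_epochs, nrow = 1L))
  }
  cuts <- utils::combn(n_epochs - 1L, k - 1L)
  t(apply(cuts, 2, function(cc) diff(c(0L, cc, n_epochs))))
}
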