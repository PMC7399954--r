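test_that("generation is deterministic given profile, date and seed", {
  h <- preset_profile("healthy")
  d1 <- generate_day(h, as.Date("2019-05-06"), seed = 99)
  d2 <- generate_day(h, as.Date("2019-05-06"), seed = 99)
  expect_identical(d1, d2)
  expect_false(identical(
    as.character(d1$state),
    as.character(generate_day(h, as.Date("2019-05-06"), seed = 100)$state)
  ))

  c1 <- generate_cohort(cohort_config(3, 1, 0.5, seed = 5))
  c2 <- generate_cohort(cohort_config(3, 1, 0.5, seed = 5))
  expect_identical(c1, c2)

  # byte-identical file output for identical config and seed
  t1 <- file.path(tempdir(), "coh1")
  t2 <- file.path(tempdir(), "coh2")
  generate_cohort(cohort_config(2, 1, 0.5, seed = 8), out_dir = t1)
  generate_cohort(cohort_config(2, 1, 0.5, seed = 8), out_dir = t2)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)))
  }
})

test_that("every generated day covers the full epoch grid and the wear window", {
  h <- preset_profile("healthy")
  d <- generate_day(h, as.Date("2019-05-06"), seed = 3)
  expect_equal(nrow(d), 2880L)
  # conservation: state counts account for every epoch
  expect_equal(sum(table(d$state)), 2880L)
  # epochs outside the 08:00-22:00 window are NON_WEAR
  mins <- (as.numeric(d$timestamp) %% 86400) / 60
  outside <- mins < 480 | mins >= 1320
  expect_true(all(d$state[outside] == "NON_WEAR"))
  expect_true(all(d$state[!outside] != "NON_WEAR"))
  expect_equal(wear_minutes(d), 840)
})

test_that("a degenerate always-sitting profile yields one wall-to-wall bout", {
  prof <- synthetic_profile(
    sitting = dwell("fixed", minutes = 1e6),
    standing = dwell("fixed", minutes = 1),
    light = dwell("fixed", minutes = 1)
  )
  # draw until the initial state is SITTING; with dwell >> window the day
  # is then a single sitting bout spanning the whole wear window
  for (seed in 1:10) {
    d <- generate_day(prof, as.Date("2019-05-06"), seed = seed)
    b <- extract_bouts(d)
    if (as.character(b$state[1]) == "SITTING") {
      expect_equal(nrow(b), 1L)
      expect_equal(b$duration_min, 840)
      expect_equal(summarize_day(d)$sssb, 840^2)
      break
    }
  }
})

test_that("realized complete sitting-bout durations recover the profile mean", {
  h <- preset_profile("healthy")
  set.seed(7)
  durs <- unlist(lapply(1:300, function(i) {
    b <- extract_bouts(generate_day(h, as.Date("2019-05-06")))
    sb <- b$duration_min[b$state == "SITTING"]
    # drop the final bout of the day: it is truncated by the window end
    if (as.character(b$state[nrow(b)]) == "SITTING") sb <- sb[-length(sb)]
    sb
  }))
  target <- exp(log(12) + 0.7^2 / 2) # analytic lognormal mean
  mc_se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - target), 3 * mc_se + 0.25) # +discretization bias bound
})

test_that("realized state occupancy matches the analytic stationary occupancy", {
  u <- preset_profile("unhealthy")
  occ <- stationary_occupancy(u)
  expect_equal(sum(occ), 1)
  set.seed(11)
  counts <- c(SITTING = 0, STANDING = 0, LIGHT_ACTIVITY = 0)
  for (i in 1:100) {
    d <- generate_day(u, as.Date("2019-05-06") + (i %% 5))
    tab <- table(d$state)
    counts <- counts + tab[names(counts)]
  }
  realized <- counts / sum(counts)
  expect_true(all(abs(realized - occ) < 0.03))
})

test_that("cohort bookkeeping: sizes, labels, files and round-trip", {
  out <- file.path(tempdir(), "coh4")
  coh <- generate_cohort(cohort_config(4, 1, mixture = 0.5, seed = 7),
    out_dir = out
  )
  expect_length(coh$streams, 4L)
  expect_equal(sum(coh$manifest$label == "unhealthy"), 2L)
  csvs <- list.files(out, pattern = "\\.csv$")
  expect_length(csvs, 4L) # one file per participant-week
  expect_true(file.exists(file.path(out, "manifest.json")))
  mf <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_length(mf$participants, 4L)
  expect_equal(
    sort(vapply(mf$participants, `[[`, "", "label")),
    sort(coh$manifest$label)
  )
  # files round-trip through the reader to the in-memory stream
  p1 <- coh$manifest$participant_id[1]
  back <- read_epoch_stream(file.path(out, paste0(p1, "_w01.csv")))
  expect_equal(as.character(back$state), as.character(coh$streams[[p1]]$state))
  expect_equal(back$timestamp, coh$streams[[p1]]$timestamp)
})

test_that("presets share expected sitting time but not its bout structure", {
  h <- profile_expected_minutes(preset_profile("healthy"))
  u <- profile_expected_minutes(preset_profile("unhealthy"))
  # equal expected daily sitting time within 5% (analytic)
  expect_lt(abs(h$sit_min - u$sit_min) / ((h$sit_min + u$sit_min) / 2), 0.05)
  # order-of-magnitude contrast in expected minutes in >90-min bouts
  expect_gt(u$long_sit_min / h$long_sit_min, 10)
})

test_that("healthy preset days are mostly classified as healthy patterns", {
  h <- preset_profile("healthy")
  set.seed(23)
  ok <- vapply(1:60, function(i) {
    summarize_day(generate_day(h, as.Date("2019-05-06")))$sssb_ok
  }, logical(1))
  expect_gt(mean(ok), 0.5)
})

test_that("preset separation and mixture cutoff ordering hold on a cohort", {
  coh <- generate_cohort(cohort_config(10, 1, mixture = 0.5, seed = 19))
  sms <- summarize_days(coh$streams)
  lab <- coh$manifest$label[match(sms$participant_id, coh$manifest$participant_id)]
  valid <- sms$valid_wear
  med_h <- median(sms$sssb[valid & lab == "healthy"])
  med_u <- median(sms$sssb[valid & lab == "unhealthy"])
  expect_lt(med_h, med_u)
  expect_lt(
    mean(sms$sssb[valid & lab == "healthy"]),
    mean(sms$sssb[valid & lab == "unhealthy"])
  )
  cut <- derive_cutoff(sms)
  expect_gt(cut, med_h)
  expect_lt(cut, med_u)
})

test_that("mean SSSB responds monotonically to the sitting fraction", {
  mean_sssb <- function(sit_meanlog, n = 30) {
    prof <- synthetic_profile(
      sitting = dwell("lognormal", meanlog = sit_meanlog, sdlog = 0.7),
      standing = dwell("lognormal", meanlog = log(9.3), sdlog = 0.52),
      light = dwell("lognormal", meanlog = log(5.8), sdlog = 0.5)
    )
    mean(vapply(1:n, function(i) {
      summarize_day(generate_day(prof, as.Date("2019-05-06"),
        seed = 7000 + i
      ))$sssb
    }, numeric(1)))
  }
  ladder <- vapply(log(c(8, 16, 32)), mean_sssb, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("profile validation rejects malformed inputs", {
  expect_error(preset_profile("weird"))
  expect_error(dwell("lognormal", meanlog = 1, sdlog = -1))
  bad_P <- matrix(c(0, .5, .5, .5, .5, 0, 1, 0, 0), 3, byrow = TRUE)
  expect_error(synthetic_profile(
    sitting = dwell("fixed", minutes = 10),
    standing = dwell("fixed", minutes = 10),
    light = dwell("fixed", minutes = 10),
    transition = bad_P
  )) # nonzero diagonal
  expect_error(synthetic_profile(
    sitting = dwell("fixed", minutes = 10),
    standing = dwell("fixed", minutes = 10),
    light = dwell("fixed", minutes = 10),
    wear_start = "10:00", wear_end = "10:00"
  ), "wear window")
})
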