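# Reading, validating and segmenting 30-s posture-epoch streams.
#
# Epoch CSV dialect: header `participant_id,timestamp,state`; one epoch per
# row; timestamp ISO-8601 `YYYY-MM-DDTHH:MM:SS` (naive local time, no zone);
# state token in {SIT, STAND, LIGHT, NONWEAR}; UTF-8, comma-separated.
# Timestamps must sit on the 30-s grid anchored at midnight and be strictly
# increasing; missing epochs between the first and last timestamp are filled
# in as NON_WEAR on read, so wear time is always explicit and day lengths are
# well defined.

#' Read a posture-epoch stream from CSV
#'
#' Reads one participant's stream of 30-second posture epochs, validates it,
#' and fills any gaps between the first and last timestamp with `NON_WEAR`
#' epochs so consecutive records are always exactly one epoch apart.
#'
#' Validation is strict: an unrecognized state token, an off-grid or
#' non-increasing timestamp, a missing column or an empty file are hard
#' errors naming the offending line; nothing is silently coerced. Repairs
#' (gap filling) are recorded in the attached validation report, retrievable
#' with [validation_report()].
#'
#' @param path path to an epoch CSV file in the dialect described above.
#' @return A tibble of class `epoch_stream` with columns `participant_id`,
#'   `timestamp` (`POSIXct`), `state` (factor with levels `SITTING`,
#'   `STANDING`, `LIGHT_ACTIVITY`, `NON_WEAR`), carrying a `"validation"`
#'   attribute with fields `n_records`, `n_gap_epochs_filled`,
#'   `n_bad_tokens`, `issues`.
#' @seealso [write_epoch_stream()], [split_into_days()]
#' @export
read_epoch_stream <- function(path) {
  if (!file.exists(path)) {
    stop("epoch file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!identical(names(raw), c("participant_id", "timestamp", "state"))) {
    stop(
      "header must be exactly 'participant_id,timestamp,state'; got: ",
      paste(names(raw), collapse = ","),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0L) {
    stop("empty epoch file: ", path, call. = FALSE)
  }
  # line numbers in the file: +1 for the header
  line_of <- function(i) i + 1L

  bad <- which(!(raw$state %in% names(TOKEN_STATES)))
  if (length(bad) > 0L) {
    stop(
      "unknown state token(s) at line(s) ",
      paste(line_of(head(bad, 5L)), collapse = ", "),
      if (length(bad) > 5L) " ..." else "",
      ": ", paste(unique(head(raw$state[bad], 5L)), collapse = ", "),
      " (expected SIT, STAND, LIGHT or NONWEAR)",
      call. = FALSE
    )
  }
  pid <- unique(raw$participant_id)
  if (length(pid) != 1L || is.na(pid) || !nzchar(pid)) {
    stop("file must contain exactly one non-empty participant_id", call. = FALSE)
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    stop(
      "unparseable timestamp at line ",
      line_of(which(is.na(ts))[1L]),
      ": ", raw$timestamp[which(is.na(ts))[1L]],
      call. = FALSE
    )
  }
  off <- which(as.numeric(ts) %% EPOCH_SEC != 0)
  if (length(off) > 0L) {
    stop(
      "timestamp off the 30-s epoch grid at line ", line_of(off[1L]),
      ": ", raw$timestamp[off[1L]],
      call. = FALSE
    )
  }
  if (any(diff(as.numeric(ts)) <= 0)) {
    i <- which(diff(as.numeric(ts)) <= 0)[1L] + 1L
    stop(
      "timestamps not strictly increasing at line ", line_of(i),
      ": ", raw$timestamp[i],
      call. = FALSE
    )
  }

  grid <- seq(ts[1L], ts[length(ts)], by = EPOCH_SEC)
  state_full <- rep("NON_WEAR", length(grid))
  state_full[match(as.numeric(ts), as.numeric(grid))] <-
    TOKEN_STATES[raw$state]
  n_gaps <- length(grid) - nrow(raw)

  issues <- character(0)
  if (n_gaps > 0L) {
    issues <- sprintf("filled %d missing epoch(s) as NON_WEAR", n_gaps)
  }
  out <- tibble::tibble(
    participant_id = pid,
    timestamp = grid,
    state = posture_factor(state_full)
  )
  attr(out, "validation") <- list(
    n_records = nrow(out),
    n_gap_epochs_filled = n_gaps,
    n_bad_tokens = 0L,
    issues = issues
  )
  class(out) <- c("epoch_stream", class(out))
  out
}

#' Retrieve the validation report attached to a stream
#'
#' @param stream an `epoch_stream` as returned by [read_epoch_stream()].
#' @return a list with `n_records`, `n_gap_epochs_filled`, `n_bad_tokens`
#'   and `issues`.
#' @export
validation_report <- function(stream) {
  rep <- attr(stream, "validation")
  if (is.null(rep)) {
    list(
      n_records = nrow(stream), n_gap_epochs_filled = 0L,
      n_bad_tokens = 0L, issues = character(0)
    )
  } else {
    rep
  }
}

#' Write a posture-epoch stream to CSV
#'
#' Serializes a stream in the same dialect [read_epoch_stream()] reads, so a
#' gap-free stream round-trips byte for byte.
#'
#' @param stream a tibble with `participant_id`, `timestamp`, `state`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_stream <- function(stream, path) {
  stopifnot(all(c("participant_id", "timestamp", "state") %in% names(stream)))
  lines <- paste(
    stream$participant_id,
    format(stream$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    STATE_TOKENS[as.character(stream$state)],
    sep = ","
  )
  writeLines(c("participant_id,timestamp,state", lines), path)
  invisible(path)
}

#' Split a stream into calendar days
#'
#' Assigns every epoch to its local calendar date; a posture run crossing
#' midnight is thereby cut at the boundary (bouts never span days).
#'
#' @param stream an epoch stream tibble.
#' @return a named list of day tibbles (one per date, names `"YYYY-MM-DD"`),
#'   each preserving epoch order.
#' @export
split_into_days <- function(stream) {
  stopifnot(nrow(stream) > 0L)
  dates <- as.Date(stream$timestamp, tz = "UTC")
  out <- split(tibble::as_tibble(stream), dates)
  out[order(names(out))]
}

#' Wear time of a day, in minutes
#'
#' Each epoch whose state is not `NON_WEAR` contributes half a minute.
#'
#' @param day a day tibble as produced by [split_into_days()].
#' @return worn minutes (multiple of 0.5).
#' @export
wear_minutes <- function(day) {
  EPOCH_MIN * sum(day$state != "NON_WEAR")
}

#' Is a day a valid wearing day?
#'
#' A day counts as a wearing day when the monitor recorded posture data for
#' at least `min_wear` minutes (default 6 hours); the threshold is inclusive.
#'
#' @param day a day tibble.
#' @param min_wear minimum wear time in minutes; must be positive.
#' @return logical.
#' @export
is_valid_wearing_day <- function(day, min_wear = 360) {
  stopifnot(is.numeric(min_wear), length(min_wear) == 1L, min_wear > 0)
  wear_minutes(day) >= min_wear
}
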