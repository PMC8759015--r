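SLEEP_STATES <- c("awake", "light", "deep")

parse_iso8601 <- function(x, path) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(t) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("%s: malformed ISO-8601 timestamp at data line %d: '%s'",
                 basename(path), bad[1], x[bad[1]]), call. = FALSE)
  }
  t
}

# sort per subject by timestamp; collapse duplicate (subject, timestamp)
# keys to the last occurrence
sort_dedupe <- function(df, path) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$subject_id, df$timestamp), , drop = FALSE]
  key <- paste(df$subject_id, as.numeric(df$timestamp))
  keep <- !duplicated(key, fromLast = TRUE)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a heart-rate sample stream
#'
#' Reads a CSV with columns `subject_id`, `timestamp` (ISO-8601, single
#' study timezone) and `hr_bpm`. Rows are sorted per subject by timestamp;
#' duplicate `(subject, timestamp)` rows are collapsed to the last
#' occurrence. An empty file yields an empty stream.
#'
#' @param path CSV file path.
#' @return data frame `subject_id`, `timestamp` (POSIXct), `hr_bpm`.
#' @export
read_hr_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "hr_bpm")
  if (nrow(df) == 0 && !all(need %in% names(df))) {
    return(data.frame(subject_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      hr_bpm = numeric(), stringsAsFactors = FALSE))
  }
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns: %s", basename(path),
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  df$timestamp <- parse_iso8601(df$timestamp, path)
  df$hr_bpm <- as.numeric(df$hr_bpm)
  bad <- which(!is.finite(df$hr_bpm))
  if (length(bad))
    stop(sprintf("%s: non-numeric hr_bpm at data line %d", basename(path),
                 bad[1]), call. = FALSE)
  sort_dedupe(df[, need], path)
}

#' Read a sleep-state event stream
#'
#' Reads a CSV with columns `subject_id`, `timestamp` and `state`
#' (`awake`/`light`/`deep`; the watch stores state *changes* only). Sorting
#' and deduplication as in [read_hr_stream()]. An unknown state is a parse
#' error naming the offending line.
#'
#' @param path CSV file path.
#' @return data frame `subject_id`, `timestamp` (POSIXct), `state`.
#' @export
read_sleep_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "state")
  if (nrow(df) == 0) {
    return(data.frame(subject_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      state = character(), stringsAsFactors = FALSE))
  }
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns: %s", basename(path),
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  bad <- which(!df$state %in% SLEEP_STATES)
  if (length(bad))
    stop(sprintf("%s: unknown sleep state '%s' at data line %d",
                 basename(path), df$state[bad[1]], bad[1]), call. = FALSE)
  df$timestamp <- parse_iso8601(df$timestamp, path)
  sort_dedupe(df[, need], path)
}

#' Read the subject allocation table
#'
#' CSV with columns `subject_id`, `arm` (`placebo`/`active`) and
#' `anchor_date` (calendar date of study day 0, `YYYY-MM-DD`). Every subject
#' must appear exactly once.
#'
#' @param path CSV file path.
#' @return data frame `subject_id`, `arm`, `anchor_date`.
#' @export
read_allocation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "anchor_date")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns: %s", basename(path),
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop(sprintf("%s: duplicated subject_id", basename(path)), call. = FALSE)
  bad <- which(!df$arm %in% c("placebo", "active"))
  if (length(bad))
    stop(sprintf("%s: unknown arm '%s' at data line %d", basename(path),
                 df$arm[bad[1]], bad[1]), call. = FALSE)
  df[, need]
}

#' Reconstruct the sleep interval of one night from state-change events
#'
#' The night window for study day `d` runs from noon of day `d` to noon of
#' day `d + 1`; the night is attributed to day `d`, the evening on which
#' sleep begins. The asleep interval starts at the first event with a
#' non-awake state (`light`/`deep`) and ends at the last state-change event
#' in the window (the terminal transition, normally back to `awake`). A
#' window with no non-awake event has status `missing`; an interval shorter
#' than 3 hours has status `excluded_short`.
#'
#' @param events data frame `timestamp`, `state` for one subject, restricted
#'   (or restrictable) to the night window; chronological.
#' @param window_start,window_end POSIXct bounds `[window_start, window_end)`.
#' @param subject_id,night_day identifiers carried into the result.
#' @return one-row data frame: `subject_id`, `night_day`, `start`, `end`,
#'   `duration_h`, `status` (`detected`/`excluded_short`/`missing`).
#' @export
reconstruct_sleep_interval <- function(events, window_start, window_end,
                                       subject_id = NA_character_,
                                       night_day = NA_integer_) {
  na_time <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  out <- data.frame(subject_id = subject_id, night_day = night_day,
                    start = na_time, end = na_time,
                    duration_h = NA_real_, status = "missing",
                    stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0) return(out)
  ev <- events[events$timestamp >= window_start &
                 events$timestamp < window_end, , drop = FALSE]
  if (nrow(ev) == 0) return(out)
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  first_sleep <- which(ev$state %in% c("light", "deep"))
  if (length(first_sleep) == 0) return(out)
  start <- ev$timestamp[first_sleep[1]]
  end <- ev$timestamp[nrow(ev)]
  if (end <= start) return(out)
  dur <- as.numeric(difftime(end, start, units = "hours"))
  out$start <- start; out$end <- end; out$duration_h <- dur
  out$status <- if (dur < 3) "excluded_short" else "detected"
  out
}

#' Reconstruct all nightly sleep intervals of a cohort
#'
#' Applies [reconstruct_sleep_interval()] to every subject and study day.
#'
#' @param sleep data frame from [read_sleep_events()].
#' @param allocation data frame from [read_allocation()].
#' @param study_days integer vector of study days to scan (default `-6:6`).
#' @return data frame of night intervals, one row per subject x day.
#' @export
reconstruct_nights <- function(sleep, allocation, study_days = -6:6) {
  rows <- lapply(seq_len(nrow(allocation)), function(i) {
    sid <- allocation$subject_id[i]
    anchor <- anchor_time(allocation$anchor_date[i])
    ev <- sleep[sleep$subject_id == sid, , drop = FALSE]
    do.call(rbind, lapply(study_days, function(d) {
      w0 <- anchor + d * 86400 + 12 * 3600
      reconstruct_sleep_interval(ev, w0, w0 + 86400, sid, d)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# awake window of one study day given the bounding night intervals;
# a non-missing (detected or excluded_short) night still bounds the day
awake_window <- function(day, anchor, prev_night, cur_night) {
  default_start <- anchor + day * 86400 + 9 * 3600   # 9 AM
  default_end <- anchor + day * 86400 + 21 * 3600    # 9 PM
  src <- "sleep_bounds"
  if (!is.null(prev_night) && prev_night$status != "missing") {
    w0 <- prev_night$end
  } else {
    w0 <- default_start; src <- "default_window"
  }
  if (!is.null(cur_night) && cur_night$status != "missing") {
    w1 <- cur_night$start
  } else {
    w1 <- default_end; src <- "default_window"
  }
  list(start = w0, end = w1, source = src)
}

#' Split one study day's HR samples into asleep and awake segments
#'
#' Asleep samples are those with timestamps in the closed interval
#' `[start, end]` of the day's attributed night (absent when the night's
#' status is not `detected`; a boundary sample counts as asleep). Awake
#' samples lie strictly between the previous night's end and the current
#' night's start. When a bounding night is missing, that bound falls back to
#' the 9 AM / 9 PM default clock window and `awake_window_source` is
#' `"default_window"`. Short (excluded) nights still bound the awake day;
#' only their asleep series is dropped.
#'
#' @param hr data frame `timestamp`, `hr_bpm` for one subject.
#' @param day study day index.
#' @param anchor POSIXct midnight of study day 0 for this subject.
#' @param prev_night,cur_night one-row night data frames (or `NULL`) from
#'   [reconstruct_nights()]: the nights attributed to `day - 1` and `day`.
#' @return list with `asleep` (numeric HR values or `NULL`), `awake`
#'   (numeric HR values), and `awake_window_source`.
#' @export
segment_day <- function(hr, day, anchor, prev_night = NULL,
                        cur_night = NULL) {
  w <- awake_window(day, anchor, prev_night, cur_night)
  t <- hr$timestamp
  in_awake <- t > w$start & t < w$end
  # samples inside a bounding (non-missing) asleep interval never leak into
  # awake even under default windows
  for (night in list(prev_night, cur_night)) {
    if (!is.null(night) && night$status != "missing") {
      in_awake <- in_awake & !(t >= night$start & t <= night$end)
    }
  }
  awake <- hr$hr_bpm[in_awake]
  asleep <- NULL
  if (!is.null(cur_night) && cur_night$status == "detected") {
    asleep <- hr$hr_bpm[t >= cur_night$start & t <= cur_night$end]
  }
  list(asleep = asleep, awake = awake, awake_window_source = w$source)
}

#' Segment a whole cohort into subject-day-period HR value sets
#'
#' @param hr data frame from [read_hr_stream()].
#' @param nights data frame from [reconstruct_nights()].
#' @param allocation data frame from [read_allocation()].
#' @param study_days integer vector of study days.
#' @return list with `segments` — a long data frame `subject_id`,
#'   `study_day`, `period`, `value_bpm` — and `windows`, one row per
#'   subject-day with the awake-window source.
#' @export
segment_cohort <- function(hr, nights, allocation, study_days = -6:6) {
  seg_rows <- list(); win_rows <- list(); k <- 0L
  for (i in seq_len(nrow(allocation))) {
    sid <- allocation$subject_id[i]
    anchor <- anchor_time(allocation$anchor_date[i])
    hr_s <- hr[hr$subject_id == sid, , drop = FALSE]
    nt_s <- nights[nights$subject_id == sid, , drop = FALSE]
    for (d in study_days) {
      prev_night <- nt_s[nt_s$night_day == d - 1L, , drop = FALSE]
      cur_night <- nt_s[nt_s$night_day == d, , drop = FALSE]
      if (nrow(prev_night) == 0) prev_night <- NULL
      if (nrow(cur_night) == 0) cur_night <- NULL
      seg <- segment_day(hr_s, d, anchor, prev_night, cur_night)
      k <- k + 1L
      win_rows[[k]] <- data.frame(subject_id = sid, study_day = d,
                                  awake_window_source = seg$awake_window_source,
                                  stringsAsFactors = FALSE)
      if (length(seg$awake) > 0) {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          subject_id = sid, study_day = d, period = "awake",
          value_bpm = seg$awake, stringsAsFactors = FALSE)
      }
      if (!is.null(seg$asleep) && length(seg$asleep) > 0) {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          subject_id = sid, study_day = d, period = "asleep",
          value_bpm = seg$asleep, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    segments = if (length(seg_rows)) do.call(rbind, seg_rows) else
      data.frame(subject_id = character(), study_day = integer(),
                 period = character(), value_bpm = numeric(),
                 stringsAsFactors = FALSE),
    windows = do.call(rbind, win_rows)
  )
}

#' Nightly sleep-duration table
#'
#' One row per *detected* night; excluded-short and missing nights are
#' absent.
#'
#' @param nights data frame from [reconstruct_nights()].
#' @param allocation optional allocation table; if supplied, an `arm` column
#'   is joined on.
#' @return data frame `subject_id`, `study_day`, `duration_h` (plus `arm`).
#' @export
sleep_duration_table <- function(nights, allocation = NULL) {
  keep <- nights[nights$status == "detected", , drop = FALSE]
  out <- data.frame(subject_id = keep$subject_id,
                    study_day = keep$night_day,
                    duration_h = keep$duration_h,
                    stringsAsFactors = FALSE)
  if (!is.null(allocation)) {
    out$arm <- allocation$arm[match(out$subject_id, allocation$subject_id)]
    out <- out[, c("subject_id", "study_day", "arm", "duration_h")]
  }
  rownames(out) <- NULL
  out
}

#' Tally excluded nights by cause
#'
#' @param nights data frame from [reconstruct_nights()].
#' @return named integer vector: `detected`, `missing_sleep_states`,
#'   `shorter_than_3h`.
#' @export
night_exclusion_counts <- function(nights) {
  c(detected = sum(nights$status == "detected"),
    missing_sleep_states = sum(nights$status == "missing"),
    shorter_than_3h = sum(nights$status == "excluded_short"))
}
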