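#' Configuration for the synthetic smartwatch-data generator
#'
#' Builds and validates the parameter set used by [simulate_cohort()]. The
#' defaults emulate a small parallel-group titration trial: 12 subjects
#' allocated 1:2 to placebo and active treatment, a 6-day baseline (study
#' days -6..-1) followed by 7 dosing days (0..6) with the active dose
#' titrated 20, 40, then 80 ug/day, heart rate sampled every 10 minutes
#' (more often during activity bursts), and nightly sleep reported as
#' state-change events (awake/light/deep) with realistic missingness.
#'
#' @param n_subjects number of subjects (default 12).
#' @param allocation_ratio integer vector `c(placebo, active)`; default
#'   `c(1, 2)` gives a 4/8 split at `n_subjects = 12`.
#' @param study_days integer vector of study days; day 0 is the first dosing
#'   day. Default `-6:6`.
#' @param dose_schedule_ug active-arm dose per treatment day (days `0..6`);
#'   must be non-decreasing over the titration days 0..2.
#' @param effect_profile_bpm data frame with columns `day`, `period`
#'   (`"awake"`/`"asleep"`) and `shift` giving the true active-arm HR shift
#'   in bpm. The default follows the asleep-median and awake-median
#'   treatment-contrast profile that the generator is calibrated to emulate.
#' @param mu_awake_bpm,mu_asleep_bpm population mean HR per period (bpm).
#' @param sigma_b_bpm between-subject SD of the random intercept (bpm).
#' @param sigma_w_bpm within-subject day-level SD (bpm): each subject-day
#'   (per period) draws a random level shift with this SD, so day-to-day
#'   marker variability matches the generating mixed model; also the
#'   residual SD of [simulate_marker_table()].
#' @param sigma_sample_bpm sample-level noise SD for raw streams (bpm).
#' @param circadian_amp_bpm,circadian_phase_h amplitude (bpm) and peak time
#'   (hours after midnight) of the sinusoidal daily HR profile.
#' @param sleep_onset_mean_clock nightly sleep-onset clock time `"HH:MM"`.
#' @param sleep_onset_sd_min SD of sleep onset (minutes).
#' @param sleep_duration_mean_h,sleep_duration_sd_h nightly sleep duration
#'   mean and total SD (hours).
#' @param sleep_duration_icc fraction of the sleep-duration variance that is
#'   between-subject (a per-subject habitual-duration shift); 0 makes nights
#'   independent across subjects.
#' @param base_sampling_min base HR sampling cadence (minutes).
#' @param activity_bursts_per_day number of daytime activity bursts.
#' @param burst_len_min burst length (minutes).
#' @param burst_sampling_min sampling cadence during a burst (minutes).
#' @param p_missing_sleep_states probability a night reports no sleep events.
#' @param p_short_night probability a night is truncated below 3 h.
#' @param anchor_date calendar date of study day 0 (`"YYYY-MM-DD"`); all
#'   timestamps are in a single fixed study timezone (UTC).
#' @param seed integer seed for the generator.
#' @return A validated list of class `"generator_config"`.
#' @seealso [simulate_cohort()], [simulate_marker_table()]
#' @export
generator_config <- function(n_subjects = 12,
                             allocation_ratio = c(1, 2),
                             study_days = -6:6,
                             dose_schedule_ug = c(20, 40, 80, 80, 80, 80, 80),
                             effect_profile_bpm = default_effect_profile(),
                             mu_awake_bpm = 75.4,
                             mu_asleep_bpm = 63.2,
                             sigma_b_bpm = 4.58,
                             sigma_w_bpm = 3.0,
                             sigma_sample_bpm = 5.0,
                             circadian_amp_bpm = 2.0,
                             circadian_phase_h = 15,
                             sleep_onset_mean_clock = "23:30",
                             sleep_onset_sd_min = 45,
                             sleep_duration_mean_h = 6.5,
                             sleep_duration_sd_h = 0.75,
                             sleep_duration_icc = 0.64,
                             base_sampling_min = 10,
                             activity_bursts_per_day = 1,
                             burst_len_min = 28,
                             burst_sampling_min = 2,
                             p_missing_sleep_states = 0.1,
                             p_short_night = 0.02,
                             anchor_date = "2020-03-02",
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    allocation_ratio = allocation_ratio,
    study_days = as.integer(study_days),
    dose_schedule_ug = dose_schedule_ug,
    effect_profile_bpm = effect_profile_bpm,
    mu_awake_bpm = mu_awake_bpm,
    mu_asleep_bpm = mu_asleep_bpm,
    sigma_b_bpm = sigma_b_bpm,
    sigma_w_bpm = sigma_w_bpm,
    sigma_sample_bpm = sigma_sample_bpm,
    circadian_amp_bpm = circadian_amp_bpm,
    circadian_phase_h = circadian_phase_h,
    sleep_onset_mean_clock = sleep_onset_mean_clock,
    sleep_onset_sd_min = sleep_onset_sd_min,
    sleep_duration_mean_h = sleep_duration_mean_h,
    sleep_duration_sd_h = sleep_duration_sd_h,
    sleep_duration_icc = sleep_duration_icc,
    base_sampling_min = base_sampling_min,
    activity_bursts_per_day = as.integer(activity_bursts_per_day),
    burst_len_min = burst_len_min,
    burst_sampling_min = burst_sampling_min,
    p_missing_sleep_states = p_missing_sleep_states,
    p_short_night = p_short_night,
    anchor_date = anchor_date,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

#' @rdname generator_config
#' @export
default_effect_profile <- function() {
  data.frame(
    day = rep(0:6, times = 2),
    period = rep(c("asleep", "awake"), each = 7),
    shift = c(3.70, 7.90, 11.87, 16.18, 13.45, 15.48, 15.18,
              1.79, 5.10, 10.79, 14.54, 16.35, 11.41, 12.22),
    stringsAsFactors = FALSE
  )
}

validate_generator_config <- function(cfg) {
  sds <- c(cfg$sigma_b_bpm, cfg$sigma_w_bpm, cfg$sigma_sample_bpm,
           cfg$circadian_amp_bpm, cfg$sleep_onset_sd_min,
           cfg$sleep_duration_sd_h)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("generator_config: all SDs and amplitudes must be finite and >= 0",
         call. = FALSE)
  probs <- c(cfg$p_missing_sleep_states, cfg$p_short_night,
             cfg$sleep_duration_icc)
  if (any(probs < 0 | probs > 1))
    stop("generator_config: probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_subjects < 1L)
    stop("generator_config: empty cohort", call. = FALSE)
  if (length(cfg$allocation_ratio) != 2L || any(cfg$allocation_ratio < 0))
    stop("generator_config: allocation_ratio must be two non-negative counts",
         call. = FALSE)
  ttr <- cfg$dose_schedule_ug[seq_len(min(3L, length(cfg$dose_schedule_ug)))]
  if (is.unsorted(ttr))
    stop("generator_config: dose schedule must be non-decreasing over the titration days",
         call. = FALSE)
  if (cfg$base_sampling_min <= 0 || cfg$burst_sampling_min <= 0)
    stop("generator_config: sampling cadences must be positive", call. = FALSE)
  invisible(cfg)
}

# Allocation of subjects to arms: the first block is placebo. Deterministic
# (no randomisation needed for a simulated cohort; arm labels are exchangeable).
allocate_arms <- function(n_subjects, ratio) {
  n_placebo <- round(n_subjects * ratio[1] / sum(ratio))
  c(rep("placebo", n_placebo), rep("active", n_subjects - n_placebo))
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

anchor_time <- function(anchor_date) {
  as.POSIXct(paste(anchor_date, "00:00:00"), tz = "UTC")
}

clock_to_hours <- function(clock) {
  parts <- as.numeric(strsplit(clock, ":", fixed = TRUE)[[1]])
  parts[1] + parts[2] / 60
}

circadian_term <- function(time, amp, phase_h) {
  h <- as.numeric(difftime(time, trunc(time, "days"), units = "hours"))
  amp * cos(2 * pi * (h - phase_h) / 24)
}

#' Simulate one night of sleep-state events
#'
#' Draws sleep onset and duration for the night attributed to `day` (the
#' evening on which sleep begins), and emits the state-change events the
#' watch would record: a first non-awake event at onset, zero or more
#' internal light/deep alternations, and a terminal `awake` event at sleep
#' end. With probability `p_missing_sleep_states` no events are emitted
#' (the true interval is still returned); with probability `p_short_night`
#' the night is truncated below 3 h. Consumes the current RNG stream.
#'
#' @param day study day the night is attributed to.
#' @param config a [generator_config()].
#' @param subject_shift_h habitual sleep-duration shift of the subject
#'   (hours); the cohort simulator draws it with SD
#'   `sleep_duration_sd_h * sqrt(sleep_duration_icc)`, leaving the
#'   night-to-night SD at `sleep_duration_sd_h * sqrt(1 - sleep_duration_icc)`.
#' @return list with `events` (data frame `timestamp`, `state`), the true
#'   `start`/`end` times, `duration_h`, and flags `missing`, `short`.
#' @export
simulate_night <- function(day, config, subject_shift_h = 0) {
  anchor <- anchor_time(config$anchor_date)
  onset_h <- clock_to_hours(config$sleep_onset_mean_clock) +
    stats::rnorm(1, 0, config$sleep_onset_sd_min / 60)
  start <- anchor + day * 86400 + onset_h * 3600

  short <- stats::runif(1) < config$p_short_night
  if (short) {
    duration_h <- stats::runif(1, 0.5, 2.9)
  } else {
    sd_night <- config$sleep_duration_sd_h *
      sqrt(1 - config$sleep_duration_icc)
    duration_h <- stats::rnorm(1, config$sleep_duration_mean_h +
                                 subject_shift_h, sd_night)
    duration_h <- max(duration_h, 3.05) # short nights arise only via p_short_night
  }
  end <- start + duration_h * 3600
  missing <- stats::runif(1) < config$p_missing_sleep_states

  if (missing) {
    events <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                         state = character(), stringsAsFactors = FALSE)
  } else {
    n_alt <- stats::rpois(1, 3)
    internal <- sort(start + stats::runif(n_alt) * (duration_h * 3600))
    times <- c(start, internal, end)
    # alternate light/deep from onset; terminal transition back to awake
    states <- c(rep_len(c("light", "deep"), length(times) - 1L), "awake")
    events <- data.frame(timestamp = times, state = states,
                         stringsAsFactors = FALSE)
  }
  list(events = events, start = start, end = end,
       duration_h = duration_h, missing = missing, short = short)
}

#' Simulate a heart-rate sample stream over a time span
#'
#' Lays a base sampling grid of one sample every `base_sampling_min` minutes
#' over `[span_start, span_end)`; inside each activity burst the base grid is
#' replaced by a denser grid at `burst_sampling_min` minutes. Each sample is
#' classified asleep if it falls inside any of the (closed) sleep intervals,
#' and its HR value is `mean_fn(time, asleep)` plus Gaussian sample noise.
#'
#' @param span_start,span_end POSIXct bounds of the span.
#' @param sleep_intervals data frame with POSIXct columns `start`, `end`
#'   (closed intervals), possibly empty.
#' @param bursts data frame with POSIXct columns `start`, `end` of activity
#'   bursts, possibly empty.
#' @param base_sampling_min,burst_sampling_min cadences in minutes.
#' @param mean_fn function `(time, asleep)` returning the noise-free HR mean.
#' @param sigma_sample_bpm sample-level noise SD (bpm).
#' @return data frame `timestamp`, `hr_bpm`, `asleep` with strictly
#'   increasing timestamps; HR clamped to the device's plausible (20, 250)
#'   bpm range.
#' @export
simulate_hr_stream <- function(span_start, span_end,
                               sleep_intervals = NULL, bursts = NULL,
                               base_sampling_min = 10, burst_sampling_min = 2,
                               mean_fn = function(time, asleep) 70,
                               sigma_sample_bpm = 0) {
  times <- seq(span_start, span_end - 1, by = base_sampling_min * 60)
  if (!is.null(bursts) && nrow(bursts) > 0) {
    for (i in seq_len(nrow(bursts))) {
      b0 <- bursts$start[i]; b1 <- bursts$end[i]
      times <- times[times < b0 | times >= b1]
      times <- c(times, seq(b0, b1 - 1, by = burst_sampling_min * 60))
    }
    times <- sort(unique(times))
  }
  asleep <- rep(FALSE, length(times))
  if (!is.null(sleep_intervals) && nrow(sleep_intervals) > 0) {
    for (i in seq_len(nrow(sleep_intervals))) {
      asleep <- asleep | (times >= sleep_intervals$start[i] &
                            times <= sleep_intervals$end[i])
    }
  }
  mu <- vapply(seq_along(times),
               function(i) mean_fn(times[i], asleep[i]), numeric(1))
  hr <- mu + stats::rnorm(length(times), 0, sigma_sample_bpm)
  hr <- pmin(pmax(hr, 20.5), 249.5)
  data.frame(timestamp = times, hr_bpm = hr, asleep = asleep)
}

#' Simulate a full smartwatch cohort
#'
#' Generates, for every subject and study day, a nightly sleep-state event
#' sequence ([simulate_night()]) and a heart-rate stream
#' ([simulate_hr_stream()]) whose noise-free mean is
#' `period mean + subject intercept + day-level shift + circadian term +
#' treatment effect`, where the day-level shift is the within-subject
#' day-to-day variation (SD `sigma_w_bpm`, drawn per subject-day-period).
#' The treatment effect applies in the active arm only, per
#' `config$effect_profile_bpm`: awake samples take the effect of the
#' calendar study day, asleep samples the effect of the night's attributed
#' day. A ground-truth record (subject intercepts, true `(day, period)`
#' means, and true sleep intervals) is returned for recovery testing.
#'
#' @param config a [generator_config()].
#' @return list of class `"hr_cohort"` with elements `hr` (subject_id,
#'   timestamp, hr_bpm), `sleep` (subject_id, timestamp, state),
#'   `allocation` (subject_id, arm, anchor_date) and `truth` (list:
#'   `intercepts`, `true_means`, `nights`). Deterministic given
#'   `config$seed`.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 2, seed = 7))
#' head(cohort$hr)
#' @export
simulate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- subject_ids(n)
  arms <- allocate_arms(n, config$allocation_ratio)
  anchor <- anchor_time(config$anchor_date)
  days <- config$study_days

  eff <- config$effect_profile_bpm
  effect_of <- function(day, period, arm) {
    if (arm != "active" || is.null(eff) || nrow(eff) == 0) return(0)
    hit <- eff$day == day & eff$period == period
    if (any(hit)) eff$shift[which(hit)[1]] else 0
  }

  intercepts <- stats::rnorm(n, 0, config$sigma_b_bpm)

  hr_list <- list(); sleep_list <- list(); night_list <- list()
  truth_rows <- list()

  for (s in seq_len(n)) {
    b_i <- intercepts[s]; arm <- arms[s]
    # within-subject day-to-day level shifts, one per (day, period)
    day_shift <- matrix(stats::rnorm(2 * length(days), 0, config$sigma_w_bpm),
                        nrow = length(days), ncol = 2,
                        dimnames = list(as.character(days),
                                        c("awake", "asleep")))

    u_sleep <- stats::rnorm(1, 0, config$sleep_duration_sd_h *
                              sqrt(config$sleep_duration_icc))
    nights <- lapply(days, function(d) simulate_night(d, config, u_sleep))
    night_df <- data.frame(
      subject_id = ids[s],
      night_day = days,
      start = as.POSIXct(vapply(nights, function(x) as.numeric(x$start), 0),
                         origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(vapply(nights, function(x) as.numeric(x$end), 0),
                       origin = "1970-01-01", tz = "UTC"),
      duration_h = vapply(nights, function(x) x$duration_h, 0),
      missing = vapply(nights, function(x) x$missing, TRUE),
      short = vapply(nights, function(x) x$short, TRUE),
      stringsAsFactors = FALSE
    )
    night_list[[s]] <- night_df

    ev <- do.call(rbind, lapply(nights, function(x) x$events))
    if (!is.null(ev) && nrow(ev) > 0) {
      sleep_list[[s]] <- data.frame(subject_id = ids[s], ev,
                                    stringsAsFactors = FALSE)
    }

    # one activity burst per study day, placed inside the true awake span
    bursts <- do.call(rbind, lapply(seq_along(days), function(k) {
      d <- days[k]
      if (config$activity_bursts_per_day < 1L || config$burst_len_min <= 0)
        return(NULL)
      awake_from <- if (k == 1L) anchor + d * 86400 + 7 * 3600
                    else night_df$end[k - 1L]
      awake_to <- night_df$start[k] - (config$burst_len_min + 10) * 60
      if (awake_to <= awake_from) return(NULL)
      reps <- config$activity_bursts_per_day
      b0 <- awake_from + stats::runif(reps) *
        as.numeric(difftime(awake_to, awake_from, units = "secs"))
      data.frame(start = b0, end = b0 + config$burst_len_min * 60)
    }))

    shift_of <- function(d, period) {
      key <- as.character(d)
      if (key %in% rownames(day_shift)) day_shift[key, period] else 0
    }
    mean_fn <- function(time, asleep) {
      d_cal <- floor(as.numeric(difftime(time, anchor, units = "days")))
      if (asleep) {
        # attribute to the night's day: a night spans into the next calendar day
        idx <- which(night_df$start <= time & night_df$end >= time)
        d_eff <- if (length(idx)) night_df$night_day[idx[1]] else d_cal
        mu <- config$mu_asleep_bpm + effect_of(d_eff, "asleep", arm) +
          shift_of(d_eff, "asleep")
      } else {
        mu <- config$mu_awake_bpm + effect_of(d_cal, "awake", arm) +
          shift_of(d_cal, "awake")
      }
      mu + b_i + circadian_term(time, config$circadian_amp_bpm,
                                config$circadian_phase_h)
    }

    span_start <- anchor + min(days) * 86400
    span_end <- anchor + (max(days) + 1) * 86400 + 12 * 3600
    stream <- simulate_hr_stream(
      span_start, span_end,
      sleep_intervals = night_df[, c("start", "end")],
      bursts = bursts,
      base_sampling_min = config$base_sampling_min,
      burst_sampling_min = config$burst_sampling_min,
      mean_fn = mean_fn,
      sigma_sample_bpm = config$sigma_sample_bpm
    )
    hr_list[[s]] <- data.frame(subject_id = ids[s],
                               stream[, c("timestamp", "hr_bpm")],
                               stringsAsFactors = FALSE)

    truth_rows[[s]] <- data.frame(
      subject_id = ids[s],
      study_day = rep(days, each = 2),
      period = rep(c("awake", "asleep"), length(days)),
      true_mean = unlist(lapply(days, function(d) c(
        config$mu_awake_bpm + b_i + effect_of(d, "awake", arm) +
          day_shift[as.character(d), "awake"],
        config$mu_asleep_bpm + b_i + effect_of(d, "asleep", arm) +
          day_shift[as.character(d), "asleep"]
      ))),
      intercept = b_i,
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    hr = do.call(rbind, hr_list),
    sleep = if (length(sleep_list)) do.call(rbind, sleep_list) else
      data.frame(subject_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 state = character(), stringsAsFactors = FALSE),
    allocation = data.frame(subject_id = ids, arm = arms,
                            anchor_date = config$anchor_date,
                            stringsAsFactors = FALSE),
    truth = list(
      intercepts = data.frame(subject_id = ids, intercept = intercepts,
                              arm = arms, stringsAsFactors = FALSE),
      true_means = do.call(rbind, truth_rows),
      nights = do.call(rbind, night_list)
    ),
    config = config
  ), class = "hr_cohort")
}

#' @export
print.hr_cohort <- function(x, ...) {
  cat("Synthetic smartwatch cohort:",
      length(unique(x$allocation$subject_id)), "subjects,",
      nrow(x$hr), "HR samples,", nrow(x$sleep), "sleep events\n")
  cat("Arms:", paste(sprintf("%s=%d", names(table(x$allocation$arm)),
                             table(x$allocation$arm)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a marker table directly from the random-intercept model
#'
#' Generates marker values at the level the mixed models consume, bypassing
#' the raw-stream stages: `value(i, d) = mu + fixed(d, arm_i) + b_i + e_id`
#' with `b_i ~ N(0, sigma_b^2)` and `e_id ~ N(0, sigma_w^2)`. Useful for
#' testing the statistics stages against known variance components.
#'
#' @param n_subjects number of subjects.
#' @param days integer vector of study days.
#' @param mu grand mean (bpm).
#' @param sigma_b,sigma_w between-subject and within-subject SDs (bpm).
#' @param effects `NULL`, or a data frame `day`, `arm`, `shift` of fixed
#'   shifts added to the matching cells.
#' @param n_placebo number of placebo subjects (the rest are active).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @param mask optional data frame `subject_id`, `study_day` of cells to
#'   drop (missingness).
#' @return data frame `subject_id`, `study_day`, `arm`, `value_bpm`, with
#'   the subject intercepts attached as `attr(, "intercepts")`.
#' @examples
#' tab <- simulate_marker_table(sigma_b = sqrt(21), sigma_w = 3, seed = 1)
#' head(tab)
#' @export
simulate_marker_table <- function(n_subjects = 12, days = -6:-1, mu = 63.2,
                                  sigma_b = sqrt(21), sigma_w = 3,
                                  effects = NULL,
                                  n_placebo = round(n_subjects / 3),
                                  seed = NULL, mask = NULL) {
  stopifnot(sigma_b >= 0, sigma_w >= 0, n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- subject_ids(n_subjects)
  arms <- c(rep("placebo", n_placebo), rep("active", n_subjects - n_placebo))
  b <- stats::rnorm(n_subjects, 0, sigma_b)
  tab <- expand.grid(study_day = days, subject_id = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("subject_id", "study_day")]
  tab$arm <- arms[match(tab$subject_id, ids)]
  fixed <- rep(0, nrow(tab))
  if (!is.null(effects) && nrow(effects) > 0) {
    key <- paste(tab$study_day, tab$arm)
    ekey <- paste(effects$day, effects$arm)
    hit <- match(key, ekey)
    fixed <- ifelse(is.na(hit), 0, effects$shift[hit])
  }
  tab$value_bpm <- mu + fixed + b[match(tab$subject_id, ids)] +
    stats::rnorm(nrow(tab), 0, sigma_w)
  if (!is.null(mask) && nrow(mask) > 0) {
    drop <- paste(tab$subject_id, tab$study_day) %in%
      paste(mask$subject_id, mask$study_day)
    tab <- tab[!drop, , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "intercepts") <- data.frame(subject_id = ids, arm = arms,
                                        intercept = b,
                                        stringsAsFactors = FALSE)
  tab
}

#' Write a simulated cohort to CSV files
#'
#' Emits `hr.csv`, `sleep.csv`, `allocation.csv` and `truth.csv` in the
#' formats the ingest functions read. Timestamps are ISO-8601 in the fixed
#' study timezone (UTC).
#'
#' @param cohort an `"hr_cohort"` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  paths <- file.path(dir, c("hr.csv", "sleep.csv", "allocation.csv",
                            "truth.csv"))
  hr <- cohort$hr; hr$timestamp <- iso(hr$timestamp)
  utils::write.csv(hr, paths[1], row.names = FALSE, quote = FALSE)
  sl <- cohort$sleep; sl$timestamp <- iso(sl$timestamp)
  utils::write.csv(sl, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$allocation, paths[3], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$truth$true_means, paths[4], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
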