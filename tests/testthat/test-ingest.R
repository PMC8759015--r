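test_that("HR streams are parsed, sorted and deduplicated", {
  df <- data.frame(subject_id = "A",
                   timestamp = c("2020-03-02T10:00:00", "2020-03-02T08:00:00",
                                 "2020-03-02T09:00:00"),
                   hr_bpm = c(70, 60, 65))
  hr <- read_hr_stream(write_csv_tmp(df))
  expect_identical(nrow(hr), 3L)
  expect_true(!is.unsorted(hr$timestamp))
  expect_equal(hr$hr_bpm, c(60, 65, 70))

  # duplicate (subject, timestamp) collapses to the last occurrence
  df2 <- rbind(df, data.frame(subject_id = "A",
                              timestamp = "2020-03-02T08:00:00",
                              hr_bpm = 99))
  hr2 <- read_hr_stream(write_csv_tmp(df2))
  expect_identical(nrow(hr2), 3L)
  expect_equal(hr2$hr_bpm[1], 99)
})

test_that("parse errors name the offending line; empty files are empty streams", {
  bad_state <- data.frame(subject_id = "A", timestamp = "2020-03-02T23:00:00",
                          state = "rem")
  expect_error(read_sleep_events(write_csv_tmp(bad_state)), "rem.*line 1")
  bad_ts <- data.frame(subject_id = "A", timestamp = c(
    "2020-03-02T23:00:00", "not-a-time"), state = c("light", "awake"))
  expect_error(read_sleep_events(write_csv_tmp(bad_ts)), "line 2")
  empty <- data.frame(subject_id = character(), timestamp = character(),
                      hr_bpm = numeric())
  expect_identical(nrow(read_hr_stream(write_csv_tmp(empty))), 0L)
})

test_that("allocation table is validated", {
  al <- data.frame(subject_id = c("A", "B"), arm = c("placebo", "active"),
                   anchor_date = "2020-03-02")
  expect_identical(nrow(read_allocation(write_csv_tmp(al))), 2L)
  expect_error(read_allocation(write_csv_tmp(rbind(al, al[1, ]))),
               "duplicated")
  al$arm[2] <- "verum"
  expect_error(read_allocation(write_csv_tmp(al)), "unknown arm")
})

test_that("sleep intervals follow the first-sleep-to-last-change rule", {
  w0 <- utc("2020-03-02 12:00:00"); w1 <- w0 + 86400
  ev <- data.frame(
    timestamp = utc(c("2020-03-02 23:40:00", "2020-03-03 02:10:00",
                      "2020-03-03 03:00:00", "2020-03-03 06:50:00")),
    state = c("light", "deep", "light", "awake"))
  iv <- reconstruct_sleep_interval(ev, w0, w1, "A", 0L)
  expect_identical(iv$status, "detected")
  expect_identical(iv$start, ev$timestamp[1])
  expect_identical(iv$end, ev$timestamp[4])
  expect_equal(iv$duration_h, 7 + 10 / 60, tolerance = 1e-9)

  short <- data.frame(timestamp = utc(c("2020-03-03 01:00:00",
                                        "2020-03-03 03:30:00")),
                      state = c("light", "awake"))
  expect_identical(reconstruct_sleep_interval(short, w0, w1)$status,
                   "excluded_short")
  expect_identical(reconstruct_sleep_interval(short[0, ], w0, w1)$status,
                   "missing")
  # awake-only events carry no sleep onset
  awake_only <- data.frame(timestamp = utc("2020-03-03 01:00:00"),
                           state = "awake")
  expect_identical(reconstruct_sleep_interval(awake_only, w0, w1)$status,
                   "missing")
})

test_that("night attribution is invariant to whole-day timestamp shifts", {
  co <- simulate_cohort(generator_config(n_subjects = 2, seed = 31))
  al <- co$allocation
  nights <- reconstruct_nights(co$sleep, al, -6:6)
  shifted <- co$sleep
  shifted$timestamp <- shifted$timestamp + 3 * 86400
  nights_s <- reconstruct_nights(shifted, al, -3:9)
  keep <- nights$status != "missing"
  expect_identical(nights$night_day[keep] + 3L, nights_s$night_day[keep])
  expect_identical(nights$status[keep], nights_s$status[keep])
  expect_equal(nights$duration_h[keep], nights_s$duration_h[keep])
})

test_that("dropping non-terminal awake events never changes the interval start
           and never lengthens it", {
  w0 <- utc("2020-03-02 12:00:00"); w1 <- w0 + 86400
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    times <- sort(w0 + 8 * 3600 + runif(n) * 12 * 3600)
    states <- c(sample(c("light", "deep", "awake"), n - 1, replace = TRUE),
                "awake")
    ev <- data.frame(timestamp = times, state = states)
    base <- reconstruct_sleep_interval(ev, w0, w1)
    if (base$status == "missing") next
    drop <- which(ev$state == "awake" & seq_len(n) < n)
    if (!length(drop)) next
    red <- reconstruct_sleep_interval(ev[-drop[1], ], w0, w1)
    expect_identical(red$start, base$start)
    expect_lte(red$duration_h, base$duration_h)
  }
})

test_that("day segmentation matches a per-sample brute-force classifier", {
  anchor <- utc("2020-03-02 00:00:00")
  set.seed(99)
  for (rep in 1:100) {
    day <- sample(-3:3, 1)
    prev_status <- sample(c("detected", "excluded_short", "missing"), 1)
    cur_status <- sample(c("detected", "excluded_short", "missing"), 1)
    prev_night <- make_night("A", day - 1L,
                             anchor + (day - 1) * 86400 + 23 * 3600,
                             anchor + day * 86400 + runif(1, 2, 8) * 3600,
                             prev_status)
    cur_night <- make_night("A", day,
                            anchor + day * 86400 + runif(1, 21, 25) * 3600,
                            anchor + day * 86400 + runif(1, 25, 32) * 3600,
                            cur_status)
    if (prev_status == "missing") prev_night <- NULL
    if (cur_status == "missing") cur_night <- NULL
    t <- anchor + (day - 1) * 86400 + sort(runif(60, 0, 60)) * 3600
    hr <- data.frame(timestamp = t, hr_bpm = round(runif(60, 50, 120), 1))
    seg <- segment_day(hr, day, anchor, prev_night, cur_night)
    lab <- vapply(seq_len(nrow(hr)), function(i) {
      brute_classify_day(hr$timestamp[i], day, anchor, prev_night, cur_night)
    }, character(1))
    expect_equal(sort(seg$awake), sort(hr$hr_bpm[lab == "awake"]))
    expect_equal(sort(c(seg$asleep, numeric(0))),
                 sort(hr$hr_bpm[lab == "asleep"]))
    # partition: every classified sample lands in exactly one period
    expect_identical(length(seg$awake) + length(seg$asleep),
                     sum(lab != "none"))
  }
})

test_that("default awake windows apply when bounding nights are missing", {
  anchor <- utc("2020-03-02 00:00:00")
  t <- anchor + seq(0, 86399, by = 600)
  hr <- data.frame(timestamp = t, hr_bpm = seq_along(t))
  seg <- segment_day(hr, 0L, anchor, NULL, NULL)
  expect_identical(seg$awake_window_source, "default_window")
  in_win <- t > anchor + 9 * 3600 & t < anchor + 21 * 3600
  expect_equal(seg$awake, hr$hr_bpm[in_win])
  expect_null(seg$asleep)
  # zero samples in window: empty awake segment, no error
  seg0 <- segment_day(hr[0, ], 0L, anchor, NULL, NULL)
  expect_length(seg0$awake, 0)
})

test_that("sleep-duration table keeps exactly the detected nights", {
  anchor <- utc("2020-03-02 00:00:00")
  nights <- do.call(rbind, lapply(1:12, function(s) {
    do.call(rbind, lapply(-6:6, function(d) {
      make_night(sprintf("S%02d", s), d,
                 anchor + d * 86400 + 23 * 3600,
                 anchor + (d + 1) * 86400 + 6 * 3600)
    }))
  }))
  nights$status[c(1, 20, 60, 100)] <- "missing"
  tab <- sleep_duration_table(nights)
  expect_identical(nrow(tab), 12L * 13L - 4L)
  nights$status[2] <- "excluded_short"
  expect_identical(nrow(sleep_duration_table(nights)), 12L * 13L - 5L)
  none <- nights; none$status <- "missing"
  expect_identical(nrow(sleep_duration_table(none)), 0L)
  counts <- night_exclusion_counts(nights)
  expect_identical(unname(counts["missing_sleep_states"] +
                            counts["shorter_than_3h"] +
                            counts["detected"]), nrow(nights))
})
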