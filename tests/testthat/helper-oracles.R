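# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# linear-interpolation percentile: sort, index h = (n-1)p, interpolate
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    if (lo >= n - 1) return(s[n])
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  }, numeric(1))
}

# method-of-moments variance components for balanced subject x day data with
# a fixed day effect: two-way ANOVA mean squares, sigma2_w = MSE,
# sigma2_b = (MS_subject - MSE) / n_days
mom_components <- function(tab, value_col = "value_bpm") {
  k <- length(unique(tab$study_day))
  form <- stats::as.formula(
    paste(value_col, "~ factor(study_day) + factor(subject_id)"))
  ms <- summary(stats::aov(form, data = tab))[[1]][["Mean Sq"]]
  list(sigma2_w = ms[3], sigma2_b = (ms[2] - ms[3]) / k)
}

# t quantile by numerically inverting the CDF (independent of qt())
t_quantile_oracle <- function(p, df) {
  stats::uniroot(function(x) stats::pt(x, df) - p, c(-100, 100),
                 tol = 1e-12)$root
}

# per-sample classifier for one study day: literal restatement of the
# segmentation rules, scalar logic only
brute_classify_day <- function(time, day, anchor, prev_night, cur_night) {
  in_night <- function(night, t) {
    !is.null(night) && night$status != "missing" &&
      t >= night$start && t <= night$end
  }
  if (!is.null(cur_night) && cur_night$status == "detected" &&
      time >= cur_night$start && time <= cur_night$end) return("asleep")
  if (!is.null(prev_night) && prev_night$status != "missing") {
    w0 <- prev_night$end
  } else w0 <- anchor + day * 86400 + 9 * 3600
  if (!is.null(cur_night) && cur_night$status != "missing") {
    w1 <- cur_night$start
  } else w1 <- anchor + day * 86400 + 21 * 3600
  if (time > w0 && time < w1 &&
      !in_night(prev_night, time) && !in_night(cur_night, time))
    return("awake")
  "none"
}

# build a one-row night record like reconstruct_nights() emits
make_night <- function(subject_id, day, start, end, status = "detected") {
  data.frame(subject_id = subject_id, night_day = day,
             start = start, end = end,
             duration_h = as.numeric(difftime(end, start, units = "hours")),
             status = status, stringsAsFactors = FALSE)
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

write_csv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
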