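MARKER_LEVELS <- c(low = 0.025, median = 0.5, high = 0.975)

#' Percentile of a heart-rate segment
#'
#' Linear-interpolation percentile between closest ranks, index
#' `h = (n - 1) p` (the "type 7" convention used by mainstream numeric
#' stacks); exact minimum/maximum at `p = 0` / `p = 1`.
#'
#' @param values non-empty numeric vector.
#' @param p fraction in `[0, 1]`.
#' @return the percentile value.
#' @examples
#' hr_percentile(c(50, 60, 70, 80, 90), 0.5)
#' @export
hr_percentile <- function(values, p) {
  if (length(values) == 0) stop("hr_percentile: empty value list",
                                call. = FALSE)
  if (any(!is.finite(values))) stop("hr_percentile: non-finite values",
                                    call. = FALSE)
  if (any(p < 0 | p > 1)) stop("hr_percentile: p must lie in [0, 1]",
                               call. = FALSE)
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Summarize one subject-day-period HR segment into percentile markers
#'
#' Emits the low (2.5th), median (50th) and high (97.5th) percentile marker
#' records. An empty segment yields zero rows (no error).
#'
#' @param values numeric HR values of the segment (bpm).
#' @param subject_id,study_day,arm,period metadata carried into the records.
#' @return data frame with columns `subject_id`, `study_day`, `arm`,
#'   `period`, `marker`, `value_bpm`, `n_samples` (0 or 3 rows).
#' @export
summarize_segment <- function(values, subject_id, study_day,
                              arm = NA_character_, period) {
  empty <- data.frame(subject_id = character(), study_day = integer(),
                      arm = character(), period = character(),
                      marker = character(), value_bpm = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  if (is.null(values) || length(values) == 0) return(empty)
  data.frame(subject_id = subject_id, study_day = study_day, arm = arm,
             period = period, marker = names(MARKER_LEVELS),
             value_bpm = hr_percentile(values, unname(MARKER_LEVELS)),
             n_samples = length(values), stringsAsFactors = FALSE)
}

#' Assemble the long marker table of a cohort
#'
#' Applies [summarize_segment()] to every non-empty subject-day-period
#' segment and joins the treatment arm. Days with absent segments are simply
#' missing (unbalanced data are handled downstream).
#'
#' @param segments long data frame from [segment_cohort()] (`subject_id`,
#'   `study_day`, `period`, `value_bpm`).
#' @param allocation data frame from [read_allocation()]; every subject in
#'   `segments` must appear here.
#' @return data frame keyed `(subject_id, study_day, period, marker)` with
#'   `arm`, `value_bpm`, `n_samples`.
#' @export
build_marker_table <- function(segments, allocation) {
  if (nrow(segments) == 0) {
    return(summarize_segment(numeric(0), "x", 0L, period = "awake"))
  }
  unknown <- setdiff(unique(segments$subject_id), allocation$subject_id)
  if (length(unknown))
    stop("build_marker_table: subjects absent from allocation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  key <- interaction(segments$subject_id, segments$study_day,
                     segments$period, drop = TRUE)
  pieces <- lapply(split(segments, key), function(g) {
    summarize_segment(g$value_bpm, g$subject_id[1], g$study_day[1],
                      allocation$arm[match(g$subject_id[1],
                                           allocation$subject_id)],
                      g$period[1])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$subject_id, out$study_day, out$period, out$marker), ]
  rownames(out) <- NULL
  out
}
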