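#' Pipeline configuration
#'
#' Collects every analysis constant of the end-to-end pipeline so nothing is
#' hard-coded: significance level and power of the MDE, its formula variant,
#' the Bonferroni family size, the predose window, and the embedded
#' generator configuration used by [simulate_to_csv()] and [run_recovery()].
#'
#' @param alpha two-sided false-positive probability (default .05).
#' @param power target power of the MDE (default .80).
#' @param mde_form `"two_sample"` or `"paired"`.
#' @param bonferroni_family `NULL` (postdose days x arms, i.e. 14) or an
#'   explicit count.
#' @param predose_days,postdose_days study-day windows.
#' @param study_days full study-day range.
#' @param percentile_convention tag recorded in outputs; only the
#'   linear-interpolation ("type7") convention is implemented.
#' @param generator a [generator_config()].
#' @param seed integer seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha = 0.05, power = 0.80,
                            mde_form = "two_sample",
                            bonferroni_family = NULL,
                            predose_days = -6:-1, postdose_days = 0:6,
                            study_days = -6:6,
                            percentile_convention = "type7",
                            generator = generator_config(), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (max(predose_days) >= 0)
    stop("pipeline_config: predose window must precede day 0", call. = FALSE)
  structure(list(alpha = alpha, power = power, mde_form = mde_form,
                 bonferroni_family = bonferroni_family,
                 predose_days = as.integer(predose_days),
                 postdose_days = as.integer(postdose_days),
                 study_days = as.integer(study_days),
                 percentile_convention = percentile_convention,
                 generator = generator, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys override [pipeline_config()] defaults; keys under `generator:`
#' override [generator_config()] defaults.
#'
#' @param path YAML file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  raw$generator <- NULL
  gen <- do.call(generator_config, if (is.null(gen_args)) list() else gen_args)
  do.call(pipeline_config, c(raw, list(generator = gen)))
}

#' Simulate a cohort and write its CSV inputs
#'
#' @param config a `"pipeline_config"`.
#' @param dir output directory.
#' @return invisibly, the file paths written.
#' @export
simulate_to_csv <- function(config, dir) {
  cohort <- simulate_cohort(config$generator)
  write_cohort_csv(cohort, dir)
}

#' Run the full analysis pipeline
#'
#' Reads the HR, sleep-event and allocation CSVs, reconstructs nights,
#' segments days, builds the marker table, and writes the five report
#' tables: `repeatability.csv` (per-marker mean, ICC, MDE, day F test),
#' `anova.csv` (type III F tests of the treatment models), `contrasts.csv`
#' (postdose-vs-baseline contrasts, Bonferroni-adjusted), `effect_sizes.csv`
#' (Cohen's d) and `sleep_model.csv`, plus `run_log.txt` recording the seed,
#' row counts and the excluded nights split by cause.
#'
#' @param hr_path,sleep_path,allocation_path input CSV paths.
#' @param out_dir output directory (created if needed).
#' @param config a `"pipeline_config"`.
#' @return invisibly, a list with the in-memory tables.
#' @export
run_pipeline <- function(hr_path, sleep_path, allocation_path, out_dir,
                         config = pipeline_config()) {
  for (p in c(hr_path, sleep_path, allocation_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  hr <- read_hr_stream(hr_path)
  sleep <- read_sleep_events(sleep_path)
  allocation <- read_allocation(allocation_path)

  nights <- reconstruct_nights(sleep, allocation, config$study_days)
  segs <- segment_cohort(hr, nights, allocation, config$study_days)
  markers <- build_marker_table(segs$segments, allocation)
  durations <- sleep_duration_table(nights, allocation)

  rep_tab <- repeatability_table(markers, config$predose_days,
                                 alpha = config$alpha, power = config$power,
                                 form = config$mde_form)

  combos <- unique(markers[, c("period", "marker")])
  anova_rows <- list(); contrast_rows <- list(); d_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sl <- markers[markers$period == combos$period[i] &
                    markers$marker == combos$marker[i], , drop = FALSE]
    fit <- fit_treatment_model(sl)
    if (!isTRUE(fit$converged))
      stop("treatment model failed to converge for marker ",
           combos$period[i], "-", combos$marker[i], call. = FALSE)
    at <- anova_table(fit)
    at <- cbind(period = combos$period[i], marker = combos$marker[i], at)
    anova_rows[[i]] <- at
    ct <- baseline_contrasts(fit, config$predose_days, config$postdose_days,
                             config$bonferroni_family)
    dd <- cohens_d(ct, fit)
    contrast_rows[[i]] <- cbind(period = combos$period[i],
                                marker = combos$marker[i],
                                as.data.frame(ct))
    d_rows[[i]] <- cbind(period = combos$period[i],
                         marker = combos$marker[i], dd)
  }
  anova_tab <- do.call(rbind, anova_rows)
  contrast_tab <- do.call(rbind, contrast_rows)
  contrast_tab$p_adj_display <- pmin(contrast_tab$p_adj, 0.99)
  effect_tab <- do.call(rbind, d_rows)

  sleep_fit <- sleep_duration_model(durations)
  sleep_tab <- cbind(sleep_fit$anova,
                     icc = sleep_fit$icc$icc,
                     sigma2_b = sleep_fit$icc$sigma2_b,
                     sigma2_w = sleep_fit$icc$sigma2_w)

  wcsv <- function(x, name) utils::write.csv(
    x, file.path(out_dir, name), row.names = FALSE)
  wcsv(rep_tab, "repeatability.csv")
  wcsv(anova_tab, "anova.csv")
  wcsv(contrast_tab, "contrasts.csv")
  wcsv(effect_tab, "effect_sizes.csv")
  wcsv(sleep_tab, "sleep_model.csv")
  wcsv(markers, "markers.csv")
  wcsv(durations, "sleep_durations.csv")

  excl <- night_exclusion_counts(nights)
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("subjects: %d", nrow(allocation)),
    sprintf("hr_samples: %d", nrow(hr)),
    sprintf("sleep_events: %d", nrow(sleep)),
    sprintf("marker_rows: %d", nrow(markers)),
    sprintf("nights_detected: %d", excl[["detected"]]),
    sprintf("nights_excluded_missing_sleep_states: %d",
            excl[["missing_sleep_states"]]),
    sprintf("nights_excluded_shorter_than_3h: %d",
            excl[["shorter_than_3h"]]))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(markers = markers, durations = durations,
                 repeatability = rep_tab, anova = anova_tab,
                 contrasts = contrast_tab, effect_sizes = effect_tab,
                 sleep_model = sleep_tab, nights = nights,
                 exclusions = excl))
}

#' Replicate parameter-recovery study
#'
#' Repeatedly generates marker tables from the random-intercept model with
#' known variance components, runs the repeatability fit, and summarises how
#' well the ICC is recovered — the package's operating-characteristic check.
#'
#' @param icc_true generating ICC values.
#' @param sigma2_tot total generating variance (bpm^2).
#' @param n_subjects,days design of each replicate study.
#' @param replicates number of replicate studies per ICC value.
#' @param seed integer seed.
#' @return data frame `icc_true`, `icc_mean`, `icc_sd`, `replicates`.
#' @export
run_recovery <- function(icc_true = c(0.70, 0.64, 0.23), sigma2_tot = 30,
                         n_subjects = 12, days = -6:-1, replicates = 200,
                         seed = 1L) {
  set.seed(seed)
  rows <- lapply(icc_true, function(r) {
    s2b <- r * sigma2_tot; s2w <- (1 - r) * sigma2_tot
    est <- vapply(seq_len(replicates), function(i) {
      tab <- simulate_marker_table(n_subjects = n_subjects, days = days,
                                   sigma_b = sqrt(s2b), sigma_w = sqrt(s2w))
      icc(fit_random_intercept(tab))$icc
    }, numeric(1))
    data.frame(icc_true = r, icc_mean = mean(est), icc_sd = stats::sd(est),
               replicates = replicates)
  })
  do.call(rbind, rows)
}

#' Plot a subject's daily heart-rate profile
#'
#' Base-graphics view of one subject's HR stream against clock time: all
#' samples pooled over days, with the median and the 2.5th/97.5th percentile
#' envelope per clock hour.
#'
#' @param hr data frame from [read_hr_stream()] (or `cohort$hr`).
#' @param subject subject identifier.
#' @param ... passed to [plot()].
#' @return invisibly, the hourly summary table.
#' @export
plot_day_profile <- function(hr, subject, ...) {
  s <- hr[hr$subject_id == subject, , drop = FALSE]
  if (nrow(s) == 0) stop("no samples for subject ", subject, call. = FALSE)
  hour <- as.numeric(format(s$timestamp, "%H")) +
    as.numeric(format(s$timestamp, "%M")) / 60
  bin <- floor(hour)
  qs <- t(vapply(split(s$hr_bpm, bin),
                 function(v) stats::quantile(v, c(0.025, 0.5, 0.975),
                                             names = FALSE),
                 numeric(3)))
  h <- as.numeric(rownames(qs)) + 0.5
  plot(h, qs[, 2], type = "l", lwd = 2, ylim = range(qs),
       xlab = "Clock time (h)", ylab = "Heart rate (bpm)",
       main = paste("Daily HR profile:", subject), ...)
  graphics::lines(h, qs[, 1], lty = 2)
  graphics::lines(h, qs[, 3], lty = 2)
  invisible(data.frame(hour = h, low = qs[, 1], median = qs[, 2],
                       high = qs[, 3]))
}
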