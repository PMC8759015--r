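#' Fit a random-intercept repeatability model to one marker
#'
#' Fits, by restricted maximum likelihood, the Gaussian linear mixed model
#' `value ~ day` with a subject-level random intercept — the model used to
#' quantify day-to-day repeatability of a marker over the predose window.
#' Day enters as a categorical fixed effect with sum-to-zero coding, so the
#' intercept is the marker's estimated mean across day levels and marginal
#' (type III) F tests are well-defined.
#'
#' @param data data frame with columns `subject_id`, `study_day` and
#'   `value_bpm` (unbalanced data allowed; `NA` values dropped).
#' @param value_col name of the response column (default `"value_bpm"`).
#' @return an object of class `"hr_lmm"`: the underlying [nlme::lme] fit
#'   plus the extracted fixed effects, between-subject variance `sigma2_b`,
#'   within-subject residual variance `sigma2_w`, and a convergence flag.
#'   A non-converged fit is returned flagged, and downstream operations
#'   refuse it.
#' @examples
#' tab <- simulate_marker_table(sigma_b = sqrt(21), sigma_w = 3, seed = 1)
#' fit <- fit_random_intercept(tab)
#' icc(fit)
#' @export
fit_random_intercept <- function(data, value_col = "value_bpm") {
  d <- prepare_model_frame(data, value_col)
  if (nlevels(d$subject_id) < 2)
    stop("fit_random_intercept: at least 2 subjects are required ",
         "(between-subject variance unidentifiable)", call. = FALSE)
  if (nlevels(d$day_f) < 2)
    stop("fit_random_intercept: at least 2 distinct days are required",
         call. = FALSE)
  wrap_lme(d, model = "repeatability")
}

prepare_model_frame <- function(data, value_col) {
  need <- c("subject_id", "study_day", value_col)
  if (!all(need %in% names(data)))
    stop("missing required columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  d <- data.frame(subject_id = factor(data$subject_id),
                  day_f = factor(data$study_day),
                  value = as.numeric(data[[value_col]]),
                  stringsAsFactors = FALSE)
  if ("arm" %in% names(data))
    d$arm <- factor(data$arm, levels = c("placebo", "active"))
  d <- d[is.finite(d$value), , drop = FALSE]
  d$subject_id <- droplevels(d$subject_id)
  d$day_f <- droplevels(d$day_f)
  d
}

wrap_lme <- function(d, model) {
  contr <- if (model == "treatment")
    list(day_f = "contr.sum", arm = "contr.sum") else
    list(day_f = "contr.sum")
  fixed_formula <- stats::as.formula(
    paste("value ~", if (model == "treatment") "day_f * arm" else "day_f"))
  fit <- tryCatch(
    nlme::lme(fixed = fixed_formula, random = ~ 1 | subject_id, data = d,
              method = "REML", na.action = stats::na.omit,
              contrasts = contr,
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         niterEM = 50, tolerance = 1e-8,
                                         returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(lme = NULL, model = model, converged = FALSE,
                message = conditionMessage(fit),
                sigma2_b = NA_real_, sigma2_w = NA_real_,
                fixed_effects = NULL, n_subjects = nlevels(d$subject_id),
                n_obs = nrow(d), fit_method = "REML", data = d)
    class(out) <- "hr_lmm"
    return(out)
  }
  vc <- nlme::VarCorr(fit)
  sigma2_b <- max(as.numeric(vc["(Intercept)", "Variance"]), 0)
  sigma2_w <- fit$sigma^2
  tt <- summary(fit)$tTable
  fe <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                   se = tt[, "Std.Error"], df = tt[, "DF"],
                   stringsAsFactors = FALSE, row.names = NULL)
  out <- list(lme = fit, model = model, converged = TRUE, message = NULL,
              sigma2_b = sigma2_b, sigma2_w = sigma2_w,
              fixed_effects = fe, n_subjects = nlevels(d$subject_id),
              n_obs = nrow(d), fit_method = "REML", data = d)
  class(out) <- "hr_lmm"
  out
}

assert_converged <- function(fit) {
  stopifnot(inherits(fit, "hr_lmm"))
  if (!isTRUE(fit$converged))
    stop("model did not converge: ", fit$message, call. = FALSE)
  invisible(fit)
}

#' Intraclass correlation coefficient
#'
#' The repeatability index: between-subject variance divided by the total
#' (between-subject plus within-subject) variance, clamped to `[0, 1]`.
#'
#' @param x an `"hr_lmm"` fit, or the between-subject variance `sigma2_b`.
#' @param ... for the numeric method, `sigma2_w` (within-subject variance).
#' @return object of class `"icc_result"`: `icc`, `sigma2_b`, `sigma2_w`.
#' @examples
#' icc(21, 9) # 0.70
#' @export
icc <- function(x, ...) UseMethod("icc")

#' @rdname icc
#' @export
icc.hr_lmm <- function(x, ...) {
  assert_converged(x)
  icc(x$sigma2_b, x$sigma2_w)
}

#' @rdname icc
#' @param sigma2_w within-subject variance (numeric method).
#' @export
icc.numeric <- function(x, sigma2_w, ...) {
  sigma2_b <- x
  stopifnot(sigma2_b >= 0, sigma2_w >= 0)
  tot <- sigma2_b + sigma2_w
  if (tot <= 0) stop("icc: total variance is zero", call. = FALSE)
  structure(list(icc = min(max(sigma2_b / tot, 0), 1),
                 sigma2_b = sigma2_b, sigma2_w = sigma2_w),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f  (sigma2_b = %.3f, sigma2_w = %.3f)\n",
              x$icc, x$sigma2_b, x$sigma2_w))
  invisible(x)
}

#' Marginal (type III) F test for the day effect
#'
#' Tests whether structural day-to-day variability is present in a
#' repeatability fit. Numerator df equals the number of day levels minus
#' one; the denominator df is nlme's between-within (containment)
#' approximation.
#'
#' @param fit a converged `"hr_lmm"` from [fit_random_intercept()].
#' @return object of class `"hr_ftest"`: `statistic`, `df_num`, `df_den`,
#'   `p_value`, `term`.
#' @export
day_f_test <- function(fit) {
  assert_converged(fit)
  a <- stats::anova(fit$lme, type = "marginal")
  if (!"day_f" %in% rownames(a))
    stop("day_f_test: no day term in the model", call. = FALSE)
  structure(list(statistic = a["day_f", "F-value"],
                 df_num = a["day_f", "numDF"],
                 df_den = a["day_f", "denDF"],
                 p_value = a["day_f", "p-value"],
                 term = "day"),
            class = "hr_ftest")
}

#' @export
print.hr_ftest <- function(x, ...) {
  cat(sprintf("Type III F(%g, %.1f) = %.3f for %s, p = %.3g\n",
              x$df_num, x$df_den, x$statistic, x$term, x$p_value))
  invisible(x)
}

#' Minimum detectable effect
#'
#' Inverse sample-size calculation: the smallest true difference detectable
#' with `n` subjects at two-sided significance level `alpha` and the given
#' power, using quantiles of the t distribution with `n - 1` degrees of
#' freedom and the marker's total SD (square root of the sum of
#' between-subject and within-subject variance):
#' `MDE = (t[1 - alpha/2, n-1] + t[power, n-1]) * sd_total * sqrt(2/n)`
#' for the two-sample (parallel-group) form; the paired form replaces
#' `sqrt(2/n)` by `sqrt(1/n)`.
#'
#' @param sd_total_bpm total SD in bpm (>= 0).
#' @param n sample size (>= 2).
#' @param alpha two-sided false-positive probability.
#' @param power target power.
#' @param form `"two_sample"` (default) or `"paired"`.
#' @param mean_bpm optional marker mean; if given, `mde_pct` is reported
#'   relative to it.
#' @return object of class `"mde_result"`: `mde_bpm`, `mde_pct`,
#'   `sd_total_bpm`, `n`, `alpha`, `power`, `form`.
#' @examples
#' mde(5.446, n = 12)$mde_bpm # 6.84
#' @export
mde <- function(sd_total_bpm, n = 12, alpha = 0.05, power = 0.80,
                form = c("two_sample", "paired"), mean_bpm = NULL) {
  form <- match.arg(form)
  if (!is.finite(sd_total_bpm) || sd_total_bpm < 0)
    stop("mde: sd_total_bpm must be >= 0", call. = FALSE)
  if (n < 2) stop("mde: n must be at least 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("mde: alpha and power must lie in (0, 1)", call. = FALSE)
  tq <- stats::qt(1 - alpha / 2, n - 1) + stats::qt(power, n - 1)
  scale <- if (form == "two_sample") sqrt(2 / n) else sqrt(1 / n)
  mde_bpm <- tq * sd_total_bpm * scale
  structure(list(mde_bpm = mde_bpm,
                 mde_pct = if (is.null(mean_bpm)) NA_real_ else
                   100 * mde_bpm / mean_bpm,
                 sd_total_bpm = sd_total_bpm, n = n, alpha = alpha,
                 power = power, form = form),
            class = "mde_result")
}

#' @export
print.mde_result <- function(x, ...) {
  cat(sprintf("MDE = %.2f bpm", x$mde_bpm))
  if (is.finite(x$mde_pct)) cat(sprintf(" (%.1f%%)", x$mde_pct))
  cat(sprintf("  [sd = %.3f, n = %d, alpha = %.2f, power = %.2f, %s]\n",
              x$sd_total_bpm, as.integer(x$n), x$alpha, x$power, x$form))
  invisible(x)
}

#' Repeatability summary over all markers
#'
#' For every period x marker combination, restricts the marker table to the
#' predose window, fits the random-intercept model, and reports the
#' estimated mean, its SE, the ICC, the MDE (absolute and relative to the
#' estimated mean) and the type III day F test.
#'
#' @param markers marker table from [build_marker_table()].
#' @param predose_days days forming the predose window (default `-6:-1`).
#' @param n sample size used in the MDE calculation; defaults to the number
#'   of subjects in the table.
#' @param alpha,power,form passed to [mde()].
#' @return data frame with one row per marker: `period`, `marker`,
#'   `mean_bpm`, `se`, `icc`, `mde_bpm`, `mde_pct`, `f_day`, `df_num`,
#'   `df_den`, `p_day`.
#' @export
repeatability_table <- function(markers, predose_days = -6:-1, n = NULL,
                                alpha = 0.05, power = 0.80,
                                form = "two_sample") {
  pre <- markers[markers$study_day %in% predose_days, , drop = FALSE]
  if (is.null(n)) n <- length(unique(markers$subject_id))
  combos <- expand.grid(period = c("asleep", "awake"),
                        marker = c("low", "median", "high"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sl <- pre[pre$period == combos$period[i] &
                pre$marker == combos$marker[i], , drop = FALSE]
    fit <- fit_random_intercept(sl)
    assert_converged(fit)
    mean_bpm <- fit$fixed_effects$estimate[1] # sum-coded intercept
    se <- fit$fixed_effects$se[1]
    ic <- icc(fit)
    md <- mde(sqrt(fit$sigma2_b + fit$sigma2_w), n = n, alpha = alpha,
              power = power, form = form, mean_bpm = mean_bpm)
    ft <- day_f_test(fit)
    data.frame(period = combos$period[i], marker = combos$marker[i],
               mean_bpm = mean_bpm, se = se, icc = ic$icc,
               mde_bpm = md$mde_bpm, mde_pct = md$mde_pct,
               f_day = ft$statistic, df_num = ft$df_num,
               df_den = ft$df_den, p_day = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
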