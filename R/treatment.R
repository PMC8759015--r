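#' Fit the treatment model to one marker
#'
#' REML fit of the Gaussian linear mixed model
#' `value ~ day + arm + day:arm` with a subject-level random intercept, on
#' all study days. Day and arm are categorical (sum-to-zero coding);
#' type III F statistics for the main and interaction terms come from
#' [anova_table()].
#'
#' @param data data frame with columns `subject_id`, `study_day`, `arm` and
#'   the response (unbalanced data allowed).
#' @param value_col name of the response column (default `"value_bpm"`).
#' @return an `"hr_lmm"` object (see [fit_random_intercept()]).
#' @export
fit_treatment_model <- function(data, value_col = "value_bpm") {
  if (!"arm" %in% names(data))
    stop("fit_treatment_model: an 'arm' column is required", call. = FALSE)
  d <- prepare_model_frame(data, value_col)
  d$arm <- droplevels(d$arm)
  if (nlevels(d$arm) < 2)
    stop("fit_treatment_model: both arms must be present", call. = FALSE)
  if (nlevels(d$subject_id) < 2)
    stop("fit_treatment_model: at least 2 subjects are required",
         call. = FALSE)
  wrap_lme(d, model = "treatment")
}

#' Type III F table of a treatment fit
#'
#' @param fit a converged `"hr_lmm"` from [fit_treatment_model()].
#' @return data frame `term` (`day`, `treatment`, `day:treatment`), `F`,
#'   `df_num`, `df_den`, `p`.
#' @export
anova_table <- function(fit) {
  assert_converged(fit)
  a <- stats::anova(fit$lme, type = "marginal")
  keep <- setdiff(rownames(a), "(Intercept)")
  out <- data.frame(term = keep, F = a[keep, "F-value"],
                    df_num = a[keep, "numDF"], df_den = a[keep, "denDF"],
                    p = a[keep, "p-value"], stringsAsFactors = FALSE,
                    row.names = NULL)
  out$term <- c(day_f = "day", arm = "treatment",
                `day_f:arm` = "day:treatment")[out$term]
  out
}

# estimated marginal means for every (day, arm) cell: model-matrix rows
# applied to the fixed-effect estimates (contrast-coding invariant)
cell_means <- function(fit) {
  assert_converged(fit)
  d <- fit$data
  grid <- expand.grid(day_f = levels(d$day_f), arm = levels(d$arm),
                      KEEP.OUT.ATTRS = FALSE)
  X <- stats::model.matrix(~ day_f * arm, grid,
                           contrasts.arg = fit$lme$contrasts)
  list(grid = grid, X = X, beta = nlme::fixef(fit$lme),
       V = stats::vcov(fit$lme))
}

#' Postdose-versus-baseline contrasts
#'
#' For each arm and each dosing day, estimates the linear contrast between
#' that day's estimated marginal mean and the average of the predose-day
#' marginal means (weights +1 on the dosing day, -1/6 on each of the six
#' predose days, within arm). Standard errors come from the fixed-effect
#' covariance; p-values use the t distribution with the interaction term's
#' between-within denominator df; Bonferroni adjustment multiplies each
#' p-value by the family size (all postdose-day x arm contrasts of the
#' model, 14 by default), capped at 1.
#'
#' @param fit a converged `"hr_lmm"` from [fit_treatment_model()].
#' @param predose_days baseline days (default `-6:-1`).
#' @param postdose_days dosing days (default `0:6`).
#' @param family_size Bonferroni family; default
#'   `length(postdose_days) * number of arms`.
#' @return data frame of class `"hr_contrasts"`: `arm`, `day`,
#'   `estimate_bpm`, `se_bpm`, `df`, `p_raw`, `p_adj`, `family_size`.
#'   A dosing day absent from the data is omitted with a warning.
#' @export
baseline_contrasts <- function(fit, predose_days = -6:-1,
                               postdose_days = 0:6, family_size = NULL) {
  cm <- cell_means(fit)
  day_levels <- levels(fit$data$day_f)
  arms <- levels(fit$data$arm)
  pre <- as.character(predose_days)
  if (!all(pre %in% day_levels))
    stop("baseline_contrasts: predose days missing from the fit: ",
         paste(setdiff(pre, day_levels), collapse = ", "), call. = FALSE)
  post <- as.character(postdose_days)
  absent <- setdiff(post, day_levels)
  if (length(absent)) {
    warning("baseline_contrasts: omitting dosing days absent from the fit: ",
            paste(absent, collapse = ", "))
    post <- setdiff(post, absent)
  }
  if (is.null(family_size))
    family_size <- length(postdose_days) * length(arms)

  a <- stats::anova(fit$lme, type = "marginal")
  df_den <- if ("day_f:arm" %in% rownames(a)) a["day_f:arm", "denDF"]
            else a["day_f", "denDF"]

  rows <- list()
  for (arm in arms) {
    idx_arm <- cm$grid$arm == arm
    X_pre <- cm$X[idx_arm & cm$grid$day_f %in% pre, , drop = FALSE]
    l_pre <- colMeans(X_pre)
    for (d in post) {
      x_d <- cm$X[idx_arm & cm$grid$day_f == d, , drop = TRUE]
      L <- x_d - l_pre
      est <- sum(L * cm$beta)
      se <- sqrt(drop(t(L) %*% cm$V %*% L))
      t_stat <- est / se
      p_raw <- 2 * stats::pt(-abs(t_stat), df_den)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, day = as.integer(d), estimate_bpm = est, se_bpm = se,
        df = df_den, p_raw = p_raw,
        p_adj = min(1, family_size * p_raw),
        family_size = as.integer(family_size), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hr_contrasts", "data.frame")
  out
}

#' @export
print.hr_contrasts <- function(x, cap = 0.99, digits = 3, ...) {
  shown <- as.data.frame(x)
  shown$p_adj <- pmin(shown$p_adj, cap) # display cap
  print(format(shown, digits = digits), ...)
  invisible(x)
}

#' Cohen's d effect sizes of baseline contrasts
#'
#' Standardizes each contrast by the total SD of the fitted treatment model:
#' `d = estimate / sqrt(sigma2_b + sigma2_w)`.
#'
#' @param contrasts an `"hr_contrasts"` data frame, or a numeric vector of
#'   contrast estimates (bpm).
#' @param fit the converged `"hr_lmm"` the contrasts came from.
#' @return data frame `arm`, `day`, `d` (or a numeric vector when
#'   `contrasts` is numeric).
#' @examples
#' # 16.18 / sqrt(24.01 + 10.63) = 2.75
#' @export
cohens_d <- function(contrasts, fit) {
  assert_converged(fit)
  tot <- fit$sigma2_b + fit$sigma2_w
  if (tot <= 0) stop("cohens_d: total variance is zero", call. = FALSE)
  if (is.numeric(contrasts)) return(contrasts / sqrt(tot))
  data.frame(arm = contrasts$arm, day = contrasts$day,
             d = contrasts$estimate_bpm / sqrt(tot),
             stringsAsFactors = FALSE)
}

#' Treatment model for nightly sleep duration
#'
#' Applies the treatment-model structure (day, arm, day-by-arm fixed
#' effects; subject random intercept) to the detected-night sleep durations,
#' and reports the type III F tests together with the ICC of the duration's
#' variance components.
#'
#' @param durations data frame from [sleep_duration_table()] with an `arm`
#'   column.
#' @return list of class `"sleep_model"`: `anova` (data frame as
#'   [anova_table()]), `icc` (an `"icc_result"`), and the underlying `fit`.
#' @export
sleep_duration_model <- function(durations) {
  fit <- fit_treatment_model(durations, value_col = "duration_h")
  assert_converged(fit)
  structure(list(anova = anova_table(fit), icc = icc(fit), fit = fit),
            class = "sleep_model")
}

#' @export
print.sleep_model <- function(x, ...) {
  cat("Sleep-duration treatment model (REML, subject random intercept)\n")
  print(format(x$anova, digits = 3))
  print(x$icc)
  invisible(x)
}
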