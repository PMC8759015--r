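#' @export
print.hr_lmm <- function(x, ...) {
  kind <- if (x$model == "treatment") "day x treatment" else "repeatability (day)"
  cat(sprintf("Random-intercept LMM (%s, %s)\n", kind, x$fit_method))
  if (!isTRUE(x$converged)) {
    cat("  ** not converged:", x$message, "**\n")
    return(invisible(x))
  }
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  cat(sprintf("  sigma2_b = %.4f   sigma2_w = %.4f   ICC = %.3f\n",
              x$sigma2_b, x$sigma2_w,
              x$sigma2_b / (x$sigma2_b + x$sigma2_w)))
  invisible(x)
}

#' @export
summary.hr_lmm <- function(object, ...) {
  print(object)
  if (isTRUE(object$converged)) {
    cat("Fixed effects (sum-to-zero coding):\n")
    print(format(object$fixed_effects, digits = 4))
    if (object$model == "treatment") {
      cat("Type III F tests:\n")
      print(format(anova_table(object), digits = 4))
    } else {
      print(day_f_test(object))
    }
  }
  invisible(object)
}

#' @export
coef.hr_lmm <- function(object, ...) {
  assert_converged(object)
  nlme::fixef(object$lme)
}

#' @export
predict.hr_lmm <- function(object, newdata = NULL, level = 0, ...) {
  assert_converged(object)
  if (is.null(newdata)) return(stats::predict(object$lme, level = level, ...))
  stats::predict(object$lme, newdata = newdata, level = level, ...)
}

#' @export
residuals.hr_lmm <- function(object, ...) {
  assert_converged(object)
  stats::residuals(object$lme, ...)
}

#' @export
fitted.hr_lmm <- function(object, ...) {
  assert_converged(object)
  stats::fitted(object$lme, ...)
}
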