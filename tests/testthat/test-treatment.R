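make_treatment_table <- function(effects = NULL, sigma_b = sqrt(24.01),
                                 sigma_w = sqrt(10.63), mu = 63.2) {
  simulate_marker_table(12, -6:6, mu = mu, sigma_b = sigma_b,
                        sigma_w = sigma_w, effects = effects, n_placebo = 4)
}

test_that("the treatment model carries the structural degrees of freedom", {
  set.seed(71)
  fit <- fit_treatment_model(make_treatment_table())
  at <- anova_table(fit)
  expect_identical(at$df_num[at$term == "day"], 12L)
  expect_identical(at$df_num[at$term == "treatment"], 1L)
  expect_identical(at$df_num[at$term == "day:treatment"], 12L)
})

test_that("single-arm data are refused", {
  set.seed(72)
  tab <- make_treatment_table()
  expect_error(fit_treatment_model(tab[tab$arm == "active", ]), "both arms")
  noarm <- tab; noarm$arm <- NULL
  expect_error(fit_treatment_model(noarm), "'arm' column")
})

test_that("vanishing noise recovers arm-specific day shifts exactly", {
  eff <- data.frame(day = c(2, 3, 5), arm = "active", shift = c(4, 9, 12))
  set.seed(73)
  tab <- simulate_marker_table(12, -6:6, mu = 63.2, sigma_b = 0,
                               sigma_w = 1e-6, effects = eff, n_placebo = 4)
  fit <- fit_treatment_model(tab)
  ct <- baseline_contrasts(fit)
  act <- ct[ct$arm == "active", ]
  expect_equal(act$estimate_bpm[act$day == 3], 9, tolerance = 1e-4)
  expect_equal(act$estimate_bpm[act$day == 2], 4, tolerance = 1e-4)
  expect_equal(act$estimate_bpm[act$day == 0], 0, tolerance = 1e-4)
  expect_true(all(abs(ct$estimate_bpm[ct$arm == "placebo"]) < 1e-4))
})

test_that("a day-0-only asleep shift appears only in the day-0 active contrast", {
  eff <- data.frame(day = 0, arm = "active", shift = 3.79)
  set.seed(74)
  tab <- simulate_marker_table(12, -6:6, mu = 63.2, sigma_b = 0,
                               sigma_w = 1e-6, effects = eff, n_placebo = 4)
  ct <- baseline_contrasts(fit_treatment_model(tab))
  expect_equal(ct$estimate_bpm[ct$arm == "active" & ct$day == 0], 3.79,
               tolerance = 1e-4)
  others <- ct[!(ct$arm == "active" & ct$day == 0), ]
  expect_true(all(abs(others$estimate_bpm) < 1e-4))
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  set.seed(75)
  ct <- baseline_contrasts(fit_treatment_model(make_treatment_table()))
  expect_identical(nrow(ct), 14L)
  expect_true(all(ct$family_size == 14L))
  expect_equal(ct$p_adj, pmin(1, 14 * ct$p_raw))
  expect_true(all(ct$p_adj >= ct$p_raw))
  # p_raw = 0.1 with family 14 caps at 1
  expect_equal(min(1, 14 * 0.1), 1)
})

test_that("contrast estimates and SEs agree with emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(76)
  eff <- data.frame(day = 0:6, arm = "active",
                    shift = c(3.7, 7.9, 11.87, 16.18, 13.45, 15.48, 15.18))
  fit <- fit_treatment_model(make_treatment_table(effects = eff))
  ct <- baseline_contrasts(fit)
  em <- emmeans::emmeans(fit$lme, ~ day_f | arm, data = fit$data)
  pre <- setNames(rep(-1 / 6, 6), as.character(-6:-1))
  meth <- lapply(0:6, function(d) {
    w <- setNames(rep(0, 13), as.character(-6:6))
    w[names(pre)] <- pre
    w[as.character(d)] <- 1
    w
  })
  s <- summary(emmeans::contrast(em, method = meth))
  expect_equal(sort(ct$estimate_bpm), sort(s$estimate), tolerance = 1e-8)
  expect_equal(sort(ct$se_bpm), sort(s$SE), tolerance = 1e-8)
})

test_that("contrast estimates are unbiased at trial scale", {
  eff <- data.frame(day = c(3, 3), arm = c("active", "placebo"),
                    shift = c(16.18, 0))
  set.seed(77)
  reps <- 200
  est <- t(vapply(seq_len(reps), function(i) {
    ct <- baseline_contrasts(fit_treatment_model(
      make_treatment_table(effects = eff)))
    c(ct$estimate_bpm[ct$arm == "active" & ct$day == 3],
      ct$estimate_bpm[ct$arm == "placebo" & ct$day == 5])
  }, numeric(2)))
  se1 <- sd(est[, 1]) / sqrt(reps)
  se2 <- sd(est[, 2]) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 16.18), 3 * se1)
  expect_lt(abs(mean(est[, 2]) - 0), 3 * se2)
})

test_that("Cohen's d standardizes by the model's total SD", {
  set.seed(78)
  fit <- fit_treatment_model(make_treatment_table())
  # worked example by independent arithmetic: 16.18 / sqrt(34.64) = 2.749
  d_direct <- 16.18 / sqrt(fit$sigma2_b + fit$sigma2_w)
  expect_equal(cohens_d(16.18, fit), d_direct)
  expect_equal(16.18 / sqrt(24.01 + 10.63), 2.749094, tolerance = 1e-6)
  expect_equal(cohens_d(0, fit), 0)
  ct <- baseline_contrasts(fit)
  dd <- cohens_d(ct, fit)
  expect_equal(sign(dd$d), sign(ct$estimate_bpm))
  # doubling both variances divides d by sqrt(2)
  fit2 <- fit
  fit2$sigma2_b <- 2 * fit$sigma2_b
  fit2$sigma2_w <- 2 * fit$sigma2_w
  expect_equal(cohens_d(10, fit2), cohens_d(10, fit) / sqrt(2))
})

test_that("Cohen's d is invariant under adding a constant to all values", {
  set.seed(79)
  tab <- make_treatment_table(effects = data.frame(day = 3, arm = "active",
                                                   shift = 16.18))
  sh <- tab; sh$value_bpm <- sh$value_bpm + 25
  f1 <- fit_treatment_model(tab)
  f2 <- fit_treatment_model(sh)
  d1 <- cohens_d(baseline_contrasts(f1), f1)
  d2 <- cohens_d(baseline_contrasts(f2), f2)
  expect_equal(d1$d, d2$d, tolerance = 1e-6)
})

test_that("null interaction p-values are uniform", {
  set.seed(80)
  p <- vapply(1:500, function(i) {
    at <- anova_table(fit_treatment_model(make_treatment_table()))
    at$p[at$term == "day:treatment"]
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the sleep-duration model reports F tests and the duration ICC", {
  set.seed(81)
  dur <- simulate_marker_table(12, -6:6, mu = 6.5, sigma_b = 0.8,
                               sigma_w = 0.6, n_placebo = 4)
  names(dur)[names(dur) == "value_bpm"] <- "duration_h"
  sm <- sleep_duration_model(dur)
  expect_identical(sm$anova$df_num[sm$anova$term == "day:treatment"], 12L)
  expect_true(sm$icc$icc > 0 && sm$icc$icc < 1)
  # injected +2 h on treatment nights in the active arm is detected
  big <- dur
  up <- big$arm == "active" & big$study_day >= 0
  big$duration_h[up] <- big$duration_h[up] + 2
  sm2 <- sleep_duration_model(big)
  expect_lt(sm2$anova$p[sm2$anova$term == "day:treatment"], 0.001)
})
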