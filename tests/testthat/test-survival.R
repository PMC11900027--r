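mk_records <- function(treatment, time, event = 1, window_start = 0) {
  data.frame(individual = paste0(treatment, seq_along(time)),
             treatment = treatment, time_days = time,
             event = rep_len(event, length(time)),
             window_start = window_start, stringsAsFactors = FALSE)
}

test_that("cox fit is null for symmetric groups and matches the log-rank", {
  rec <- rbind(mk_records("t", c(1, 2, 3, 5)),
               mk_records("control", c(1, 2, 3, 5)))
  cx <- cox_ph(rec, "t")
  expect_equal(cx$beta, 0, tolerance = 1e-8)
  expect_equal(cx$p, 1, tolerance = 1e-6)
  expect_true(cx$converged)
  # 4 subjects, alternating groups: score test equals log-rank chi-square
  rec2 <- rbind(mk_records("t", c(1, 3)), mk_records("control", c(2, 4)))
  cx2 <- cox_ph(rec2, "t")
  expect_equal(cx2$score_chisq, 0.6153846, tolerance = 1e-6)
  sd2 <- survival::survdiff(survival::Surv(time_days, event) ~ treatment,
                            data = rec2)
  expect_equal(cx2$score_chisq, unname(sd2$chisq), tolerance = 1e-8)
})

test_that("cox estimates recover a known hazard ratio and match coxph", {
  set.seed(33)
  n <- 400
  t0 <- rexp(n, 0.1); t1 <- rexp(n, 0.2)
  rec <- rbind(
    mk_records("control", pmin(t0, 20), event = as.integer(t0 <= 20)),
    mk_records("t", pmin(t1, 20), event = as.integer(t1 <= 20))
  )
  cx <- cox_ph(rec, "t")
  expect_lt(abs(cx$beta - log(2)), 3 * cx$se)
  oracle <- survival::coxph(
    survival::Surv(time_days, event) ~ I(treatment == "t"),
    data = rec, ties = "breslow")
  expect_equal(cx$beta, unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(cx$se, unname(sqrt(vcov(oracle)[1, 1])), tolerance = 1e-6)
  # swapping the group labels flips the effect
  rec_sw <- rec
  rec_sw$treatment <- ifelse(rec$treatment == "t", "control", "t")
  cx_sw <- cox_ph(rec_sw, "t")
  expect_equal(cx_sw$beta, -cx$beta, tolerance = 1e-6)
  expect_equal(cx_sw$hazard_ratio, 1 / cx$hazard_ratio, tolerance = 1e-6)
})

test_that("monotone likelihoods fall back to the score test", {
  rec <- rbind(mk_records("t", c(1, 2, 3)),
               mk_records("control", c(10, 11, 12)))
  expect_warning(cx <- cox_ph(rec, "t"), "monotone")
  expect_false(is.finite(cx$beta))
  expect_true(cx$monotone)
  expect_equal(cx$p, cx$score_p)
  expect_lt(cx$p, 0.2)
})

test_that("acute records are re-zeroed to the exposure window", {
  rec <- rbind(
    mk_records("t", c(5, 12.5, 13, 14), event = c(1, 1, 1, 0),
               window_start = 12),
    mk_records("control", c(8, 13.5, 14, 14), event = c(1, 1, 0, 0),
               window_start = 0)
  )
  cx <- suppressWarnings(cox_ph(rec, "t"))
  # pre-window individuals (times 5 and 8) are excluded from both arms
  expect_equal(cx$n, 6)
  expect_equal(cx$events, 3)
})

test_that("Kaplan-Meier mortality matches the product-limit computation", {
  rec <- mk_records("t", c(3, 5, 8), event = 0)
  expect_equal(survival_proportion(rec, "t", 14), 0)
  rec2 <- mk_records("t", 1:10, event = c(rep(1, 3), rep(0, 7)))
  expect_equal(survival_proportion(rec2, "t", 10), 0.3)
  # staggered censoring fixture: S(4) = 5/6 * 3/4 * 2/3 = 5/12
  rec3 <- mk_records("t", 1:6, event = c(1, 0, 1, 1, 0, 1))
  expect_equal(survival_proportion(rec3, "t", 4), 1 - 5 / 12,
               tolerance = 1e-9)
  # non-increasing survival in the horizon
  horizons <- c(1, 2, 3, 4, 5, 6)
  mort <- vapply(horizons, function(h) survival_proportion(rec3, "t", h),
                 numeric(1))
  expect_true(all(diff(mort) >= -1e-12))
})

test_that("intake OLS equals the normal-equation solution", {
  rec <- data.frame(
    microcolony = rep(c("m1", "m2", "m3", "m4"), each = 3),
    colony = rep(c(1, 2, 1, 2), each = 3),
    treatment = rep(c("control", "control", "t_chronic", "t_chronic"),
                    each = 3),
    day = rep(c(2, 4, 6), 4),
    intake_ml_per_bee = c(1.0, 1.1, 1.2, 1.1, 1.2, 1.3,
                          0.9, 0.8, 0.7, 1.0, 0.9, 0.8)
  )
  fit <- intake_ols(rec)
  X <- model.matrix(~ factor(colony) + day * relevel(factor(treatment),
                                                     "control"),
                    data = rec)
  beta <- solve(crossprod(X), crossprod(X, rec$intake_ml_per_bee))
  expect_equal(unname(fit$coefficients$estimate), unname(drop(beta)),
               tolerance = 1e-10)
  # all-identical treatments: interaction terms vanish
  rec0 <- rec
  rec0$intake_ml_per_bee <- rep(c(1.0, 1.1, 1.2), 4)
  f0 <- intake_ols(rec0)
  ia <- grep("^day:", f0$coefficients$term)
  expect_equal(f0$coefficients$estimate[ia], 0, tolerance = 1e-10)
})

test_that("ppb conversion reproduces the feeding-solution concentrations", {
  expect_identical(ppb_concentration(5), 4.4)
  expect_identical(ppb_concentration(25), 22.1)
  expect_identical(ppb_concentration(0), 0)
  expect_error(ppb_concentration(5, 0), "positive")
})

test_that("cumulative dose arithmetic and equality construction hold", {
  # 10 mL of solution at 5 ug/L shared by 6 bees
  rec <- data.frame(microcolony = "m1", colony = 1, treatment = "t",
                    day = c(2, 4), intake_ml_per_bee = c(4, 6))
  cd <- cumulative_dose(rec, 5, bees_per_colony = 6, intake_is_total = TRUE)
  expect_equal(cd$median_dose_ug_per_bee, 0.05 / 6, tolerance = 1e-12)
  # zero intake, zero dose
  rec0 <- transform(rec, intake_ml_per_bee = 0)
  expect_equal(cumulative_dose(rec0, 5)$median_dose_ug_per_bee, 0)
  expect_error(cumulative_dose(transform(rec, intake_ml_per_bee = -1), 5),
               "negative")
  # construction: acute at 25 ug/L over 2 days equals chronic at 5 ug/L
  # over 12 days when chronic intake is 5/6 of acute intake x (2/12) scale
  chronic <- data.frame(microcolony = "c1", colony = 1, treatment = "c",
                        day = seq(4, 14, 2),
                        intake_ml_per_bee = rep(1, 6))
  acute <- data.frame(microcolony = "a1", colony = 1, treatment = "a",
                      day = 14, intake_ml_per_bee = 6 * 5 / 25)
  d_chronic <- cumulative_dose(chronic, 5)$median_dose_ug_per_bee
  d_acute <- cumulative_dose(acute, 25)$median_dose_ug_per_bee
  expect_equal(d_chronic, d_acute, tolerance = 1e-12)
})
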