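#' Cox proportional-hazards comparison of one treatment against control
#'
#' Single binary covariate, Breslow tie handling, partial likelihood
#' maximized by Newton-Raphson. When the treatment group's records carry a
#' positive `window_start` (acute exposure opening two days before the
#' horizon), both arms are restricted to individuals still alive at the
#' window start and times are shifted so the analysis window begins at
#' zero. Monotone partial likelihoods (all events ordered by group) are
#' flagged: the coefficient is reported as non-finite with a warning and
#' the p-value falls back to the score test, which at beta = 0 equals the
#' log-rank chi-square.
#'
#' @param records survival record data frame (`treatment`, `time_days`,
#'   `event`, optional `window_start`).
#' @param treatment,control group labels.
#' @return list of class `cox_result`: beta, se, hazard_ratio, z, p (Wald),
#'   score_chisq, score_p, n, events, monotone flag, converged flag,
#'   ties_method.
#' @export
cox_ph <- function(records, treatment, control = "control") {
  sub <- records[records$treatment %in% c(treatment, control), , drop = FALSE]
  if (!nrow(sub)) stopf("no records for the requested groups")
  ws <- 0
  if ("window_start" %in% names(sub))
    ws <- max(sub$window_start[sub$treatment == treatment], 0)
  if (ws > 0) {
    sub <- sub[sub$time_days > ws, , drop = FALSE]
    sub$time_days <- sub$time_days - ws
  }
  x <- as.numeric(sub$treatment == treatment)
  time <- sub$time_days
  event <- sub$event
  if (!any(x == 1) || !any(x == 0))
    stopf("both groups must be non-empty inside the analysis window")
  if (sum(event) == 0) stopf("no events in the analysis window")

  # Breslow partial likelihood derivatives for a binary covariate
  derivs <- function(beta) {
    ord <- order(time)
    t_o <- time[ord]; x_o <- x[ord]; d_o <- event[ord]
    ex <- exp(beta * x_o)
    # risk-set sums via reverse cumulative sums
    s0 <- rev(cumsum(rev(ex)))
    s1 <- rev(cumsum(rev(x_o * ex)))
    # collapse tied event times
    ev_idx <- which(d_o == 1)
    if (!length(ev_idx)) return(c(U = 0, I = 0))
    first_at <- match(t_o, t_o) # first index of each time value
    u <- 0; info <- 0
    for (tt in unique(t_o[ev_idx])) {
      at <- ev_idx[t_o[ev_idx] == tt]
      d <- length(at)
      r <- first_at[match(tt, t_o)]
      e1 <- s1[r] / s0[r]
      u <- u + sum(x_o[at]) - d * e1
      info <- info + d * (e1 - e1^2) # S2 = S1 for binary x
    }
    c(U = u, I = info)
  }

  d0 <- derivs(0)
  score_chisq <- if (d0[["I"]] > 0) d0[["U"]]^2 / d0[["I"]] else 0
  score_p <- pchisq(score_chisq, 1, lower.tail = FALSE)

  beta <- 0
  converged <- FALSE
  monotone <- FALSE
  for (it in seq_len(50)) {
    d <- derivs(beta)
    if (d[["I"]] <= 1e-12) { monotone <- TRUE; break }
    step <- d[["U"]] / d[["I"]]
    step <- max(min(step, 2), -2) # damp huge steps
    beta <- beta + step
    if (abs(beta) > 15) { monotone <- TRUE; break }
    if (abs(d[["U"]]) < 1e-9 || abs(step) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (monotone) {
    warning("monotone partial likelihood; coefficient unbounded, ",
            "p-value from the score test")
    beta <- sign(d0[["U"]]) * Inf
    se <- NA_real_
    z <- NA_real_
    p <- score_p
  } else {
    info <- derivs(beta)[["I"]]
    se <- 1 / sqrt(info)
    z <- beta / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(beta = beta, se = se, hazard_ratio = exp(beta),
                 z = z, p = p,
                 score_chisq = score_chisq, score_p = score_p,
                 n = nrow(sub), events = sum(event),
                 window_start = ws, monotone = monotone,
                 converged = converged, ties_method = "breslow"),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (Breslow ties): beta = %.4f (SE %.4f), HR = %.3f\n",
              x$beta, x$se, x$hazard_ratio))
  cat(sprintf("Wald p = %.4g; score chi2 = %.3f (p = %.4g); %d events / %d\n",
              x$p, x$score_chisq, x$score_p, x$events, x$n))
  invisible(x)
}

#' Kaplan-Meier mortality proportion at a horizon
#'
#' One minus the product-limit survival estimate at `horizon`; equals the
#' plain death fraction when no censoring occurs before the horizon.
#'
#' @param records survival records.
#' @param treatment group label.
#' @param horizon time point (days).
#' @return mortality proportion in `[0, 1]`.
#' @export
survival_proportion <- function(records, treatment, horizon) {
  sub <- records[records$treatment == treatment, , drop = FALSE]
  if (!nrow(sub)) stopf("no records for treatment %s", treatment)
  fit <- survival::survfit(Surv(time_days, event) ~ 1, data = sub)
  s <- summary(fit, times = horizon, extend = TRUE)$surv
  1 - s
}

#' Linear model of food intake
#'
#' Ordinary least squares of average daily intake per bee on source colony,
#' measurement day, treatment, and the day x treatment interaction (control
#' is the reference level). With `acute_window = TRUE` only measurements on
#' days 12 (last pre-exposure day) and 14 (sampling day) enter, matching
#' the two-day acute exposure.
#'
#' @param records intake records (`colony`, `treatment`, `day`,
#'   `intake_ml_per_bee`).
#' @param treatments restrict to these treatments plus control (default:
#'   all present).
#' @param acute_window restrict to days 12 and 14.
#' @return list with `coefficients` (term, estimate, se, t, p) and the
#'   fitted `lm` object.
#' @export
intake_ols <- function(records, treatments = NULL, acute_window = FALSE) {
  dat <- records
  if (!is.null(treatments))
    dat <- dat[dat$treatment %in% c("control", treatments), , drop = FALSE]
  if (acute_window) dat <- dat[dat$day %in% c(12, 14), , drop = FALSE]
  if (!nrow(dat)) stopf("no intake records left after filtering")
  if (length(unique(dat$day)) < 2)
    stopf("need at least two measurement days per treatment")
  dat$treatment <- stats::relevel(factor(dat$treatment), ref = "control")
  dat$colony <- factor(dat$colony)
  form <- if (nlevels(dat$colony) > 1)
    intake_ml_per_bee ~ colony + day * treatment
  else intake_ml_per_bee ~ day * treatment
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit))))
    stopf("collinear intake design: %s",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  cf <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(cf),
                                 estimate = cf[, 1], se = cf[, 2],
                                 t = cf[, 3], p = cf[, 4],
                                 stringsAsFactors = FALSE, row.names = NULL),
       fit = fit)
}

#' Mass concentration of a feeding solution in parts per billion
#'
#' Converts a pesticide concentration in micrograms per litre of feeding
#' solution into micrograms per kilogram (ppb by mass), dividing by the
#' solution density and rounding half up to one decimal. A litre of 30%
#' sucrose solution weighs 1130 g, so 5 and 25 ug/L correspond to 4.4 and
#' 22.1 ppb.
#'
#' @param pesticide_ug_per_l pesticide mass concentration (ug per litre of
#'   solution).
#' @param solution_density_g_per_l solution density (g per litre).
#' @return concentration in ppb (ug per kg), one decimal.
#' @export
ppb_concentration <- function(pesticide_ug_per_l,
                              solution_density_g_per_l = 1130) {
  if (any(pesticide_ug_per_l < 0)) stopf("concentration must not be negative")
  if (any(solution_density_g_per_l <= 0)) stopf("density must be positive")
  round_half_up(pesticide_ug_per_l / (solution_density_g_per_l / 1000), 1)
}

#' Cumulative pesticide dose per bee
#'
#' Sums the solution volume consumed over the exposure window and converts
#' it to micrograms of pesticide per bee. Records may carry per-bee daily
#' intake (the generator's output; each measurement covers
#' `interval_days` days) or microcolony totals (`intake_is_total = TRUE`).
#'
#' @param intakes intake records restricted to the exposure window.
#' @param pesticide_ug_per_l solution concentration (ug per litre).
#' @param bees_per_colony bees per microcolony.
#' @param interval_days days covered by one measurement.
#' @param intake_is_total whether `intake_ml_per_bee` values are microcolony
#'   totals rather than per-bee daily averages.
#' @return list with `per_microcolony` (microcolony, dose_ug_per_bee) and
#'   `median_dose_ug_per_bee`.
#' @export
cumulative_dose <- function(intakes, pesticide_ug_per_l,
                            bees_per_colony = 6, interval_days = 2,
                            intake_is_total = FALSE) {
  if (any(intakes$intake_ml_per_bee < 0))
    stopf("negative intake encountered")
  if (pesticide_ug_per_l < 0) stopf("concentration must not be negative")
  ml <- tapply(intakes$intake_ml_per_bee, intakes$microcolony, sum)
  total_ml <- if (intake_is_total) ml
              else ml * bees_per_colony * interval_days
  dose_per_bee <- total_ml * pesticide_ug_per_l / 1000 / bees_per_colony
  per_mc <- data.frame(microcolony = names(dose_per_bee),
                       dose_ug_per_bee = as.numeric(dose_per_bee),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(per_microcolony = per_mc,
       median_dose_ug_per_bee = median(per_mc$dose_ug_per_bee))
}
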