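conf_cols <- c("age", "lvef", "lv_mass_index", "nyha34", "alcohol_excess")

cohort_frame <- function(n, seed, ...) {
  co <- make_synthetic_cohort(n, seed = seed, render_slices = FALSE, ...)
  fr <- attr(co, "frame")
  fr$nyha34 <- as.numeric(fr$nyha34)
  fr$alcohol_excess <- as.numeric(fr$alcohol_excess)
  fr
}

test_that("per-SD standardization yields exact moments and errors on constants", {
  fr <- cohort_frame(100, 2)
  st <- standardize_per_sd(fr, c("age", "interface_area_cm2"))
  expect_lt(abs(mean(st$age)), 1e-12)
  expect_lt(abs(sd(st$age) - 1), 1e-12)
  fr$flat <- 3
  expect_error(standardize_per_sd(fr, "flat"), "flat")
})

test_that("per-SD hazard ratio equals the raw HR to the power of the SD", {
  fr <- cohort_frame(300, 6)
  raw <- cox_fit(fr, "interface_area_cm2", robust = FALSE)
  st <- standardize_per_sd(fr, "interface_area_cm2")
  per_sd <- cox_fit(st, "interface_area_cm2", robust = FALSE)
  s <- sd(fr$interface_area_cm2)
  expect_equal(per_sd$table$log_hr, raw$table$log_hr * s, tolerance = 1e-6)
})

test_that("weights stay uniform when target and confounders are orthogonal", {
  set.seed(4)
  n <- 80
  x <- rnorm(n)
  t0 <- rnorm(n)
  t_orth <- residuals(lm(t0 ~ x))            # exactly uncorrelated sample
  fr <- data.frame(target = t_orth, x = x)
  w <- ipw_weights(fr, "target", "x")
  expect_lt(max(abs(w - 1)), 1e-6)
})

test_that("entropy-balancing weights zero out every weighted correlation", {
  fr <- cohort_frame(400, 9, confounding_correlation = 0.45)
  w <- ipw_weights(fr, "interface_area_cm2", conf_cols)
  expect_equal(sum(w), nrow(fr), tolerance = 1e-8)
  expect_true(all(w > 0))
  for (cc in conf_cols) {
    wm_t <- weighted.mean(fr$interface_area_cm2, w)
    wm_x <- weighted.mean(fr[[cc]], w)
    wc <- sum(w * (fr$interface_area_cm2 - wm_t) * (fr[[cc]] - wm_x)) /
      sqrt(sum(w * (fr$interface_area_cm2 - wm_t)^2) *
           sum(w * (fr[[cc]] - wm_x)^2))
    expect_lt(abs(wc), 1e-6)
  }
  # a confounder perfectly collinear with the target is infeasible
  fr$clone <- fr$interface_area_cm2
  expect_error(ipw_weights(fr, "interface_area_cm2", "clone"), "collinear")
})

test_that("six-subject weights match a brute-force simplex optimizer", {
  set.seed(12)
  t_raw <- rnorm(6)
  x <- rnorm(6) + 0.5 * t_raw
  fr <- data.frame(target = t_raw, x = x)
  w <- ipw_weights(fr, "target", "x")
  w_oracle <- oracle_ipw_weights(t_raw, x)
  expect_lt(max(abs(w - w_oracle)), 1e-4)
})

test_that("symmetric two-group data give a hazard ratio of exactly one", {
  fr <- data.frame(followup_days = rep(c(1, 2, 3, 4), 2),
                   event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                   g = rep(0:1, each = 4),
                   patient_id = letters[1:8])
  fit <- cox_fit(fr, "g", robust = FALSE)
  expect_equal(fit$table$hazard_ratio, 1.0, tolerance = 1e-8)
})

test_that("cox_fit matches the written-out partial likelihood oracle", {
  set.seed(8)
  for (k in 1:20) {
    fr <- draw_nondegenerate_cox_data(6)
    fit <- cox_fit(fr, "x", robust = FALSE)
    beta_oracle <- oracle_cox_beta(fr$followup_days, fr$event, fr$x)
    expect_lt(abs(fit$table$log_hr - beta_oracle), 1e-6)
  }
})

test_that("time-varying ICD expansion bookkeeping is exact", {
  fr <- data.frame(followup_days = c(10, 20, 30, 40),
                   event = c(TRUE, FALSE, TRUE, TRUE),
                   x = c(0.2, -1, 0.7, 1.5),
                   icd_day = c(NA, 5, 12, NA),
                   patient_id = c("a", "b", "c", "d"))
  tv <- cox_time_varying(fr, "x")
  expect_equal(nrow(tv$expanded), 4 + 2)     # n + number of ICD patients
  # matches a hand-expanded counting-process fit
  hand <- data.frame(
    t0 = c(0, 0, 5, 0, 12, 0), t1 = c(10, 5, 20, 12, 30, 40),
    ev = c(1, 0, 0, 0, 1, 1),
    x = c(0.2, -1, -1, 0.7, 0.7, 1.5),
    icd = c(0, 0, 1, 0, 1, 0),
    subj = c("a", "b", "b", "c", "c", "d"))
  ref <- survival::coxph(
    survival::Surv(t0, t1, ev) ~ x + icd + cluster(subj), data = hand,
    ties = "efron", robust = TRUE)
  expect_equal(coef(tv), coef(ref), tolerance = 1e-8,
               ignore_attr = TRUE)
  # icd_day beyond follow-up is a validation error
  bad <- fr; bad$icd_day[2] <- 25
  expect_error(cox_time_varying(bad, "x"), "follow-up")
  # without any ICD the fit reduces to the ordinary model
  none <- fr; none$icd_day <- NA
  tv0 <- cox_time_varying(none, "x", robust = FALSE)
  plain <- cox_fit(fr, "x", robust = FALSE)
  expect_equal(tv0$table$log_hr, plain$table$log_hr, tolerance = 1e-10)
})

test_that("terciles split 156 patients into 52/52/52 with deterministic ties", {
  fr <- cohort_frame(156, 13)
  ts <- tercile_stratify(fr, "interface_area_cm2")
  expect_equal(ts$summary$n, c(52L, 52L, 52L))
  # ties straddling the cutpoint: stable order on (value, patient_id)
  fr2 <- fr
  fr2$interface_area_cm2 <- rep(1, 156)       # fully tied column
  ts2 <- tercile_stratify(fr2, "interface_area_cm2")
  expect_equal(ts2$summary$n, c(52L, 52L, 52L))
  first_ids <- fr2$patient_id[order(fr2$interface_area_cm2, fr2$patient_id)][1:52]
  expect_setequal(fr2$patient_id[ts2$group == "low"], first_ids)
  expect_error(tercile_stratify(fr[1:2, ], "interface_area_cm2"), "3 patients")
})

test_that("event rates rise across terciles of a monotone-risk cohort", {
  hits <- vapply(1:50, function(r) {
    fr <- cohort_frame(120, 100 + r, beta_interface_per_sd = log(3))
    # small groups can have zero events; the indicator HRs may diverge,
    # which is irrelevant to the event-count comparison here
    ts <- suppressWarnings(tercile_stratify(fr, "interface_area_cm2"))
    ts$summary$events[3] >= ts$summary$events[1]
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("Kaplan-Meier reduces to the empirical survival curve without censoring", {
  fr <- data.frame(followup_days = c(1, 3, 5, 7, 9, 11),
                   event = TRUE, g = rep(1:2, 3))
  km <- km_logrank(fr, fr$g)
  sf <- summary(km$survfit)
  # group 1 times 1,5,9: survival 2/3, 1/3, 0
  g1 <- sf$surv[sf$strata == levels(sf$strata)[1]]
  expect_equal(g1, c(2, 1, 0) / 3, tolerance = 1e-12)
  # identical groups: log-rank statistic is zero
  fr2 <- data.frame(followup_days = rep(c(2, 4, 6, 8), 2),
                    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                    g = rep(1:2, each = 4))
  expect_lt(km_logrank(fr2, fr2$g)$chisq, 1e-10)
  expect_error(km_logrank(fr, rep(1, 6)), "2 groups")
})

test_that("log-rank matches the hand-worked observed-minus-expected table", {
  # 8 subjects, 2 groups; compute O-E and V by hand at each event time
  tt <- c(2, 4, 5, 7, 8, 10, 12, 14)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  gg <- c(1, 2, 1, 1, 2, 1, 2, 2)
  o_minus_e <- 0; v <- 0
  for (i in which(ev)) {
    at_risk <- tt >= tt[i]
    n1 <- sum(at_risk & gg == 1); n <- sum(at_risk)
    o_minus_e <- o_minus_e + (gg[i] == 1) - n1 / n
    if (n > 1) v <- v + n1 / n * (1 - n1 / n)
  }
  chisq_hand <- o_minus_e^2 / v
  fr <- data.frame(followup_days = tt, event = ev)
  res <- km_logrank(fr, gg)
  expect_equal(res$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(res$df, 1)
})

test_that("event rates print the conventional one-decimal percentages", {
  expect_identical(event_rates(0, 50), 0)
  expect_identical(event_rates(1, 3), 33.3)
  expect_error(event_rates(5, 0), "positive")
  expect_error(event_rates(5, 4), "exceed")
})
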