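test_that("with day and minute variance off, every day mean equals the true mean HR", {
  p <- sim_params(n_patients = 4, preop_days = 10, postop_days = 4,
                  sigma_day_hr = 0, sigma_minute_hr = 0, daily_gap_rate = 0,
                  missing_day_rate = 0, artifact_rate = 0, postop_hr_shift = 0,
                  seed = 21)
  coh <- generate_cohort(p)
  cl <- clean_cohort(coh)
  dm <- merge(cl$day_summaries[hr_day_included == TRUE,
                               .(patient_id, mean_hr)],
              coh$truth[, .(patient_id, true_hr)], by = "patient_id")
  expect_gt(nrow(dm), 30)
  expect_equal(dm$mean_hr, dm$true_hr, tolerance = 1e-10)
})

test_that("samples respect the wear window and the technical HR range", {
  coh <- generate_cohort(sim_params(n_patients = 5, seed = 31))
  hrs <- data.table::hour(coh$vitals$timestamp)
  p <- coh$params
  expect_true(all(hrs >= p$wake_start & hrs < p$wake_end))
  expect_true(all(coh$vitals$hr >= 30 & coh$vitals$hr <= 240))
  # no home data during the hospital stay
  v <- merge(coh$vitals[, .(patient_id, date = as.Date(timestamp, tz = "UTC"))],
             coh$timelines, by = "patient_id")
  expect_equal(nrow(v[date >= admission_date & date <= discharge_date]), 0)
})

test_that("PROM schedule: at most two entries per item-day, morning in [9, 13), evening 20:00", {
  coh <- generate_cohort(sim_params(n_patients = 6, seed = 41))
  pr <- data.table::copy(coh$proms)
  pr[, date := as.Date(timestamp, tz = "UTC")]
  per_day <- pr[, .N, by = .(patient_id, date, item)]
  expect_true(all(per_day$N <= 2))
  h <- data.table::hour(pr$timestamp) + data.table::minute(pr$timestamp) / 60
  expect_true(all((h >= 9 & h < 13) | h == 20))
  expect_true(all(pr$score >= 0 & pr$score <= 10))
})

test_that("patient and day variance components are recovered by one-way ANOVA", {
  cl <- get_big_cleaned()
  ds <- cl$day_summaries[phase == "preop_home" & hr_day_included == TRUE]
  av <- stats::anova(stats::lm(mean_hr ~ patient_id, data = ds))
  n_days <- 21
  ms_between <- av["patient_id", "Mean Sq"]
  ms_within <- av["Residuals", "Mean Sq"]
  sigma_b2 <- (ms_between - ms_within) / n_days
  expect_lt(abs(sigma_b2 - 64) / 64, 0.10)
  expect_lt(abs(ms_within - 16) / 16, 0.10)
})

test_that("artifact injection: rate 0 is a no-op with an empty log", {
  coh <- generate_cohort(sim_params(n_patients = 2, preop_days = 8,
                                    postop_days = 3, artifact_rate = 0,
                                    seed = 51))
  out <- inject_removal_artifacts(coh$vitals, rate = 0)
  expect_identical(out$vitals, coh$vitals)
  expect_equal(nrow(out$log), 0)
  expect_error(inject_removal_artifacts(coh$vitals, rate = 1.2), "rate")
})

test_that("sessions shorter than six minutes are never injected, only logged as skipped", {
  v <- make_day_vitals("S001", "2021-02-01", 4L, 1L)
  out <- inject_removal_artifacts(v, rate = 1, seed = 5)
  expect_identical(out$vitals, v)
  expect_true(all(out$log$skipped))
  expect_equal(nrow(out$log), 1)
})

test_that("injected artifact segments sit in the final five minutes of a session", {
  coh <- generate_cohort(sim_params(n_patients = 6, artifact_rate = 0.5,
                                    seed = 61))
  lg <- coh$artifact_log[skipped == FALSE]
  expect_gt(nrow(lg), 5)
  sess <- basewear:::session_table(segment_sessions(coh$vitals))
  m <- merge(lg, sess, by = c("patient_id", "session_id"))
  expect_equal(nrow(m), nrow(lg))
  expect_true(all(m$end_ts.x == m$end_ts.y))
  expect_true(all(m$n_minutes == 5L))
  expect_true(all(as.numeric(m$end_ts.x - m$start_ts.x, units = "mins") <= 5))
})
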