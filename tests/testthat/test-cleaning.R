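make_session <- function(hr, temp, start = "2021-02-01 10:00:00",
                         pid = "C001") {
  data.table(
    patient_id = pid,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_along(hr) - 1L) * 60,
    hr = hr, skin_temp = temp
  )
}

test_that("session segmentation splits on gaps and assigns every sample once", {
  v1 <- make_session(rep(70, 120), rep(33.4, 120))
  s1 <- segment_sessions(v1)
  expect_equal(unique(s1$session_id), 1L)

  v2 <- rbind(make_session(rep(70, 60), rep(33.4, 60)),
              make_session(rep(70, 60), rep(33.4, 60),
                           start = "2021-02-01 11:30:00"))
  s2 <- segment_sessions(v2, gap_threshold = 5)
  expect_equal(sort(unique(s2$session_id)), c(1L, 2L))
  expect_equal(nrow(s2), nrow(v2))

  s0 <- segment_sessions(v1[0])
  expect_equal(nrow(s0), 0)
})

test_that("technical-range filter excludes strictly outside 30-240 bpm", {
  v <- make_session(c(25, 30, 70, 240, 241, NA), rep(33.4, 6))
  f <- filter_technical_range(v)
  expect_equal(f$hr_valid, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$excl_reason,
               c("technical_range", NA, NA, NA, "technical_range", NA))
})

test_that("removal-tail detector flags forced joint temperature/HR signatures", {
  # pre-tail: HR cycling 67/70/73 (median 70, raw MAD 3), temp 33.5
  pre_hr <- rep(c(67, 70, 73), length.out = 55)
  calm <- make_session(c(pre_hr, rep(70, 5)), rep(33.5, 60))
  res0 <- detect_removal_tails(calm)
  expect_false(any(res0$sessions$flagged))
  expect_true(all(res0$vitals$hr_valid))

  # tail: HR 85 > 70 + 3*3, temp 0.6 below the pre-tail median
  hot <- make_session(c(pre_hr, rep(85, 5)), c(rep(33.5, 55), rep(32.9, 5)))
  res1 <- detect_removal_tails(hot)
  expect_true(res1$sessions$flagged)
  expect_equal(sum(!res1$vitals$hr_valid), 5)
  expect_equal(res1$vitals[hr_valid == FALSE, unique(excl_reason)],
               "removal_tail")
  # excluded minutes are exactly the session's final window
  expect_equal(res1$vitals[hr_valid == FALSE, timestamp],
               tail(hot$timestamp, 5))

  # temperature drop alone is not enough
  cold <- make_session(c(pre_hr, rep(70, 5)), c(rep(33.5, 55), rep(32.9, 5)))
  expect_false(detect_removal_tails(cold)$sessions$flagged)

  # HR spike alone is not enough
  spike <- make_session(c(pre_hr, rep(85, 5)), rep(33.5, 60))
  expect_false(detect_removal_tails(spike)$sessions$flagged)

  # short sessions are not evaluable
  short <- make_session(c(70, 70, 85, 85), c(33.5, 33.5, 32.0, 32.0))
  expect_false(detect_removal_tails(short)$sessions$flagged)
})

test_that("cleaning cascade is idempotent on its own output", {
  coh <- generate_cohort(sim_params(n_patients = 6, artifact_rate = 0.3,
                                    seed = 17))
  first <- clean_vitals(coh$vitals)
  kept <- first$vitals[hr_valid == TRUE,
                       .(patient_id, timestamp, hr, skin_temp)]
  second <- clean_vitals(kept)
  expect_equal(second$counts$excluded_technical_range, 0)
  expect_equal(second$counts$excluded_removal_tail, 0)
  expect_identical(second$vitals[hr_valid == TRUE,
                                 .(patient_id, timestamp, hr, skin_temp)],
                   kept)
})

test_that("day-level rules: 60 HR minutes and 8 wear hours, at their boundaries", {
  v <- rbind(
    make_day_vitals("D001", "2021-03-01", 59L, 2L),   # one minute short
    make_day_vitals("D001", "2021-03-02", 60L, 2L),   # exactly one hour
    make_day_vitals("D001", "2021-03-03", 120L, 7L),  # 7 wear hours
    make_day_vitals("D001", "2021-03-04", 120L, 8L)   # 8 wear hours
  )
  tl <- data.table(patient_id = "D001",
                   monitoring_start = as.Date("2021-03-01"),
                   admission_date = as.Date("2021-03-10"),
                   surgery_date = as.Date("2021-03-11"),
                   discharge_date = as.Date("2021-03-16"))
  ds <- summarize_days(clean_vitals(v)$vitals, v[0, .(patient_id,
                                                      hour_start = timestamp,
                                                      steps = 0L)],
                       v[0, .(patient_id, timestamp,
                              item = character(0), score = numeric(0))], tl)
  expect_equal(ds$hr_day_included, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(ds$step_day_included, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(ds$hr_minutes, c(59L, 60L, 120L, 120L))
  expect_equal(ds$wear_hours, c(2L, 2L, 7L, 8L))
})

test_that("patient rule keeps exactly those with >= 7 qualifying preoperative days", {
  fx <- make_filter_fixture()
  cl <- clean_cohort(fx)
  expect_equal(length(cl$included), 16)
  expect_setequal(cl$excluded, sprintf("F%03d", 17:20))
  # boundary: 6 qualifying days excluded, 7 included
  expect_true(all(cl$patient_days[patient_id %in% cl$excluded, n_days] == 6))
  expect_true("F016" %in% cl$included)  # qualifies via PROM-only days
})

test_that("every excluded sample falls under exactly one cleaning category", {
  coh <- generate_cohort(sim_params(n_patients = 8, artifact_rate = 0.3,
                                    seed = 23))
  cl <- clean_vitals(coh$vitals)
  v <- cl$vitals
  n_excl <- sum(!v$hr_valid & !is.na(v$hr))
  expect_equal(cl$counts$excluded_technical_range +
                 cl$counts$excluded_removal_tail, n_excl)
  expect_true(all(table(v[!is.na(excl_reason), excl_reason]) >= 0))
  expect_false(any(v$hr_valid & !is.na(v$excl_reason)))
})
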