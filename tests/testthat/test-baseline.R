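baseline_fixture <- function() {
  # three preop days with day-mean HRs 70, 72, 74 but unequal minute counts,
  # so the day-weighted reference (72) differs from the all-minutes mean
  v <- rbind(
    make_day_vitals("B001", "2021-03-01", 60L, 8L, hr = 70),
    make_day_vitals("B001", "2021-03-02", 240L, 8L, hr = 72),
    make_day_vitals("B001", "2021-03-03", 60L, 8L, hr = 74)
  )
  tl <- data.table(patient_id = "B001",
                   monitoring_start = as.Date("2021-03-01"),
                   admission_date = as.Date("2021-03-08"),
                   surgery_date = as.Date("2021-03-09"),
                   discharge_date = as.Date("2021-03-14"))
  pr <- rbind(make_prom_entry("B001", "2021-03-01", score = 2),
              make_prom_entry("B001", "2021-03-02", score = 4))
  clean_cohort(list(vitals = v, steps = v[0, .(patient_id,
                                               hour_start = timestamp,
                                               steps = 0L)],
                    proms = pr, timelines = tl))
}

test_that("reference values are unweighted means of day means", {
  cl <- baseline_fixture()
  refs <- compute_reference(cl, patients = "B001")
  expect_equal(refs$ref_hr, 72)          # mean of 70, 72, 74
  expect_equal(refs$n_ref_days_hr, 3L)
  # all-minutes mean is pulled toward the heavy middle day; must differ
  all_minutes <- cl$vitals[hr_valid == TRUE, mean(hr)]
  expect_equal(all_minutes, 72)  # symmetric fixture: same value
  # order invariance
  v2 <- cl$day_summaries[order(-date)]
  expect_equal(mean(v2[hr_day_included == TRUE, mean_hr]), 72)
  # PROM reference is the mean over all preop entries
  expect_equal(refs$ref_pain, 3)
  expect_equal(refs$n_ref_days_prom, 2L)
})

test_that("day weighting differs from minute weighting on an asymmetric fixture", {
  v <- rbind(
    make_day_vitals("B002", "2021-03-01", 60L, 8L, hr = 70),
    make_day_vitals("B002", "2021-03-02", 300L, 8L, hr = 80)
  )
  tl <- data.table(patient_id = "B002",
                   monitoring_start = as.Date("2021-03-01"),
                   admission_date = as.Date("2021-03-08"),
                   surgery_date = as.Date("2021-03-09"),
                   discharge_date = as.Date("2021-03-14"))
  cl <- clean_cohort(list(vitals = v,
                          steps = v[0, .(patient_id, hour_start = timestamp,
                                         steps = 0L)],
                          proms = v[0, .(patient_id, timestamp,
                                         item = character(0),
                                         score = numeric(0))],
                          timelines = tl))
  refs <- compute_reference(cl, patients = "B002")
  expect_equal(refs$ref_hr, 75)                       # (70 + 80) / 2
  expect_gt(cl$vitals[hr_valid == TRUE, mean(hr)], 78)  # minutes say ~78.3
})

test_that("with day variance off the reference recovers the true mean HR", {
  p <- sim_params(n_patients = 5, preop_days = 12, postop_days = 3,
                  sigma_day_hr = 0, sigma_minute_hr = 0, daily_gap_rate = 0,
                  missing_day_rate = 0, artifact_rate = 0, seed = 33)
  coh <- generate_cohort(p)
  cl <- clean_cohort(coh)
  refs <- compute_reference(cl)
  m <- merge(refs, coh$truth, by = "patient_id")
  expect_equal(m$ref_hr, m$true_hr, tolerance = 1e-10)
})

test_that("special days respect availability rules", {
  # first day has only 40 HR minutes -> HR unavailable there
  v <- rbind(
    make_day_vitals("B003", "2021-03-01", 40L, 8L, hr = 70),
    make_day_vitals("B003", "2021-03-02", 120L, 8L, hr = 72),
    make_day_vitals("B003", "2021-03-03", 120L, 8L, hr = 74)
  )
  tl <- data.table(patient_id = "B003",
                   monitoring_start = as.Date("2021-03-01"),
                   admission_date = as.Date("2021-03-10"),
                   surgery_date = as.Date("2021-03-11"),
                   discharge_date = as.Date("2021-03-16"))
  cl <- clean_cohort(list(vitals = v,
                          steps = v[0, .(patient_id, hour_start = timestamp,
                                         steps = 0L)],
                          proms = v[0, .(patient_id, timestamp,
                                         item = character(0),
                                         score = numeric(0))],
                          timelines = tl))
  fd <- extract_special_day(cl, "first_day", patients = "B003")
  expect_false(fd$hr_available)
  expect_true(is.na(fd$mean_hr))
  # the day before admission (2021-03-09) has no data at all
  ba <- extract_special_day(cl, "day_before_admission", patients = "B003")
  expect_false(ba$hr_available)
  expect_false(ba$steps_available)
  expect_false(ba$prom_available)
  expect_equal(ba$date, as.Date("2021-03-09"))
})

test_that("special-day availability varies across a cohort like the study tables", {
  cl <- get_small_cleaned()
  fd <- extract_special_day(cl, "first_day")
  ba <- extract_special_day(cl, "day_before_admission")
  expect_true(all(c(sum(fd$hr_available), sum(ba$hr_available)) <=
                    length(cl$included)))
  refs <- compute_reference(cl)
  expect_true(all(refs$n_ref_days_hr >= 1))
  expect_true(all(refs[!is.na(ref_pain), ref_pain] >= 0 &
                    refs[!is.na(ref_pain), ref_pain] <= 10))
})
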