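test_that("contiguous-period sampling honours feasibility and contiguity", {
  # 2 eligible days cannot host a 3-day period
  d2 <- as.Date("2021-03-01") + c(0, 1)
  expect_true(is.na(sample_contiguous_period(d2, c(70, 72), 3)))

  # a hole in the calendar invalidates windows spanning it
  d_hole <- as.Date("2021-03-01") + c(0, 1, 3, 4)
  set.seed(1)
  for (i in 1:20) {
    v <- sample_contiguous_period(d_hole, c(1, 2, 10, 20), 2)
    expect_true(v %in% c(1.5, 15))  # only (1,2) and (3,4) are contiguous
  }

  # spec length = all eligible days: deterministic regardless of seed
  d5 <- as.Date("2021-03-01") + 0:4
  vals <- c(60, 65, 70, 75, 80)
  for (s in 1:5) {
    set.seed(s)
    expect_equal(sample_contiguous_period(d5, vals, 5), 70)
  }
})

test_that("special days never enter sampled periods and n is non-increasing in length", {
  cl <- get_small_cleaned()
  tl <- cl$timelines
  for (par in c("hr", "steps")) {
    elig <- basewear:::eligible_period_days(cl, par)
    bad <- merge(elig, tl, by = "patient_id")
    expect_equal(nrow(bad[date == monitoring_start |
                            date == admission_date - 1]), 0)
  }
  refs <- compute_reference(cl)
  rel <- reliability_table(cl, refs, seed = 5)
  for (par in c("hr", "steps")) {
    nn <- rel[parameter == par & grepl("^[0-9]d$", period)][order(period)]
    nn <- nn[match(sprintf("%dd", 1:7), period)]
    expect_true(all(diff(nn$n) <= 0))
  }
})

test_that("single PROM draws are deterministic under a fixed seed and unique entries", {
  cl <- get_small_cleaned()
  set.seed(42)
  a <- sample_single_prom(cl, "pain")
  set.seed(42)
  b <- sample_single_prom(cl, "pain")
  expect_identical(a, b)
  expect_true(all(is.na(a$value) | (a$value >= 0 & a$value <= 10)))

  # a patient with exactly one eligible entry gets it deterministically
  v <- make_day_vitals("R001", "2021-03-02", 120L, 8L)
  pr <- make_prom_entry("R001", "2021-03-03", score = 6.5)
  tl <- data.table(patient_id = "R001",
                   monitoring_start = as.Date("2021-03-01"),
                   admission_date = as.Date("2021-03-10"),
                   surgery_date = as.Date("2021-03-11"),
                   discharge_date = as.Date("2021-03-16"))
  cl1 <- clean_cohort(list(vitals = v,
                           steps = v[0, .(patient_id, hour_start = timestamp,
                                          steps = 0L)],
                           proms = pr, timelines = tl))
  out <- sample_single_prom(cl1, "pain", patients = "R001")
  expect_equal(out$value, 6.5)
})

test_that("zero within-patient PROM variance yields ICC 1 against the reference", {
  p <- sim_params(n_patients = 10, preop_days = 12, postop_days = 3,
                  prom_within_sd = 0, prom_missing_rate = 0,
                  artifact_rate = 0, missing_day_rate = 0, seed = 55)
  cl <- clean_cohort(generate_cohort(p))
  refs <- compute_reference(cl)
  sp <- sample_single_prom(cl, "pain")
  m <- merge(sp, refs[, .(patient_id, ref = ref_pain)], by = "patient_id")
  m <- m[!is.na(value) & !is.na(ref)]
  r <- icc_a_k(cbind(m$value, m$ref))
  expect_equal(r$icc, 1, tolerance = 1e-12)
})

test_that("with day variance off every reliability row is ICC 1", {
  p <- sim_params(n_patients = 8, preop_days = 14, postop_days = 3,
                  sigma_day_hr = 0, sigma_minute_hr = 0,
                  step_day_dispersion = 0, prom_within_sd = 0,
                  first_day_step_shift = 0, daily_gap_rate = 0,
                  prom_missing_rate = 0, artifact_rate = 0,
                  missing_day_rate = 0, seed = 66)
  cl <- clean_cohort(generate_cohort(p))
  refs <- compute_reference(cl)
  rel <- reliability_table(cl, refs, seed = 6, hr_hours = integer(0))
  day_rows <- rel[grepl("d$|single_entry|first_day|day_before", period)]
  # step totals are integer-rounded hour allocations; allow that rounding
  expect_true(all(day_rows[!is.na(icc), icc] > 0.999))
})

test_that("hour-level windows require coverage and fall inside eligible days", {
  cl <- get_small_cleaned()
  refs <- compute_reference(cl)
  rel <- reliability_table(cl, refs, seed = 8, day_lengths = 1L)
  hr_rows <- rel[parameter == "hr" & period %in% c("1h", "4h")]
  expect_equal(nrow(hr_rows), 2)
  expect_true(all(hr_rows$n >= 2))
  expect_true(all(is.finite(hr_rows$icc)))
})

test_that("replicates add stability columns", {
  cl <- get_small_cleaned()
  refs <- compute_reference(cl)
  rel <- reliability_table(cl, refs, seed = 5, day_lengths = c(1L, 3L),
                           hr_hours = integer(0), replicates = 5L)
  expect_true(all(c("icc_mean", "icc_sd") %in% names(rel)))
  rnd <- rel[period %in% c("1d", "3d")]
  expect_true(all(is.finite(rnd$icc_mean)))
})
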