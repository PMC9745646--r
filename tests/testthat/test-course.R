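test_that("boxplot statistics follow linear-interpolated quartiles and Tukey whiskers", {
  bs <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(bs$median, 3)
  expect_equal(bs$q1, 2)
  expect_equal(bs$q3, 4)
  expect_equal(bs$whisker_low, 1)
  expect_equal(bs$whisker_high, 4)
  expect_equal(bs$outliers, 100)

  one <- boxplot_stats(5)
  expect_equal(one$median, 5)
  expect_equal(one$q1, 5)
  expect_equal(one$q3, 5)
  expect_equal(length(one$outliers), 0)
})

test_that("day alignment anchors preop on admission and postop on surgery", {
  cl <- get_small_cleaned()
  al <- align_days(cl)
  tl <- cl$timelines
  merged <- merge(cl$day_summaries[patient_id %in% cl$included],
                  tl, by = "patient_id")
  # an in-hospital day never appears
  expect_true(all(al$day_index != 0))
  expect_true(all(al$day_index >= -14 & al$day_index <= 30))
  # postop indices only after discharge
  post <- merged[phase == "postop_home"]
  expect_true(all(post$date > post$discharge_date))
  # spot-check one patient's index arithmetic
  pid <- cl$included[1]
  adm <- tl[patient_id == pid, admission_date]
  day <- cl$day_summaries[patient_id == pid & phase == "preop_home" &
                            hr_day_included == TRUE &
                            date >= adm - 14L][1]
  idx <- al[patient_id == pid & parameter == "hr" &
              value == day$mean_hr, day_index]
  expect_true(as.integer(day$date - adm) %in% idx)
})

test_that("contributing-patient counts are exhaustive per parameter", {
  cl <- get_small_cleaned()
  al <- align_days(cl)
  crs <- course_summary(cl)
  for (par in unique(crs$parameter)) {
    expect_equal(sum(crs[parameter == par, n]),
                 nrow(al[parameter == par]))
  }
  expect_true(all(crs$q1 <= crs$median & crs$median <= crs$q3))
  expect_true(all(crs$whisker_low >= crs$q1 - 1.5 * (crs$q3 - crs$q1) - 1e-9))
  expect_true(all(crs$whisker_high <= crs$q3 + 1.5 * (crs$q3 - crs$q1) + 1e-9))
})

test_that("postoperative step suppression is recovered in the course summary", {
  p <- sim_params(n_patients = 30, preop_days = 14, postop_days = 20,
                  los_days = 3, postop_step_multiplier = 0.35,
                  first_day_step_shift = 0, artifact_rate = 0,
                  missing_day_rate = 0, seed = 77)
  cl <- clean_cohort(generate_cohort(p))
  al <- align_days(cl, postop_window = 20)
  pre <- al[parameter == "steps" & day_index < 0, median(value)]
  post <- al[parameter == "steps" & day_index > 0, median(value)]
  expect_lt(abs(post / pre - 0.35), 0.1)
})
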