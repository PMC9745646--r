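library(data.table)

# Shared fixture cache so expensive cohorts are generated once per run.
.fixtures <- new.env(parent = emptyenv())

# Large artifact-free calibration cohort: 200 patients, 21 preoperative
# days each, between-patient HR SD 8 bpm, day-level SD 4 bpm, no
# missingness or charging gaps. Used for variance-decomposition and
# reliability-recovery checks.
get_big_cleaned <- function() {
  if (is.null(.fixtures$big_cleaned)) {
    p <- sim_params(n_patients = 200, preop_days = 21, postop_days = 2,
                    los_days = 1, sigma_between_hr = 8, sigma_day_hr = 4,
                    artifact_rate = 0, missing_day_rate = 0,
                    daily_gap_rate = 0, seed = 7)
    .fixtures$big_cleaned <- clean_cohort(generate_cohort(p))
  }
  .fixtures$big_cleaned
}

# Small default-condition cohort (all artifact/missingness machinery on).
get_small_cleaned <- function() {
  if (is.null(.fixtures$small_cleaned)) {
    p <- sim_params(n_patients = 16, seed = 3)
    .fixtures$small_cleaned <- clean_cohort(generate_cohort(p))
  }
  .fixtures$small_cleaned
}

# One patient-day of minute-level vitals: `n_min` HR minutes spread over
# `n_hours` distinct clock hours starting at 08:00, constant HR/temp.
make_day_vitals <- function(pid, date, n_min, n_hours, hr = 70,
                            temp = 33.4) {
  per <- ceiling(n_min / n_hours)
  slots <- unlist(lapply(seq_len(n_hours) - 1L, function(h) {
    (8L + h) * 60L + seq_len(min(per, 60L)) - 1L
  }))[seq_len(n_min)]
  data.table(
    patient_id = pid,
    timestamp = as.POSIXct(as.Date(date), tz = "UTC") + slots * 60,
    hr = hr, skin_temp = temp
  )
}

make_prom_entry <- function(pid, date, score = 2, hour = 20L) {
  data.table(
    patient_id = pid,
    timestamp = as.POSIXct(as.Date(date), tz = "UTC") + hour * 3600,
    item = rep(prom_items(), each = 1L),
    score = score
  )
}

# Hand-constructed 20-patient cohort for the exclusion cascade:
#   patients 1-15: 7 qualifying preop days of 120 HR minutes in 8 hours
#   patient 16:    4 HR days + 3 PROM-only days (qualifies via the OR rule)
#   patients 17-20: 6 qualifying days only (excluded by the 7-day rule)
# Every patient additionally has one 59-minute day (HR day excluded, does
# not qualify) and patient 1 has a 60-minute/7-hour boundary day replacing
# one standard day.
make_filter_fixture <- function() {
  start <- as.Date("2021-01-04")
  vit <- list(); prm <- list(); tl <- list(); stp <- list()
  for (i in 1:20) {
    pid <- sprintf("F%03d", i)
    mon <- start
    n_qual <- if (i <= 16) 7L else 6L
    days <- mon + seq_len(n_qual) - 1L
    for (j in seq_along(days)) {
      d <- days[j]
      if (i == 16 && j >= 5L) {
        prm[[length(prm) + 1L]] <- make_prom_entry(pid, d)       # PROM-only day
      } else if (i == 1L && j == 7L) {
        vit[[length(vit) + 1L]] <- make_day_vitals(pid, d, 60L, 7L)  # boundary day
      } else {
        vit[[length(vit) + 1L]] <- make_day_vitals(pid, d, 120L, 8L)
        stp[[length(stp) + 1L]] <- data.table(
          patient_id = pid,
          hour_start = as.POSIXct(d, tz = "UTC") + (8:15) * 3600,
          steps = 250L
        )
      }
    }
    # a 59-minute day that never qualifies
    vit[[length(vit) + 1L]] <- make_day_vitals(pid, mon + 8L, 59L, 2L)
    tl[[length(tl) + 1L]] <- data.table(
      patient_id = pid, monitoring_start = mon,
      admission_date = mon + 10L, surgery_date = mon + 11L,
      discharge_date = mon + 16L
    )
  }
  list(vitals = rbindlist(vit), steps = rbindlist(stp),
       proms = rbindlist(prm), timelines = rbindlist(tl))
}

# Brute-force two-way ANOVA ICC(A,k) point estimate: model fitted by
# lm()/anova() (QR path), independent of the closed-form row/column-mean
# computation in icc_a_k().
oracle_icc_ak <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  av <- suppressWarnings(stats::anova(stats::lm(y ~ subject + rater,
                                                data = long)))
  msr <- av["subject", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Simulate one two-way random-effects matrix with a given population
# ICC(A,k): sigma_r^2 = icc/(1-icc) * (sigma_c^2 + sigma_e^2)/k.
simulate_two_way <- function(n, k, icc_ak, sig_c2 = 0.1, sig_e2 = 0.9) {
  sig_r2 <- icc_ak / (1 - icc_ak) * (sig_c2 + sig_e2) / k
  matrix(rnorm(n, 0, sqrt(sig_r2)), n, k) +
    matrix(rnorm(k, 0, sqrt(sig_c2)), n, k, byrow = TRUE) +
    matrix(rnorm(n * k, 0, sqrt(sig_e2)), n, k)
}
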