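# Days eligible for random-period selection: preoperative home days,
# excluding the first telemonitoring day and the day before admission,
# with at least `min_wear_hours` hours of HR wear (the day condition the
# random-period analysis imposes for sensor parameters).
eligible_period_days <- function(cleaned, parameter,
                                 patients = cleaned$included) {
  ds <- cleaned$day_summaries[patient_id %in% patients & phase == "preop_home"]
  tl <- cleaned$timelines[patient_id %in% patients,
                          .(patient_id, monitoring_start, admission_date)]
  ds <- merge(ds, tl, by = "patient_id")
  ds <- ds[date != monitoring_start & date != admission_date - 1L]
  min_wh <- cleaned$config$clean$min_wear_hours
  if (parameter == "hr") {
    ds <- ds[hr_day_included == TRUE & wear_hours >= min_wh]
    ds[, value := mean_hr]
  } else if (parameter == "steps") {
    ds <- ds[step_day_included == TRUE & !is.na(steps_total)]
    ds[, value := as.numeric(steps_total)]
  } else {
    col <- paste0("prom_", parameter)
    ds <- ds[prom_entries >= 1L & !is.na(get(col))]
    ds[, value := get(col)]
  }
  setorder(ds, patient_id, date)
  ds[, .(patient_id, date, value)]
}

# Candidate window starts: indices i such that the `len` consecutive
# calendar days from dates[i] are all eligible (an ineligible day inside a
# window invalidates it; no skipping).
window_starts <- function(dates, len) {
  if (length(dates) < len) return(integer())
  which(vapply(seq_along(dates),
               function(i) all((dates[i] + seq_len(len) - 1L) %in% dates),
               logical(1)))
}

#' Mean over one randomly selected contiguous period of days
#'
#' Draws a start day uniformly among all starts whose `len` consecutive
#' calendar days are all eligible, and returns the unweighted mean of those
#' days' values. Patients without any feasible window get `NA`
#' (unavailable). With exactly one feasible window the draw is
#' deterministic.
#'
#' @param dates sorted `Date` vector of a patient's eligible days.
#' @param values day values aligned with `dates`.
#' @param len period length in days.
#' @return The period mean, or `NA_real_` when no window fits.
#' @export
sample_contiguous_period <- function(dates, values, len) {
  starts <- window_starts(dates, len)
  if (length(starts) == 0L) return(NA_real_)
  s <- if (length(starts) == 1L) starts else starts[sample.int(length(starts), 1L)]
  win <- dates >= dates[s] & dates <= dates[s] + len - 1L
  mean(values[win])
}

# Random contiguous clock window of `len_hours` within one eligible day.
# A window is feasible when it holds at least `min_cov` of its possible
# valid HR minutes; the day is drawn uniformly among days with a feasible
# window, then the window uniformly within the day.
sample_hour_window <- function(vitals_pat, elig_dates, len_hours,
                               min_cov = 0.5) {
  v <- vitals_pat[hr_valid == TRUE]
  v[, date := as.Date(timestamp, tz = "UTC")]
  v <- v[date %in% elig_dates]
  if (nrow(v) == 0L) return(NA_real_)
  v[, minute_of_day := hour(timestamp) * 60L + minute(timestamp)]
  need <- min_cov * 60 * len_hours
  starts_by_day <- v[, {
    cnt <- tabulate(minute_of_day %/% 60L + 1L, nbins = 24L)
    win <- vapply(0:(24 - len_hours),
                  function(h) sum(cnt[(h + 1):(h + len_hours)]), numeric(1))
    list(start_hour = (0:(24 - len_hours))[win >= need])
  }, by = date]
  if (nrow(starts_by_day) == 0L) return(NA_real_)
  days <- unique(starts_by_day$date)
  d <- if (length(days) == 1L) days else days[sample.int(length(days), 1L)]
  st <- starts_by_day[date == d, start_hour]
  h <- if (length(st) == 1L) st else st[sample.int(length(st), 1L)]
  v[date == d & minute_of_day >= h * 60L & minute_of_day < (h + len_hours) * 60L,
    mean(hr)]
}

#' One randomly selected PROM entry per patient
#'
#' Draws one entry uniformly from a patient's preoperative entries for an
#' item, excluding entries made on the first telemonitoring day or the day
#' before admission.
#'
#' @param cleaned a `cleaned_cohort`.
#' @param item one of `"pain"`, `"anxiety"`, `"fatigue"`, `"nausea"`.
#' @param patients patient ids; defaults to included patients.
#' @return data.table (`patient_id`, `value`); `NA` when a patient has no
#'   eligible entry.
#' @export
sample_single_prom <- function(cleaned, item, patients = cleaned$included) {
  it <- item
  pr <- cleaned$proms[patient_id %in% patients][item == it]
  tl <- cleaned$timelines[patient_id %in% patients]
  out <- data.table(patient_id = sort(patients), value = NA_real_)
  if (nrow(pr) > 0L) {
    pr[, date := as.Date(timestamp, tz = "UTC")]
    pr <- merge(pr, tl[, .(patient_id, monitoring_start, admission_date)],
                by = "patient_id")
    pr <- pr[date >= monitoring_start & date < admission_date &
               date != monitoring_start & date != admission_date - 1L]
    setorder(pr, patient_id, timestamp)
    for (pid in out$patient_id) {
      sc <- pr[patient_id == pid, score]
      if (length(sc) == 1L) out[patient_id == pid, value := sc]
      else if (length(sc) > 1L) {
        out[patient_id == pid, value := sc[sample.int(length(sc), 1L)]]
      }
    }
  }
  out[]
}

ref_column <- function(parameter) {
  switch(parameter, hr = "ref_hr", steps = "ref_steps",
         paste0("ref_", parameter))
}

special_column <- function(parameter) {
  switch(parameter, hr = "mean_hr", steps = "steps_total",
         paste0("prom_", parameter))
}

# Build the paired (period, reference) matrix, dropping incomplete pairs.
paired_matrix <- function(period_values, references, parameter) {
  m <- merge(period_values,
             references[, .(patient_id, ref = get(ref_column(parameter)))],
             by = "patient_id")
  m <- m[!is.na(value) & !is.na(ref)]
  m
}

icc_row <- function(parameter, period, pm, alpha = 0.05) {
  n_pairs <- nrow(pm)
  if (n_pairs < 2L) {
    return(data.table(parameter = parameter, period = period, n = n_pairs,
                      icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      band = NA_character_))
  }
  res <- icc_a_k(cbind(pm$value, pm$ref), alpha = alpha)
  data.table(parameter = parameter, period = period, n = n_pairs,
             icc = res$icc, ci_low = res$ci_low, ci_high = res$ci_high,
             band = res$band)
}

#' Reliability table: ICC of special days and random periods vs reference
#'
#' Reproduces the study design: for every parameter, the ICC (two-way
#' random effects, absolute agreement, average measures, with 95% CI)
#' between the individual reference values and (a) the mean values of the
#' first telemonitoring day and the day before admission, (b) the mean of
#' one randomly selected contiguous period per patient — 1 and 4 clock
#' hours and 1-7 days for HR, 1-7 days for steps — and (c) one randomly
#' selected entry for each PROM item. Patients without a feasible period
#' are excluded from that row (so `n` is non-increasing in period length).
#' One draw is taken per patient per row; `replicates > 1` adds the mean
#' and SD of the ICC over independent re-draws of the random rows.
#'
#' @param cleaned a `cleaned_cohort`.
#' @param references output of [compute_reference()].
#' @param seed integer seed governing all random draws.
#' @param day_lengths period lengths in days for HR and steps.
#' @param hr_hours period lengths in clock hours for HR.
#' @param replicates number of independent draws for random rows.
#' @param alpha CI error rate.
#' @return data.table with columns `parameter`, `period`, `n`, `icc`,
#'   `ci_low`, `ci_high`, `band` (plus `icc_mean`, `icc_sd` when
#'   `replicates > 1`).
#' @export
reliability_table <- function(cleaned, references, seed = 1L,
                              day_lengths = 1:7, hr_hours = c(1L, 4L),
                              replicates = 1L, alpha = 0.05) {
  set.seed(seed)
  pats <- cleaned$included
  rows <- list()
  rep_stats <- list()
  min_cov <- cleaned$config$reliability$min_window_cov
  params <- c("hr", "steps", prom_items())

  first_day <- extract_special_day(cleaned, "first_day", pats)
  before_adm <- extract_special_day(cleaned, "day_before_admission", pats)
  for (par in params) {
    col <- special_column(par)
    for (sp in list(list(tab = first_day, lab = "first_day"),
                    list(tab = before_adm, lab = "day_before_admission"))) {
      pv <- sp$tab[, .(patient_id, value = as.numeric(get(col)))]
      rows[[length(rows) + 1L]] <-
        icc_row(par, sp$lab, paired_matrix(pv, references, par), alpha)
    }
  }

  draw_row <- function(par, period_lab, draw_fun) {
    reps <- max(1L, as.integer(replicates))
    iccs <- numeric(0)
    first <- NULL
    for (r in seq_len(reps)) {
      pv <- draw_fun()
      rr <- icc_row(par, period_lab, paired_matrix(pv, references, par), alpha)
      if (r == 1L) first <- rr
      iccs <- c(iccs, rr$icc)
    }
    if (reps > 1L) {
      first[, `:=`(icc_mean = mean(iccs, na.rm = TRUE),
                   icc_sd = sd(iccs))]
    }
    first
  }

  for (par in c("hr", "steps")) {
    elig <- eligible_period_days(cleaned, par, pats)
    if (par == "hr") {
      for (lh in hr_hours) {
        rows[[length(rows) + 1L]] <- draw_row(par, sprintf("%dh", lh), function() {
          rbindlist(lapply(sort(pats), function(pid) {
            data.table(patient_id = pid,
                       value = sample_hour_window(
                         cleaned$vitals[patient_id == pid],
                         elig[patient_id == pid, date], lh, min_cov))
          }))
        })
      }
    }
    for (ld in day_lengths) {
      rows[[length(rows) + 1L]] <- draw_row(par, sprintf("%dd", ld), function() {
        rbindlist(lapply(sort(pats), function(pid) {
          e <- elig[patient_id == pid]
          data.table(patient_id = pid,
                     value = sample_contiguous_period(e$date, e$value, ld))
        }))
      })
    }
  }

  for (par in prom_items()) {
    rows[[length(rows) + 1L]] <- draw_row(par, "single_entry", function() {
      sample_single_prom(cleaned, par, pats)
    })
  }

  rbindlist(rows, fill = TRUE)
}

#' Reliability of a d-day mean from two independent periods
#'
#' Estimates how reliable a d-day measurement mean is as an estimate of a
#' patient's long-run level, by drawing two non-overlapping random
#' contiguous d-day periods per patient and computing the single-measures
#' ICC (two-way random effects, absolute agreement) between the two period
#' means. Under the additive patient/day variance decomposition this ICC
#' estimates `sigma_b^2 / (sigma_b^2 + sigma_w^2 / d)`, where `sigma_b^2`
#' and `sigma_w^2` are the between-patient and day-level variance
#' components of the day means — the analytic reliability of a d-day mean.
#' (The paired period-vs-reference design of [reliability_table()]
#' estimates agreement with the full-phase reference instead, a related
#' but larger quantity, because the reference itself is nearly noise-free
#' and overlaps the period.)
#'
#' @param cleaned a `cleaned_cohort`.
#' @param parameter `"hr"` or `"steps"`.
#' @param d period length in days.
#' @param seed integer seed.
#' @param patients patient ids; defaults to included patients.
#' @return An `icc_result` (single measures) with attribute `n_pairs`;
#'   patients lacking two disjoint feasible windows are dropped.
#' @export
day_mean_reliability <- function(cleaned, parameter = "hr", d, seed = 1L,
                                 patients = cleaned$included) {
  set.seed(seed)
  elig <- eligible_period_days(cleaned, parameter, patients)
  vals <- rbindlist(lapply(sort(patients), function(pid) {
    e <- elig[patient_id == pid]
    starts <- window_starts(e$date, d)
    if (length(starts) < 2L) {
      return(data.table(patient_id = pid, v1 = NA_real_, v2 = NA_real_))
    }
    pairs <- which(outer(e$date[starts], e$date[starts],
                         function(a, b) abs(as.numeric(a - b)) >= d),
                   arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0L) {
      return(data.table(patient_id = pid, v1 = NA_real_, v2 = NA_real_))
    }
    pk <- pairs[sample.int(nrow(pairs), 1L), ]
    win_mean <- function(s) {
      idx <- e$date >= e$date[s] & e$date <= e$date[s] + d - 1L
      mean(e$value[idx])
    }
    data.table(patient_id = pid, v1 = win_mean(starts[pk[1]]),
               v2 = win_mean(starts[pk[2]]))
  }))
  vals <- vals[!is.na(v1) & !is.na(v2)]
  res <- icc_a_k(cbind(vals$v1, vals$v2), measures = "single")
  attr(res, "n_pairs") <- nrow(vals)
  res
}
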