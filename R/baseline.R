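#' Per-patient individual reference values
#'
#' The reference value of a parameter is the unweighted mean over all
#' included preoperative home days: for HR the mean of the day-mean HRs
#' (days weigh equally regardless of how many minutes they carry), for
#' steps the mean of included days' totals, and for each PROM item the
#' mean over all preoperative entries. The two special preoperative days
#' (first telemonitoring day, day before admission) are part of the
#' reference. A parameter with zero included days simply has a missing
#' reference.
#'
#' @param cleaned a `cleaned_cohort` from [clean_cohort()].
#' @param patients patient ids to compute references for; defaults to the
#'   included patients.
#' @return A data.table, one row per patient: `ref_hr`, `ref_hr_sd` (mean
#'   of the within-day minute-level SDs), `ref_steps`, `ref_<item>` per
#'   PROM item, and per-parameter reference-day counts.
#' @export
compute_reference <- function(cleaned, patients = cleaned$included) {
  ds <- cleaned$day_summaries[patient_id %in% patients & phase == "preop_home"]
  hr_ref <- ds[hr_day_included == TRUE,
               .(ref_hr = mean(mean_hr), ref_hr_sd = mean(sd_hr),
                 n_ref_days_hr = .N), by = patient_id]
  st_ref <- ds[step_day_included == TRUE & !is.na(steps_total),
               .(ref_steps = mean(as.numeric(steps_total)),
                 n_ref_days_steps = .N), by = patient_id]
  pr <- cleaned$proms[patient_id %in% patients]
  if (nrow(pr) > 0L) {
    pr[, date := as.Date(timestamp, tz = "UTC")]
    pr <- merge(pr, cleaned$timelines[, .(patient_id, monitoring_start,
                                          admission_date)],
                by = "patient_id")
    pr <- pr[date >= monitoring_start & date < admission_date]
  }
  if (nrow(pr) > 0L) {
    pr_ref <- dcast(pr[, .(value = mean(score)), by = .(patient_id, item)],
                    patient_id ~ item, value.var = "value")
    for (it in setdiff(prom_items(), names(pr_ref))) pr_ref[, (it) := NA_real_]
    setnames(pr_ref, prom_items(), paste0("ref_", prom_items()))
    pr_days <- pr[, .(n_ref_days_prom = uniqueN(date)), by = patient_id]
  } else {
    pr_ref <- data.table(patient_id = character(), ref_pain = numeric(),
                         ref_anxiety = numeric(), ref_fatigue = numeric(),
                         ref_nausea = numeric())
    pr_days <- data.table(patient_id = character(), n_ref_days_prom = integer())
  }

  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", all = TRUE),
                list(data.table(patient_id = patients), hr_ref, st_ref,
                     pr_ref, pr_days))
  for (col in c("n_ref_days_hr", "n_ref_days_steps", "n_ref_days_prom")) {
    out[is.na(get(col)), (col) := 0L]
  }
  setorder(out, patient_id)
  out[]
}

#' Values measured on the two special preoperative days
#'
#' Extracts, per patient, the day summary of either the first day of
#' telemonitoring (`monitoring_start`) or the last day before hospital
#' admission (`admission_date - 1`). Availability flags mirror the
#' day-level inclusion rules: a special day's HR mean is unavailable when
#' that day fails the 60-minute rule, its step total when the day fails
#' the 8-wear-hour rule, and a PROM item when no entry was made that day.
#'
#' @param cleaned a `cleaned_cohort`.
#' @param which `"first_day"` or `"day_before_admission"`.
#' @param patients patient ids; defaults to the included patients.
#' @return A data.table, one row per patient, with the day's values and
#'   `hr_available` / `steps_available` / `prom_available` flags.
#' @export
extract_special_day <- function(cleaned,
                                which = c("first_day", "day_before_admission"),
                                patients = cleaned$included) {
  which <- match.arg(which)
  tl <- cleaned$timelines[patient_id %in% patients]
  target <- tl[, .(patient_id,
                   date = if (which == "first_day") monitoring_start
                          else admission_date - 1L)]
  ds <- cleaned$day_summaries[target, on = .(patient_id, date)]
  out <- data.table(
    patient_id = target$patient_id,
    which = which,
    date = target$date,
    mean_hr = fifelse(!is.na(ds$hr_day_included) & ds$hr_day_included,
                      ds$mean_hr, NA_real_),
    steps_total = fifelse(!is.na(ds$step_day_included) & ds$step_day_included,
                          as.numeric(ds$steps_total), NA_real_),
    prom_pain = ds$prom_pain, prom_anxiety = ds$prom_anxiety,
    prom_fatigue = ds$prom_fatigue, prom_nausea = ds$prom_nausea,
    wear_hours = fifelse(is.na(ds$wear_hours), 0L, ds$wear_hours)
  )
  out[, hr_available := !is.na(mean_hr)]
  out[, steps_available := !is.na(steps_total)]
  out[, prom_available := !is.na(prom_pain) | !is.na(prom_anxiety) |
        !is.na(prom_fatigue) | !is.na(prom_nausea)]
  setorder(out, patient_id)
  out[]
}
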