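#' Segment minute-level vitals into wear sessions
#'
#' A wear session (measurement period) is a maximal run of minute samples
#' whose inter-sample gaps do not exceed `gap_threshold` minutes; doffing
#' the sensor or putting it on the charger breaks the run. Every sample is
#' assigned to exactly one session.
#'
#' @param vitals minute-level vitals data.table, sorted within patient.
#' @param gap_threshold maximum tolerated gap between consecutive samples,
#'   minutes.
#' @return A copy of `vitals` with an integer `session_id` column
#'   (numbered per patient in time order).
#' @export
segment_sessions <- function(vitals, gap_threshold = 5) {
  v <- copy(as.data.table(vitals))
  if (nrow(v) == 0L) {
    v[, session_id := integer()]
    return(v[])
  }
  setorder(v, patient_id, timestamp)
  v[, session_id := {
    gap_min <- c(0, diff(as.numeric(timestamp)) / 60)
    cumsum(gap_min > gap_threshold) + 1L
  }, by = patient_id]
  v[]
}

# Session-level summary of a segmented vitals table.
session_table <- function(vitals_seg) {
  vitals_seg[, .(start_ts = timestamp[1L], end_ts = timestamp[.N], n = .N),
             by = .(patient_id, session_id)]
}

#' Exclude heart-rate samples outside the sensor's technical range
#'
#' Heart rates strictly below `lo` or strictly above `hi` bpm (the
#' manufacturer's technical range) are marked invalid; the boundary values
#' themselves are kept. Samples with missing HR are kept but carry no valid
#' HR.
#'
#' @param vitals minute-level vitals data.table.
#' @param lo,hi inclusive technical range, bpm.
#' @return A copy of `vitals` with logical `hr_valid` and character
#'   `excl_reason` (`NA`, or `"technical_range"`) columns.
#' @export
filter_technical_range <- function(vitals, lo = 30, hi = 240) {
  v <- copy(as.data.table(vitals))
  v[, hr_valid := !is.na(hr) & hr >= lo & hr <= hi]
  v[, excl_reason := fifelse(!is.na(hr) & (hr < lo | hr > hi),
                             "technical_range", NA_character_)]
  v[]
}

#' Detect sensor-removal artifacts at the end of wear sessions
#'
#' When the sensor is taken off but not put straight on its charger, it
#' keeps sampling for a few minutes: skin temperature falls while the
#' photoplethysmographic HR becomes unreliable and spikes. A session tail
#' (its final `window` minutes) is flagged when both hold:
#' \itemize{
#'   \item temperature drops by at least `temp_drop` deg C — measured as
#'     the pre-tail session median minus the tail minimum; and
#'   \item HR exceeds the pre-tail median plus `mad_mult` times the raw
#'     pre-tail median absolute deviation for at least
#'     `ceiling(vote_frac * window)` of the tail minutes.
#' }
#' Reference statistics are computed over the pre-tail portion of the same
#' session so the artifact cannot contaminate its own reference. Sessions
#' with fewer than `2 * window` minutes carrying both a valid HR and a
#' temperature are not evaluable and are never flagged. Flagged tails have
#' their HR minutes excluded (reason `"removal_tail"`); no minute outside
#' the final window of a session is ever excluded by this rule.
#'
#' @param vitals a segmented, technical-range-filtered vitals table (see
#'   [segment_sessions()], [filter_technical_range()]).
#' @param window tail length in minutes.
#' @param temp_drop temperature-drop threshold, deg C.
#' @param mad_mult MAD multiplier for the HR threshold.
#' @param vote_frac fraction of tail minutes that must satisfy the HR
#'   condition.
#' @return list with `vitals` (tail HR minutes of flagged sessions marked
#'   invalid) and `sessions`, a per-session table with the flag and the
#'   excluded minute range.
#' @export
detect_removal_tails <- function(vitals, window = 5L, temp_drop = 0.5,
                                 mad_mult = 3, vote_frac = 0.6) {
  v <- copy(as.data.table(vitals))
  if (!"session_id" %in% names(v)) v <- segment_sessions(v)
  if (!"hr_valid" %in% names(v)) v <- filter_technical_range(v)
  votes_needed <- ceiling(vote_frac * window)
  if (nrow(v) == 0L) {
    sess <- data.table(patient_id = character(), session_id = integer(),
                       flagged = logical(),
                       tail_start = as.POSIXct(character(), tz = "UTC"),
                       tail_end = as.POSIXct(character(), tz = "UTC"))
    return(list(vitals = v[], sessions = sess))
  }
  setorder(v, patient_id, timestamp)
  sess <- v[, {
    nr <- .N
    pre_idx <- seq_len(max(0L, nr - window))
    tail_idx <- setdiff(seq_len(nr), pre_idx)
    joint <- hr_valid & !is.na(skin_temp)
    flag <- FALSE
    if (sum(joint) >= 2L * window && length(pre_idx) > 0L) {
      pre_hr <- hr[pre_idx][hr_valid[pre_idx]]
      pre_tmp <- skin_temp[pre_idx][!is.na(skin_temp[pre_idx])]
      tail_hr <- hr[tail_idx][hr_valid[tail_idx]]
      tail_tmp <- skin_temp[tail_idx][!is.na(skin_temp[tail_idx])]
      if (length(pre_hr) >= window && length(pre_tmp) >= 1L &&
          length(tail_tmp) >= 1L) {
        thr <- stats::median(pre_hr) + mad_mult * stats::mad(pre_hr, constant = 1)
        drop_ok <- (stats::median(pre_tmp) - min(tail_tmp)) >= temp_drop
        hr_ok <- sum(tail_hr > thr) >= votes_needed
        flag <- drop_ok && hr_ok
      }
    }
    list(flagged = flag,
         tail_start = if (flag) timestamp[tail_idx[1L]] else as.POSIXct(NA, tz = "UTC"),
         tail_end = if (flag) timestamp[nr] else as.POSIXct(NA, tz = "UTC"))
  }, by = .(patient_id, session_id)]

  flagged_sess <- sess[flagged == TRUE, .(patient_id, session_id)]
  if (nrow(flagged_sess) > 0L) {
    v[, row_in_sess := seq_len(.N), by = .(patient_id, session_id)]
    v[, sess_n := .N, by = .(patient_id, session_id)]
    v[flagged_sess, on = .(patient_id, session_id),
      in_tail := row_in_sess > sess_n - window]
    v[in_tail == TRUE & hr_valid == TRUE,
      `:=`(hr_valid = FALSE, excl_reason = "removal_tail")]
    v[, c("row_in_sess", "sess_n", "in_tail") := NULL]
  }
  list(vitals = v[], sessions = sess)
}

#' Apply the measurement-level cleaning cascade to raw vitals
#'
#' Runs, in order: wear-session segmentation, the technical-range filter
#' (30-240 bpm by default), and removal-tail detection. The cascade is
#' idempotent: re-running it on its own cleaned output excludes nothing
#' further on artifact-free tails.
#'
#' @param vitals raw minute-level vitals.
#' @param config a cleaning configuration, see [default_config()]
#'   (`$clean`).
#' @return list with `vitals` (flag columns added), `sessions` (per-session
#'   removal flags) and `counts` (samples excluded per rule).
#' @export
clean_vitals <- function(vitals, config = default_config()$clean) {
  v <- segment_sessions(vitals, gap_threshold = config$gap_threshold)
  v <- filter_technical_range(v, lo = config$hr_range[1], hi = config$hr_range[2])
  det <- detect_removal_tails(v, window = config$tail_window,
                              temp_drop = config$temp_drop,
                              mad_mult = config$mad_mult,
                              vote_frac = config$vote_frac)
  v <- det$vitals
  counts <- list(
    n_samples = nrow(v),
    excluded_technical_range = sum(v$excl_reason == "technical_range", na.rm = TRUE),
    excluded_removal_tail = sum(v$excl_reason == "removal_tail", na.rm = TRUE),
    sessions_flagged = sum(det$sessions$flagged)
  )
  list(vitals = v, sessions = det$sessions, counts = counts)
}

#' Summarize cleaned streams per patient-day
#'
#' Aggregates the cleaned minute-level HR, hourly steps and PROM entries to
#' one row per patient and calendar day, applies the day-level inclusion
#' rules, and labels each day's perioperative phase:
#' \itemize{
#'   \item an HR day is included when at least `min_hr_minutes` (default
#'     60) valid HR minutes are available;
#'   \item a step day is included when valid HR minutes occur in at least
#'     `min_wear_hours` (default 8) distinct clock hours — wear time is
#'     inferred from the HR stream because hourly step records carry no
#'     wear indicator.
#' }
#'
#' @param vitals_clean cleaned vitals (output of [clean_vitals()]).
#' @param steps hourly step records.
#' @param proms PROM entries.
#' @param timelines patient timelines.
#' @param config cleaning configuration (see [default_config()]).
#' @return A data.table with one row per patient-day: counts, day means,
#'   inclusion flags and PROM day means per item.
#' @export
summarize_days <- function(vitals_clean, steps, proms, timelines,
                           config = default_config()$clean) {
  vv <- as.data.table(vitals_clean)
  if (!"hr_valid" %in% names(vv)) vv <- filter_technical_range(vv)
  hr_day <- vv[hr_valid == TRUE, {
    list(hr_minutes = .N, mean_hr = mean(hr), sd_hr = sd(hr),
         wear_hours = uniqueN(hour(timestamp)))
  }, by = .(patient_id, date = as.Date(timestamp, tz = "UTC"))]

  step_day <- as.data.table(steps)[, .(steps_total = sum(steps)),
                                   by = .(patient_id, date = as.Date(hour_start, tz = "UTC"))]

  pr <- as.data.table(proms)
  prom_day <- if (nrow(pr) > 0L) {
    long <- pr[, .(value = mean(score), n = .N),
               by = .(patient_id, date = as.Date(timestamp, tz = "UTC"), item)]
    wide <- dcast(long, patient_id + date ~ item, value.var = "value")
    for (it in setdiff(prom_items(), names(wide))) wide[, (it) := NA_real_]
    setnames(wide, prom_items(), paste0("prom_", prom_items()))
    ent <- pr[, .(prom_entries = uniqueN(timestamp)),
              by = .(patient_id, date = as.Date(timestamp, tz = "UTC"))]
    merge(wide, ent, by = c("patient_id", "date"))
  } else {
    data.table(patient_id = character(), date = as.Date(character()),
               prom_pain = numeric(), prom_anxiety = numeric(),
               prom_fatigue = numeric(), prom_nausea = numeric(),
               prom_entries = integer())
  }

  days <- Reduce(function(a, b) merge(a, b, by = c("patient_id", "date"), all = TRUE),
                 list(hr_day, step_day, prom_day))
  days[is.na(hr_minutes), hr_minutes := 0L]
  days[is.na(wear_hours), wear_hours := 0L]
  days[is.na(prom_entries), prom_entries := 0L]
  days[, hr_day_included := hr_minutes >= config$min_hr_minutes]
  days[, step_day_included := wear_hours >= config$min_wear_hours]
  days[, phase := assign_phase(.SD, as.data.table(timelines),
                               postop_window = config$postop_window)]
  setcolorder(days, c("patient_id", "date", "phase", "hr_minutes", "mean_hr",
                      "sd_hr", "hr_day_included", "wear_hours", "steps_total",
                      "step_day_included"))
  setorder(days, patient_id, date)
  days[]
}

#' Apply the patient-level inclusion rule
#'
#' A patient enters the analysis only with at least `min_preop_days`
#' qualifying preoperative home days, where a day qualifies when its HR day
#' is included or it has at least one PROM entry (one patient count is
#' applied across all parameters).
#'
#' @param day_summaries output of [summarize_days()].
#' @param min_preop_days minimum number of qualifying preoperative days.
#' @return list with `included` and `excluded` patient id vectors and the
#'   per-patient qualifying-day counts.
#' @export
filter_patients <- function(day_summaries, min_preop_days = 7L) {
  ds <- as.data.table(day_summaries)
  per_pat <- ds[, .(n_days = sum(phase == "preop_home" &
                                   (hr_day_included | prom_entries >= 1L))),
                by = patient_id]
  list(
    included = per_pat[n_days >= min_preop_days, patient_id],
    excluded = per_pat[n_days < min_preop_days, patient_id],
    counts = per_pat[]
  )
}

#' Run the full exclusion cascade on a cohort
#'
#' Measurement-level filters, day-level rules and the patient-level rule,
#' in that order, with an exhaustive cleaning report (each excluded sample,
#' day and patient is counted under exactly one rule).
#'
#' @param cohort a `wearable_cohort` or list with `vitals`, `steps`,
#'   `proms`, `timelines`.
#' @param config configuration list (see [default_config()]); `$clean` is
#'   used.
#' @return list of class `cleaned_cohort`: `vitals` (flagged), `sessions`,
#'   `day_summaries`, `included`/`excluded` patient ids, and `report`.
#' @export
clean_cohort <- function(cohort, config = default_config()) {
  cc <- config$clean
  cl <- clean_vitals(cohort$vitals, cc)
  days <- summarize_days(cl$vitals, cohort$steps, cohort$proms,
                         cohort$timelines, cc)
  pats <- filter_patients(days, min_preop_days = cc$min_preop_days)
  report <- cleaning_report(cl, days, pats)
  structure(
    list(vitals = cl$vitals, sessions = cl$sessions, day_summaries = days,
         included = pats$included, excluded = pats$excluded,
         patient_days = pats$counts, report = report,
         timelines = as.data.table(cohort$timelines),
         steps = as.data.table(cohort$steps),
         proms = as.data.table(cohort$proms), config = config),
    class = "cleaned_cohort"
  )
}

cleaning_report <- function(cl, days, pats) {
  ds <- as.data.table(days)
  list(
    measurements = cl$counts,
    days = list(
      hr_days_total = ds[hr_minutes > 0L, .N],
      hr_days_excluded = ds[hr_minutes > 0L & !hr_day_included, .N],
      step_days_total = ds[!is.na(steps_total), .N],
      step_days_excluded = ds[!is.na(steps_total) & !step_day_included, .N]
    ),
    patients = list(
      total = length(pats$included) + length(pats$excluded),
      included = length(pats$included),
      excluded = length(pats$excluded)
    )
  )
}

#' @export
print.cleaned_cohort <- function(x, ...) {
  r <- x$report
  cat("Cleaned telemonitoring cohort\n")
  cat(sprintf("  samples: %d (%d excluded by technical range, %d by removal-tail rule)\n",
              r$measurements$n_samples, r$measurements$excluded_technical_range,
              r$measurements$excluded_removal_tail))
  cat(sprintf("  HR days excluded: %d/%d; step days excluded: %d/%d\n",
              r$days$hr_days_excluded, r$days$hr_days_total,
              r$days$step_days_excluded, r$days$step_days_total))
  cat(sprintf("  patients included: %d/%d\n", r$patients$included,
              r$patients$total))
  invisible(x)
}
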