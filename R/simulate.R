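#' Generate a synthetic perioperative telemonitoring cohort
#'
#' Simulates the raw data streams of a home-telemonitoring study around
#' major surgery: minute-level heart rate and skin temperature during
#' waking-hour wear sessions, hourly step counts, twice-daily
#' patient-reported outcomes (morning entry at a random time between 09:00
#' and 13:00, evening entry at 20:00), and a per-patient timeline
#' (telemonitoring start, hospital admission, surgery the next day,
#' discharge). No home data are generated during the in-hospital stay.
#' Ground truth (each patient's true mean HR, daily step budget, and PROM
#' level) is returned alongside so downstream estimators can be validated
#' against known values.
#'
#' Wear sessions may contain one mid-day charging gap; whole days can be
#' missing; and, at rate `artifact_rate`, the final five minutes of a wear
#' session receive a sensor-removal artifact (temperature drop plus HR
#' spike) via [inject_removal_artifacts()], with every injected segment
#' recorded in the artifact log.
#'
#' The generator is fully deterministic given `params` (a single seed is
#' split hierarchically per patient, so enlarging the cohort never perturbs
#' earlier patients' data).
#'
#' @param params a [sim_params()] object.
#' @return An object of class `wearable_cohort`: a list with data.tables
#'   `vitals` (patient_id, timestamp, hr, skin_temp), `steps` (patient_id,
#'   hour_start, steps), `proms` (patient_id, timestamp, item, score),
#'   `timelines`, `truth`, `artifact_log`, plus the `params` used.
#' @seealso [write_cohort()], [clean_cohort()]
#' @export
#' @examples
#' coh <- generate_cohort(sim_params(n_patients = 2, preop_days = 8,
#'                                   postop_days = 5, seed = 1))
#' coh$timelines
generate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) {
    params <- do.call(sim_params, as.list(params))
  }
  p <- params
  items <- prom_items()
  vit <- stp <- prm <- tl <- tr <- vector("list", p$n_patients)

  wake_min <- (p$wake_end - p$wake_start) * 60L
  wake_grid <- p$wake_start * 60L + seq_len(wake_min) - 1L
  # circadian term centred on the wear window so that, absent day and minute
  # noise, a full day's mean HR equals the patient's true mean exactly
  circ_of <- function(minute_of_day) {
    p$circadian_amplitude * sin(2 * pi * (minute_of_day / 60 - 10) / 24)
  }
  circ_center <- mean(circ_of(wake_grid))

  for (i in seq_len(p$n_patients)) {
    set.seed(derive_seed(p$seed, i))
    pid <- sprintf("P%03d", i)
    n_pre <- if (length(p$preop_days) == 2L) {
      sample(seq(p$preop_days[1], p$preop_days[2]), 1L)
    } else p$preop_days
    mon_start <- p$start_date + 7L * (i - 1L)
    admission <- mon_start + n_pre
    surgery <- admission + 1L
    discharge <- surgery + p$los_days

    hr_true <- p$hr_cohort_mean + rnorm(1, 0, p$sigma_between_hr)
    step_budget <- exp(rnorm(1, p$step_mean_log, p$step_sd_log))
    temp_true <- p$temp_baseline + rnorm(1, 0, p$temp_patient_sd)
    prom_true <- clamp(rnorm(length(items), p$prom_patient_mean[items],
                             p$prom_between_sd), 0, 10)
    names(prom_true) <- items

    pre_dates <- seq(mon_start, admission - 1L, by = "day")
    post_end <- surgery + p$postop_days
    post_dates <- if (discharge + 1L <= post_end) {
      seq(discharge + 1L, post_end, by = "day")
    } else as.Date(character())
    dd <- data.table(
      date = c(pre_dates, post_dates),
      postop = rep(c(FALSE, TRUE), c(length(pre_dates), length(post_dates)))
    )
    nd <- nrow(dd)
    dd[, missing_day := runif(nd) < p$missing_day_rate]
    dd[, day_off := rnorm(nd, 0, p$sigma_day_hr)]
    dd[, mult := exp(rnorm(nd, 0, p$step_day_dispersion) -
                       p$step_day_dispersion^2 / 2)]
    dd[, gap := runif(nd) < p$daily_gap_rate]
    dd[, gap_start := floor(runif(nd, 11 * 60, 15 * 60))]

    wd <- dd[missing_day == FALSE]
    if (nrow(wd) > 0L) {
      # minute-level vitals over the wear window, minus the charging gap
      mdt <- wd[rep(seq_len(.N), each = wake_min)]
      mdt[, minute_of_day := rep(wake_grid, times = nrow(wd))]
      mdt <- mdt[!(gap & minute_of_day >= gap_start &
                     minute_of_day < gap_start + p$daily_gap_minutes)]
      nm <- nrow(mdt)
      hrv <- hr_true + mdt$day_off +
        ifelse(mdt$postop, p$postop_hr_shift, 0) +
        circ_of(mdt$minute_of_day) - circ_center +
        rnorm(nm, 0, p$sigma_minute_hr)
      vit[[i]] <- data.table(
        patient_id = pid,
        timestamp = as.POSIXct(mdt$date, tz = "UTC") + mdt$minute_of_day * 60,
        hr = clamp(hrv, 30, 240),
        skin_temp = temp_true + rnorm(nm, 0, p$temp_minute_sd)
      )

      # hourly step counts: daily budget spread over wake hours with a
      # mid-afternoon activity profile and multiplicative hour noise
      hrs <- p$wake_start:(p$wake_end - 1L)
      sdt <- wd[rep(seq_len(.N), each = length(hrs))]
      sdt[, hour := rep(hrs, times = nrow(wd))]
      sdt[, weight := (stats::dnorm(hour, 14, 3) + 0.05) *
            rgamma(.N, shape = 2, rate = 2)]
      first_day <- mon_start
      sdt[, day_total := {
        tot <- step_budget * mult[1L] *
          (if (postop[1L]) p$postop_step_multiplier else 1)
        if (date[1L] == first_day) tot <- tot + p$first_day_step_shift
        max(0, round(tot))
      }, by = date]
      sdt[, steps := {
        cs <- round(cumsum(weight) / sum(weight) * day_total[1L])
        as.integer(diff(c(0, cs)))
      }, by = date]
      stp[[i]] <- data.table(
        patient_id = pid,
        hour_start = as.POSIXct(sdt$date, tz = "UTC") + sdt$hour * 3600,
        steps = sdt$steps
      )
    }

    # PROM entries happen on all home days (tablet, independent of wear)
    morn_present <- runif(nd) >= p$prom_missing_rate
    morn_min <- 9L * 60L + floor(runif(nd) * 240)
    eve_present <- runif(nd) >= p$prom_missing_rate
    ent <- rbind(
      dd[morn_present, .(date, postop, time_min = morn_min[morn_present])],
      dd[eve_present, .(date, postop, time_min = 20L * 60L)]
    )
    if (nrow(ent) > 0L) {
      ent <- ent[rep(seq_len(.N), each = length(items))]
      ent[, item := rep(items, times = .N / length(items))]
      dsurg <- as.integer(ent$date - surgery)
      boost <- ifelse(ent$item == "pain" & ent$postop,
                      p$postop_pain_peak * pmax(0, 1 - dsurg / p$postop_days),
                      0)
      sc <- clamp(prom_true[ent$item] + boost +
                    rnorm(nrow(ent), 0, p$prom_within_sd), 0, 10)
      prm[[i]] <- data.table(
        patient_id = pid,
        timestamp = as.POSIXct(ent$date, tz = "UTC") + ent$time_min * 60,
        item = ent$item,
        score = round(sc, 1)
      )
    }

    tl[[i]] <- data.table(
      patient_id = pid, monitoring_start = mon_start,
      admission_date = admission, surgery_date = surgery,
      discharge_date = discharge
    )
    tr[[i]] <- data.table(
      patient_id = pid, true_hr = hr_true, true_steps = step_budget,
      true_pain = prom_true[["pain"]], true_anxiety = prom_true[["anxiety"]],
      true_fatigue = prom_true[["fatigue"]], true_nausea = prom_true[["nausea"]]
    )
  }

  vitals <- rbindlist(vit[!vapply(vit, is.null, logical(1))])
  steps <- rbindlist(stp[!vapply(stp, is.null, logical(1))])
  proms <- rbindlist(prm[!vapply(prm, is.null, logical(1))])
  timelines <- rbindlist(tl)
  truth <- rbindlist(tr)
  if (nrow(vitals)) setorder(vitals, patient_id, timestamp)
  if (nrow(steps)) setorder(steps, patient_id, hour_start)
  if (nrow(proms)) setorder(proms, patient_id, timestamp, item)

  art_log <- empty_artifact_log()
  if (p$artifact_rate > 0 && nrow(vitals) > 0L) {
    inj <- inject_removal_artifacts(
      vitals, rate = p$artifact_rate, temp_drop = p$artifact_temp_drop,
      hr_boost = p$artifact_hr_boost, mad_mult = p$artifact_mad_mult,
      seed = derive_seed(p$seed, 0L)
    )
    vitals <- inj$vitals
    art_log <- inj$log
  }

  structure(
    list(vitals = vitals, steps = steps, proms = proms,
         timelines = timelines, truth = truth, artifact_log = art_log,
         params = p),
    class = "wearable_cohort"
  )
}

#' @export
print.wearable_cohort <- function(x, ...) {
  cat(sprintf("Synthetic telemonitoring cohort: %d patients\n",
              nrow(x$timelines)))
  cat(sprintf("  %d minute-level vital samples, %d hourly step records, %d PROM entries\n",
              nrow(x$vitals), nrow(x$steps), nrow(x$proms)))
  cat(sprintf("  %d injected removal artifacts\n",
              nrow(x$artifact_log[skipped == FALSE])))
  invisible(x)
}

empty_artifact_log <- function() {
  data.table(
    patient_id = character(), session_id = integer(),
    start_ts = as.POSIXct(character(), tz = "UTC"),
    end_ts = as.POSIXct(character(), tz = "UTC"),
    n_minutes = integer(), hr_boost = numeric(), skipped = logical()
  )
}

#' Inject end-of-session sensor-removal artifacts
#'
#' Emulates the signature left when a wearable is taken off but not put on
#' its charger: for each selected wear session the final `window` minutes
#' get skin temperature lowered by `temp_drop` below the session's
#' pre-tail median and heart rate raised by a boost. The boost is either a
#' fixed `hr_boost` in bpm or, when `hr_boost` is `NULL`/`NA`,
#' `mad_mult` times the raw median absolute deviation of the session's
#' pre-tail HR — i.e. scaled to the same robust statistic the removal
#' detector thresholds on. Sessions shorter than `window + 1` minutes are
#' never modified; if selected, they are logged as skipped.
#'
#' @param vitals minute-level vitals data.table (patient_id, timestamp, hr,
#'   skin_temp), sorted within patient.
#' @param rate probability in \[0, 1\] that a session receives an artifact.
#' @param temp_drop temperature drop in deg C.
#' @param hr_boost fixed HR boost in bpm, or `NULL`/`NA` for the MAD-scaled
#'   boost.
#' @param mad_mult MAD multiplier for the scaled boost.
#' @param window artifact length in minutes (the session tail).
#' @param gap_threshold maximum inter-sample gap, in minutes, within a wear
#'   session (see [segment_sessions()]).
#' @param seed optional integer seed for the session-selection draws.
#' @return list with `vitals` (modified copy) and `log`, a data.table of
#'   injected segments (exact minute ranges) and skipped selections.
#' @export
inject_removal_artifacts <- function(vitals, rate, temp_drop = 0.6,
                                     hr_boost = NULL, mad_mult = 5,
                                     window = 5L, gap_threshold = 5,
                                     seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop_param("rate", "must be a probability in [0, 1]")
  }
  log0 <- empty_artifact_log()
  if (rate == 0 || nrow(vitals) == 0L) {
    return(list(vitals = copy(vitals), log = log0))
  }
  if (!is.null(seed)) set.seed(seed)
  fixed_boost <- !is.null(hr_boost) && !is.na(hr_boost)

  v <- segment_sessions(vitals, gap_threshold = gap_threshold)
  sess <- v[, .(n = .N), by = .(patient_id, session_id)]
  sess[, selected := runif(.N) < rate]
  sess[, eligible := n >= window + 1L]

  sel <- sess[selected == TRUE & eligible == TRUE, .(patient_id, session_id)]
  info <- NULL
  if (nrow(sel) > 0L) {
    vs <- v[sel, on = .(patient_id, session_id)]
    info <- vs[, {
      pre_hr <- head(hr, .N - window)
      pre_tmp <- head(skin_temp, .N - window)
      b <- if (fixed_boost) hr_boost else
        mad_mult * stats::mad(pre_hr[!is.na(pre_hr)], constant = 1)
      list(
        pre_med_temp = stats::median(pre_tmp, na.rm = TRUE),
        boost = b,
        start_ts = timestamp[.N - window + 1L],
        end_ts = timestamp[.N],
        n_minutes = window
      )
    }, by = .(patient_id, session_id)]
    v[, row_in_sess := seq_len(.N), by = .(patient_id, session_id)]
    v[, sess_n := .N, by = .(patient_id, session_id)]
    v[info, on = .(patient_id, session_id),
      `:=`(boost = i.boost, pre_med_temp = i.pre_med_temp)]
    tail_rows <- !is.na(v$boost) & v$row_in_sess > v$sess_n - window
    v[tail_rows, `:=`(hr = pmin(240, hr + boost),
                      skin_temp = pre_med_temp - temp_drop)]
    v[, c("row_in_sess", "sess_n", "boost", "pre_med_temp") := NULL]
  }

  skipped <- sess[selected == TRUE & eligible == FALSE]
  lg <- rbind(
    if (!is.null(info)) {
      info[, .(patient_id, session_id, start_ts, end_ts, n_minutes,
               hr_boost = boost, skipped = FALSE)]
    } else log0,
    if (nrow(skipped) > 0L) {
      data.table(patient_id = skipped$patient_id,
                 session_id = skipped$session_id,
                 start_ts = as.POSIXct(NA, tz = "UTC"),
                 end_ts = as.POSIXct(NA, tz = "UTC"),
                 n_minutes = NA_integer_, hr_boost = NA_real_,
                 skipped = TRUE)
    } else NULL
  )
  setorder(lg, patient_id, session_id)
  v[, session_id := NULL]
  list(vitals = v[], log = lg[])
}
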