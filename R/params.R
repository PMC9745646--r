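#' Parameters for the synthetic perioperative cohort
#'
#' `sim_params()` collects every knob of the synthetic-data generator in a
#' validated object. The defaults emulate the measurement design of a
#' perioperative telemonitoring study of major abdominal surgery patients:
#' an upper-arm wearable worn during waking hours (charged overnight) storing
#' heart rate once per minute and step count once per hour, plus twice-daily
#' patient-reported outcomes (VAS 0-10) on a tablet.
#'
#' Heart rate is built additively: cohort mean + patient offset
#' (`sigma_between_hr`) + day offset (`sigma_day_hr`) + a sinusoidal
#' circadian term + minute noise (`sigma_minute_hr`), clipped to 30-240 bpm.
#' This decomposition makes the reliability of a d-day mean analytically
#' `sigma_between^2 / (sigma_between^2 + sigma_day^2 / d)`, the quantity the
#' reliability stage estimates empirically via the ICC. Daily step budgets
#' are log-normal between patients with a multiplicative day-to-day
#' dispersion; VAS scores are Gaussian clamped to [0, 10].
#'
#' @param n_patients number of patients enrolled.
#' @param preop_days length of the home telemonitoring period before
#'   hospital admission, in days; either a single count or a
#'   `c(min, max)` range sampled uniformly per patient.
#' @param postop_days length of the postoperative observation window
#'   counted from the day of surgery (home data are generated only after
#'   discharge).
#' @param los_days hospital length of stay: discharge is
#'   `surgery + los_days`.
#' @param hr_cohort_mean cohort mean heart rate, bpm.
#' @param sigma_between_hr SD of patient-level mean HR around the cohort
#'   mean, bpm.
#' @param sigma_day_hr SD of day-level HR offsets within patient, bpm.
#' @param sigma_minute_hr minute-level HR noise SD, bpm.
#' @param circadian_amplitude amplitude of the sinusoidal within-day HR
#'   term, bpm (peak mid-afternoon).
#' @param postop_hr_shift additive HR shift on postoperative home days, bpm.
#' @param step_mean_log,step_sd_log log-scale mean and SD of the
#'   patient-level daily step budget (log-normal between patients).
#' @param step_day_dispersion within-patient day-to-day multiplicative SD of
#'   the daily step total (log scale; the multiplier has mean 1).
#' @param postop_step_multiplier multiplier applied to daily step budgets on
#'   postoperative home days (activity suppression after surgery).
#' @param first_day_step_shift additive shift, in steps, applied to the
#'   first telemonitoring day's step total (behavioural first-day effect;
#'   negative values are a first-day deficit).
#' @param prom_patient_mean named numeric: cohort-level mean VAS per item
#'   (`pain`, `anxiety`, `fatigue`, `nausea`).
#' @param prom_between_sd SD of patient-level mean VAS around
#'   `prom_patient_mean`, VAS units.
#' @param prom_within_sd entry-to-entry VAS noise SD within patient.
#' @param prom_missing_rate probability that a scheduled PROM entry is
#'   skipped.
#' @param postop_pain_peak added pain VAS immediately after surgery,
#'   decaying linearly to zero over `postop_days`.
#' @param wake_start,wake_end clock hours delimiting the daily wear window
#'   (sensor charged outside it).
#' @param daily_gap_rate probability that a worn day contains one mid-day
#'   charging/doffing gap.
#' @param daily_gap_minutes length of that gap, minutes.
#' @param temp_baseline cohort mean skin temperature, deg C.
#' @param temp_patient_sd,temp_minute_sd patient-level and minute-level skin
#'   temperature SDs, deg C.
#' @param artifact_rate probability per wear session of an end-of-session
#'   removal artifact (sensor taken off but not put on the charger).
#' @param artifact_temp_drop temperature drop injected in artifact tails,
#'   deg C.
#' @param artifact_hr_boost HR boost injected in artifact tails, bpm; `NA`
#'   (the default) scales the boost per session as
#'   `artifact_mad_mult` x MAD of the session's pre-tail HR.
#' @param artifact_mad_mult MAD multiplier used when `artifact_hr_boost` is
#'   `NA`.
#' @param missing_day_rate probability that a home day has no sensor data at
#'   all (device not worn).
#' @param start_date calendar date at which the first patient starts
#'   telemonitoring; subsequent patients are staggered weekly.
#' @param seed integer seed; identical `sim_params` (including seed) yield
#'   byte-identical generated data.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' p <- sim_params(n_patients = 4, preop_days = 10, seed = 7)
#' p$sigma_between_hr
sim_params <- function(n_patients = 20L,
                       preop_days = c(10L, 40L),
                       postop_days = 30L,
                       los_days = 7L,
                       hr_cohort_mean = 75,
                       sigma_between_hr = 8,
                       sigma_day_hr = 4,
                       sigma_minute_hr = 7,
                       circadian_amplitude = 6,
                       postop_hr_shift = 3,
                       step_mean_log = log(2500),
                       step_sd_log = 0.7,
                       step_day_dispersion = 0.45,
                       postop_step_multiplier = 0.35,
                       first_day_step_shift = -500,
                       prom_patient_mean = c(pain = 1.5, anxiety = 1.2,
                                             fatigue = 1.5, nausea = 0.8),
                       prom_between_sd = 1.5,
                       prom_within_sd = 0.8,
                       prom_missing_rate = 0.1,
                       postop_pain_peak = 3,
                       wake_start = 8L,
                       wake_end = 22L,
                       daily_gap_rate = 0.3,
                       daily_gap_minutes = 45L,
                       temp_baseline = 33.5,
                       temp_patient_sd = 0.3,
                       temp_minute_sd = 0.1,
                       artifact_rate = 0.1,
                       artifact_temp_drop = 0.6,
                       artifact_hr_boost = NA_real_,
                       artifact_mad_mult = 5,
                       missing_day_rate = 0.05,
                       start_date = as.Date("2020-03-02"),
                       seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients),
    preop_days = as.integer(preop_days),
    postop_days = as.integer(postop_days),
    los_days = as.integer(los_days),
    hr_cohort_mean = hr_cohort_mean,
    sigma_between_hr = sigma_between_hr,
    sigma_day_hr = sigma_day_hr,
    sigma_minute_hr = sigma_minute_hr,
    circadian_amplitude = circadian_amplitude,
    postop_hr_shift = postop_hr_shift,
    step_mean_log = step_mean_log,
    step_sd_log = step_sd_log,
    step_day_dispersion = step_day_dispersion,
    postop_step_multiplier = postop_step_multiplier,
    first_day_step_shift = first_day_step_shift,
    prom_patient_mean = prom_patient_mean,
    prom_between_sd = prom_between_sd,
    prom_within_sd = prom_within_sd,
    prom_missing_rate = prom_missing_rate,
    postop_pain_peak = postop_pain_peak,
    wake_start = as.integer(wake_start),
    wake_end = as.integer(wake_end),
    daily_gap_rate = daily_gap_rate,
    daily_gap_minutes = as.integer(daily_gap_minutes),
    temp_baseline = temp_baseline,
    temp_patient_sd = temp_patient_sd,
    temp_minute_sd = temp_minute_sd,
    artifact_rate = artifact_rate,
    artifact_temp_drop = artifact_temp_drop,
    artifact_hr_boost = artifact_hr_boost,
    artifact_mad_mult = artifact_mad_mult,
    missing_day_rate = missing_day_rate,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

validate_sim_params <- function(p) {
  chk_count <- function(field, x, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      stop_param(field, sprintf("must be a single integer >= %d", min))
  }
  chk_nonneg <- function(field, x) {
    if (length(x) != 1L || is.na(x) || x < 0)
      stop_param(field, "must be a single nonnegative number")
  }
  chk_rate <- function(field, x) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop_param(field, "must be a probability in [0, 1]")
  }
  chk_count("n_patients", p$n_patients)
  if (!length(p$preop_days) %in% 1:2 || anyNA(p$preop_days) ||
      any(p$preop_days < 1L) || is.unsorted(p$preop_days))
    stop_param("preop_days", "must be a positive count or an increasing c(min, max) range")
  chk_count("postop_days", p$postop_days)
  chk_count("los_days", p$los_days)
  for (f in c("sigma_between_hr", "sigma_day_hr", "sigma_minute_hr",
              "circadian_amplitude", "step_sd_log", "step_day_dispersion",
              "prom_between_sd", "prom_within_sd", "postop_pain_peak",
              "temp_patient_sd", "temp_minute_sd", "artifact_temp_drop",
              "artifact_mad_mult"))
    chk_nonneg(f, p[[f]])
  for (f in c("daily_gap_rate", "missing_day_rate", "artifact_rate",
              "prom_missing_rate"))
    chk_rate(f, p[[f]])
  if (p$postop_step_multiplier < 0)
    stop_param("postop_step_multiplier", "must be nonnegative")
  if (p$wake_start >= p$wake_end)
    stop_param("wake_start", "wake_start must be strictly before wake_end")
  if (p$wake_start < 0L || p$wake_end > 24L)
    stop_param("wake_end", "wear window must lie within 0-24 h")
  items <- c("pain", "anxiety", "fatigue", "nausea")
  if (!all(items %in% names(p$prom_patient_mean)))
    stop_param("prom_patient_mean", "must name pain, anxiety, fatigue and nausea")
  if (any(p$prom_patient_mean < 0 | p$prom_patient_mean > 10))
    stop_param("prom_patient_mean", "VAS means must lie in [0, 10]")
  if (length(p$seed) != 1L || is.na(p$seed))
    stop_param("seed", "must be a single integer")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  %d patients, preop %s days at home, postop window %d days (LOS %d)\n",
              x$n_patients, paste(x$preop_days, collapse = "-"),
              x$postop_days, x$los_days))
  cat(sprintf("  HR: mean %.0f bpm, SD between %.1f / day %.1f / minute %.1f, circadian %.1f\n",
              x$hr_cohort_mean, x$sigma_between_hr, x$sigma_day_hr,
              x$sigma_minute_hr, x$circadian_amplitude))
  cat(sprintf("  steps: exp(N(%.2f, %.2f)) budget, day dispersion %.2f, postop x%.2f\n",
              x$step_mean_log, x$step_sd_log, x$step_day_dispersion,
              x$postop_step_multiplier))
  cat(sprintf("  wear %02d:00-%02d:00, gap rate %.2f, missing-day rate %.2f, artifact rate %.2f\n",
              x$wake_start, x$wake_end, x$daily_gap_rate,
              x$missing_day_rate, x$artifact_rate))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Deterministic per-patient substream seed so that adding a patient never
# perturbs earlier patients' draws. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 48271 + index * 9973) %% 2147483647)
}

prom_items <- function() c("pain", "anxiety", "fatigue", "nausea")

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
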