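#' Read one of the canonical telemonitoring CSV streams
#'
#' The pipeline exchanges four UTF-8, comma-separated files with ISO-8601
#' timestamps:
#' \describe{
#'   \item{vitals}{`patient_id,timestamp,hr,skin_temp` — minute-level heart
#'     rate (bpm, positive or empty) and skin temperature (deg C or empty).}
#'   \item{steps}{`patient_id,hour_start,steps` — hourly step counts,
#'     `hour_start` truncated to the hour, `steps` a nonnegative integer.}
#'   \item{proms}{`patient_id,timestamp,item,score` — VAS 0-10 entries for
#'     pain, anxiety, fatigue, nausea.}
#'   \item{timeline}{`patient_id,monitoring_start,admission_date,
#'     surgery_date,discharge_date` — one row per patient;
#'     `discharge_date` may be empty.}
#' }
#' Rows violating the per-row invariants (unparseable timestamps, VAS
#' outside 0-10, negative steps, nonpositive HR) are rejected with their row
#' numbers; duplicated patient-minute or patient-hour keys are an error
#' naming the offending rows.
#'
#' @param path path to the CSV file.
#' @param kind one of `"vitals"`, `"steps"`, `"proms"`, `"timeline"`.
#' @return A validated data.table, sorted by patient and time.
#' @seealso [write_stream()], [read_cohort()]
#' @export
read_stream <- function(path, kind = c("vitals", "steps", "proms", "timeline")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- fread(path, colClasses = "character", na.strings = c("", "NA"))
  need <- stream_schema(kind)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- x[, need, with = FALSE]
  switch(kind,
    vitals = validate_vitals(x, path),
    steps = validate_steps(x, path),
    proms = validate_proms(x, path),
    timeline = validate_timeline(x, path)
  )
}

stream_schema <- function(kind) {
  switch(kind,
    vitals = c("patient_id", "timestamp", "hr", "skin_temp"),
    steps = c("patient_id", "hour_start", "steps"),
    proms = c("patient_id", "timestamp", "item", "score"),
    timeline = c("patient_id", "monitoring_start", "admission_date",
                 "surgery_date", "discharge_date")
  )
}

fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_ts <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

row_error <- function(path, rows, what) {
  rows <- utils::head(rows, 20L)
  stop(sprintf("invalid rows in %s (%s): row(s) %s", path, what,
               paste(rows, collapse = ", ")), call. = FALSE)
}

dup_error <- function(path, key, idx) {
  stop(sprintf("duplicate %s key(s) in %s: rows %s", key, path,
               paste(utils::head(idx, 20L), collapse = ", ")), call. = FALSE)
}

validate_vitals <- function(x, path) {
  ts <- parse_ts(x$timestamp)
  if (anyNA(ts)) row_error(path, which(is.na(ts)), "unparseable timestamp")
  hr <- suppressWarnings(as.numeric(x$hr))
  bad_hr <- !is.na(x$hr) & (is.na(hr) | hr <= 0)
  if (any(bad_hr)) row_error(path, which(bad_hr), "heart rate not a positive number")
  tmp <- suppressWarnings(as.numeric(x$skin_temp))
  bad_tmp <- !is.na(x$skin_temp) & is.na(tmp)
  if (any(bad_tmp)) row_error(path, which(bad_tmp), "unparseable skin temperature")
  key <- paste(x$patient_id, trunc(ts, "mins"))
  if (anyDuplicated(key)) {
    d <- which(key %in% key[duplicated(key)])
    dup_error(path, "patient-minute", d)
  }
  out <- data.table(patient_id = x$patient_id, timestamp = ts,
                    hr = hr, skin_temp = tmp)
  setorder(out, patient_id, timestamp)
  out[]
}

validate_steps <- function(x, path) {
  ts <- parse_ts(x$hour_start)
  if (anyNA(ts)) row_error(path, which(is.na(ts)), "unparseable hour_start")
  off_hour <- as.POSIXlt(ts, tz = "UTC")
  bad_hour <- off_hour$min != 0L | off_hour$sec != 0
  if (any(bad_hour)) row_error(path, which(bad_hour), "hour_start not truncated to the hour")
  st <- suppressWarnings(as.numeric(x$steps))
  bad <- is.na(st) | st < 0 | st != round(st)
  if (any(bad)) row_error(path, which(bad), "steps not a nonnegative integer")
  key <- paste(x$patient_id, ts)
  if (anyDuplicated(key)) {
    d <- which(key %in% key[duplicated(key)])
    dup_error(path, "patient-hour", d)
  }
  out <- data.table(patient_id = x$patient_id, hour_start = ts,
                    steps = as.integer(st))
  setorder(out, patient_id, hour_start)
  out[]
}

validate_proms <- function(x, path) {
  ts <- parse_ts(x$timestamp)
  if (anyNA(ts)) row_error(path, which(is.na(ts)), "unparseable timestamp")
  bad_item <- !x$item %in% prom_items()
  if (any(bad_item)) row_error(path, which(bad_item), "unknown PROM item")
  sc <- suppressWarnings(as.numeric(x$score))
  bad <- is.na(sc) | sc < 0 | sc > 10
  if (any(bad)) row_error(path, which(bad), "VAS score outside [0, 10]")
  out <- data.table(patient_id = x$patient_id, timestamp = ts,
                    item = x$item, score = sc)
  setorder(out, patient_id, timestamp, item)
  out[]
}

validate_timeline <- function(x, path) {
  pd <- function(col) as.Date(x[[col]], format = "%Y-%m-%d")
  ms <- pd("monitoring_start"); ad <- pd("admission_date")
  sg <- pd("surgery_date"); dc <- pd("discharge_date")
  bad <- (is.na(ms) & !is.na(x$monitoring_start)) | is.na(ms) |
    is.na(ad) | is.na(sg)
  if (any(bad)) row_error(path, which(bad), "unparseable or missing date")
  bad_order <- !(ms < ad & ad <= sg) | (!is.na(dc) & dc < sg)
  if (any(bad_order)) {
    row_error(path, which(bad_order),
              "dates must satisfy monitoring_start < admission <= surgery <= discharge")
  }
  if (anyDuplicated(x$patient_id)) {
    dup_error(path, "patient", which(x$patient_id %in% x$patient_id[duplicated(x$patient_id)]))
  }
  out <- data.table(patient_id = x$patient_id, monitoring_start = ms,
                    admission_date = ad, surgery_date = sg,
                    discharge_date = dc)
  setorder(out, patient_id)
  out[]
}

#' Write a data stream in its canonical CSV form
#'
#' Formats timestamps as ISO-8601 (`%Y-%m-%dT%H:%M:%S`, UTC) and rounds
#' continuous sensor channels to three decimals, so that
#' `write(read(file))` reproduces `file` byte for byte for canonical files.
#'
#' @param x the data.table to write.
#' @param path output path.
#' @param kind one of `"vitals"`, `"steps"`, `"proms"`, `"timeline"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(x, path, kind = c("vitals", "steps", "proms", "timeline")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    vitals = data.table(patient_id = x$patient_id, timestamp = fmt_ts(x$timestamp),
                        hr = round(x$hr, 3), skin_temp = round(x$skin_temp, 3)),
    steps = data.table(patient_id = x$patient_id, hour_start = fmt_ts(x$hour_start),
                       steps = x$steps),
    proms = data.table(patient_id = x$patient_id, timestamp = fmt_ts(x$timestamp),
                       item = x$item, score = round(x$score, 3)),
    timeline = data.table(patient_id = x$patient_id,
                          monitoring_start = format(x$monitoring_start),
                          admission_date = format(x$admission_date),
                          surgery_date = format(x$surgery_date),
                          discharge_date = ifelse(is.na(x$discharge_date), "",
                                                  format(x$discharge_date)))
  )
  fwrite(out, path, na = "")
  invisible(path)
}

#' Write all streams of a cohort to a directory
#'
#' Emits `vitals.csv`, `steps.csv`, `proms.csv`, `timeline.csv` and, for
#' synthetic cohorts, `ground_truth.csv` and `artifact_log.csv`.
#'
#' @param cohort a `wearable_cohort` (or a plain list with the same
#'   elements).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stream(cohort$vitals, file.path(dir, "vitals.csv"), "vitals")
  write_stream(cohort$steps, file.path(dir, "steps.csv"), "steps")
  write_stream(cohort$proms, file.path(dir, "proms.csv"), "proms")
  write_stream(cohort$timelines, file.path(dir, "timeline.csv"), "timeline")
  if (!is.null(cohort$truth)) {
    fwrite(cohort$truth, file.path(dir, "ground_truth.csv"))
  }
  if (!is.null(cohort$artifact_log)) {
    al <- copy(cohort$artifact_log)
    al[, `:=`(start_ts = fmt_ts(start_ts), end_ts = fmt_ts(end_ts))]
    fwrite(al, file.path(dir, "artifact_log.csv"), na = "")
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the four canonical CSVs.
#' @return A `wearable_cohort`-shaped list (without ground truth unless
#'   present on disk).
#' @export
read_cohort <- function(dir) {
  out <- list(
    vitals = read_stream(file.path(dir, "vitals.csv"), "vitals"),
    steps = read_stream(file.path(dir, "steps.csv"), "steps"),
    proms = read_stream(file.path(dir, "proms.csv"), "proms"),
    timelines = read_stream(file.path(dir, "timeline.csv"), "timeline")
  )
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) out$truth <- fread(gt)
  structure(out, class = "wearable_cohort")
}

#' Classify a calendar day within a patient's perioperative timeline
#'
#' Days from `monitoring_start` up to (but excluding) `admission_date` are
#' preoperative home days; admission through discharge is the in-hospital
#' stay; days after discharge up to `surgery_date + postop_window` are
#' postoperative home days; anything else is out of window. When
#' `discharge_date` is missing the patient is treated as still in hospital
#' for the rest of the window, so no postoperative home days exist.
#'
#' @param timeline a one-row timeline (list or data.table row) with
#'   `monitoring_start`, `admission_date`, `surgery_date`,
#'   `discharge_date`.
#' @param date a `Date` vector.
#' @param postop_window days after surgery included in the observation
#'   window.
#' @return Character vector: `"preop_home"`, `"in_hospital"`,
#'   `"postop_home"` or `"out_of_window"`.
#' @export
#' @examples
#' tl <- list(monitoring_start = as.Date("2020-03-02"),
#'            admission_date = as.Date("2020-03-20"),
#'            surgery_date = as.Date("2020-03-21"),
#'            discharge_date = as.Date("2020-03-28"))
#' phase_of_day(tl, as.Date("2020-03-19"))  # preop_home
#' phase_of_day(tl, as.Date("2020-03-21"))  # in_hospital
phase_of_day <- function(timeline, date, postop_window = 30L) {
  date <- as.Date(date)
  ms <- as.Date(timeline$monitoring_start)
  ad <- as.Date(timeline$admission_date)
  sg <- as.Date(timeline$surgery_date)
  dc <- as.Date(timeline$discharge_date)
  win_end <- sg + postop_window
  res <- rep("out_of_window", length(date))
  res[date >= ms & date < ad] <- "preop_home"
  hosp_end <- if (length(dc) == 0L || is.na(dc)) win_end else dc
  res[date >= ad & date <= hosp_end] <- "in_hospital"
  if (length(dc) == 1L && !is.na(dc)) {
    res[date > dc & date <= win_end] <- "postop_home"
  }
  res
}

# Vectorised phase assignment by joining day rows to their timelines.
assign_phase <- function(days, timelines, postop_window = 30L) {
  d <- merge(days, timelines, by = "patient_id", all.x = TRUE, sort = FALSE)
  win_end <- d$surgery_date + postop_window
  hosp_end <- fifelse(is.na(d$discharge_date), win_end, d$discharge_date)
  phase <- rep("out_of_window", nrow(d))
  phase[d$date >= d$monitoring_start & d$date < d$admission_date] <- "preop_home"
  phase[d$date >= d$admission_date & d$date <= hosp_end] <- "in_hospital"
  sel <- !is.na(d$discharge_date) & d$date > d$discharge_date & d$date <= win_end
  phase[sel] <- "postop_home"
  phase
}
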