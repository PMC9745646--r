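#' Align patient-days on the perioperative anchors
#'
#' Indexes each included home day relative to the study's two anchors:
#' preoperative home days get negative indices counted back from hospital
#' admission (`-1` = day before admission), postoperative home days get
#' positive indices counted from surgery (`+1` = day after surgery).
#' In-hospital days are dropped, and the postoperative range only contains
#' days after discharge. Day values follow the cleaning rules: HR day
#' means for included HR days, step totals for included step days, PROM
#' day means for days with entries.
#'
#' @param cleaned a `cleaned_cohort`.
#' @param preop_window days before admission to keep (default 14).
#' @param postop_window days after surgery to keep (default 30).
#' @param patients patient ids; defaults to included patients.
#' @return Long data.table: `patient_id`, `parameter`, `day_index`,
#'   `value`.
#' @export
align_days <- function(cleaned, preop_window = 14L, postop_window = 30L,
                       patients = cleaned$included) {
  ds <- cleaned$day_summaries[patient_id %in% patients]
  tl <- cleaned$timelines[patient_id %in% patients,
                          .(patient_id, admission_date, surgery_date)]
  ds <- merge(ds, tl, by = "patient_id")
  ds[, day_index := NA_integer_]
  ds[phase == "preop_home",
     day_index := as.integer(date - admission_date)]
  ds[phase == "postop_home",
     day_index := as.integer(date - surgery_date)]
  ds <- ds[(phase == "preop_home" & day_index >= -preop_window) |
             (phase == "postop_home" & day_index <= postop_window)]

  out <- rbind(
    ds[hr_day_included == TRUE,
       .(patient_id, parameter = "hr", day_index, value = mean_hr)],
    ds[step_day_included == TRUE & !is.na(steps_total),
       .(patient_id, parameter = "steps", day_index,
         value = as.numeric(steps_total))],
    rbindlist(lapply(prom_items(), function(it) {
      col <- paste0("prom_", it)
      ds[prom_entries >= 1L & !is.na(get(col)),
         .(patient_id, parameter = it, day_index, value = get(col))]
    }))
  )
  setorder(out, parameter, day_index, patient_id)
  out[]
}

#' Five-number boxplot statistics with Tukey whiskers
#'
#' Median and quartiles by linear interpolation of order statistics
#' (`stats::quantile` type 7), whiskers at the most extreme observations
#' within 1.5 IQR of the quartiles, and everything beyond listed as
#' outliers.
#'
#' @param values numeric vector (at least one value).
#' @param coef whisker multiplier (1.5 for Tukey's rule).
#' @return list: `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))
boxplot_stats <- function(values, coef = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("need at least one value", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - coef * iqr
  hi_fence <- q[3] + coef * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Perioperative-course summary (boxplot statistics per day)
#'
#' For each parameter and aligned day index, the cohort boxplot statistics
#' of the per-patient day means, describing the course of HR, daily steps
#' and PROMs from `preop_window` days before admission to `postop_window`
#' days after surgery at home.
#'
#' @inheritParams align_days
#' @return data.table: `parameter`, `day_index`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `outliers` (comma-separated
#'   string).
#' @export
course_summary <- function(cleaned, preop_window = 14L, postop_window = 30L,
                           patients = cleaned$included) {
  al <- align_days(cleaned, preop_window, postop_window, patients)
  al[, {
    bs <- boxplot_stats(value)
    list(n = bs$n, median = bs$median, q1 = bs$q1, q3 = bs$q3,
         whisker_low = bs$whisker_low, whisker_high = bs$whisker_high,
         outliers = paste(signif(bs$outliers, 6), collapse = ","))
  }, by = .(parameter, day_index)][order(parameter, day_index)]
}

#' Plot the perioperative course as boxplots
#'
#' @param cleaned a `cleaned_cohort`.
#' @param parameter which parameter to plot.
#' @inheritParams align_days
#' @return A ggplot object (boxplots of patient day means by day index).
#' @export
plot_course <- function(cleaned, parameter = "steps", preop_window = 14L,
                        postop_window = 30L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  par <- parameter
  al <- align_days(cleaned, preop_window, postop_window)[parameter == par]
  ggplot2::ggplot(al, ggplot2::aes(x = factor(day_index), y = value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = "Day (negative: before admission; positive: after surgery)",
                  y = par) +
    ggplot2::theme_minimal()
}
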