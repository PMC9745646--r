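#' Bland-Altman agreement between paired measurements
#'
#' Quantifies agreement between a special-day measurement and the
#' individual reference value (or any two paired measurements): the mean
#' difference (consistent bias), the sample SD of the differences (n-1
#' denominator), and the 95% limits of agreement
#' `bias +/- multiplier * sd_diff` (1.96 by default). Differences are
#' oriented as `x - y` (special day minus reference); the per-pair
#' (average, difference) points are returned for plotting.
#'
#' @param x,y paired numeric vectors (e.g. special-day values and reference
#'   values); pairs with a missing member are dropped.
#' @param multiplier LoA multiplier (1.96 for normal-theory 95% limits).
#' @param labels optional identifiers per pair, carried into the point
#'   cloud.
#' @return Object of class `bland_altman_result`: `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, and `points` (a data.table with
#'   `average` and `difference`).
#' @export
#' @examples
#' ba <- bland_altman(c(70, 75, 80, 85), c(71, 73, 82, 84))
#' ba$mean_diff
bland_altman <- function(x, y, multiplier = 1.96, labels = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("insufficient data: need at least 2 complete pairs",
                   call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  pts <- data.table(average = (x + y) / 2, difference = d)
  if (!is.null(labels)) pts[, label := labels[keep]]
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         loa_low = m - multiplier * s, loa_high = m + multiplier * s,
         multiplier = multiplier, points = pts),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  bias %.3f, SD of differences %.3f\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  %.0f%% limits of agreement [%.3f, %.3f]\n",
              100 * 2 * (stats::pnorm(x$multiplier) - 0.5),
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman agreement for the two special preoperative days
#'
#' Runs [bland_altman()] for HR and daily step count on the first
#' telemonitoring day and the day before admission, against the reference
#' values.
#'
#' @param cleaned a `cleaned_cohort`.
#' @param references output of [compute_reference()].
#' @param multiplier LoA multiplier.
#' @return data.table with one row per (parameter, day): `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`.
#' @export
agreement_table <- function(cleaned, references, multiplier = 1.96) {
  rows <- list()
  for (sp in c("first_day", "day_before_admission")) {
    sd_tab <- extract_special_day(cleaned, sp)
    for (par in c("hr", "steps")) {
      col <- special_column(par)
      m <- merge(sd_tab[, .(patient_id, value = as.numeric(get(col)))],
                 references[, .(patient_id, ref = get(ref_column(par)))],
                 by = "patient_id")
      m <- m[!is.na(value) & !is.na(ref)]
      rows[[length(rows) + 1L]] <- if (nrow(m) >= 2L) {
        ba <- bland_altman(m$value, m$ref, multiplier)
        data.table(parameter = par, period = sp, n = ba$n,
                   mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                   loa_low = ba$loa_low, loa_high = ba$loa_high)
      } else {
        data.table(parameter = par, period = sp, n = nrow(m),
                   mean_diff = NA_real_, sd_diff = NA_real_,
                   loa_low = NA_real_, loa_high = NA_real_)
      }
    }
  }
  rbindlist(rows)
}

#' Plot a Bland-Altman result
#'
#' Scatter of per-pair differences against averages with dotted lines at
#' the bias and the limits of agreement. Requires ggplot2.
#'
#' @param x a `bland_altman_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.bland_altman_result <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(x$points, ggplot2::aes(x = average, y = difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(x$mean_diff, x$loa_low, x$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "Average of pair", y = "Difference (day - reference)") +
    ggplot2::theme_minimal()
}
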