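#' Daily mean soil temperatures
#'
#' Averages all logger readings per calendar date (UTC).
#'
#' @param series Data.frame with `timestamp` (POSIXct) and
#'   `temperature_c`.
#' @return A data.frame with `date`, `mean_c`, `n_readings`, ordered by
#'   date; dates with no readings are simply absent.
#' @export
daily_means <- function(series) {
  if (nrow(series) == 0) stop("empty series")
  date <- as.Date(series$timestamp, tz = "UTC")
  agg <- stats::aggregate(series$temperature_c, by = list(date = date),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(date = agg$date, mean_c = agg$x[, 1],
                    n_readings = as.integer(agg$x[, 2]))
  out[order(out$date), , drop = FALSE]
}

#' Annual windows over a daily series
#'
#' Splits the span of a daily series into consecutive 12-month windows
#' starting at its first date (for an 01 Aug start, Aug-Jul hydrological
#' years); only windows fully covered by the span are returned.
#'
#' @param daily Output of [daily_means()].
#' @return A data.frame with `start` and `end` dates, one row per
#'   complete window.
#' @export
annual_windows <- function(daily) {
  first <- min(daily$date)
  last <- max(daily$date)
  starts <- seq(first, last, by = "12 months")
  ends <- seq(first, by = "12 months", length.out = length(starts) + 1)[-1] - 1
  keep <- ends <= last
  if (!any(keep)) stop("series shorter than one annual window")
  data.frame(start = starts[keep], end = ends[keep])
}

#' Count cold days per annual window
#'
#' A cold day is a date whose daily mean temperature is at or below
#' `threshold`. The default threshold of 2 degC operationalises a
#' dormancy-release band of 1 +/- 1 degC by its upper bound.
#'
#' @param daily Output of [daily_means()].
#' @param threshold Cold-day threshold (degrees C), default 2.
#' @param windows Data.frame of `start`/`end` dates (see
#'   [annual_windows()]); default: annual windows over the series.
#' @return An object of class `"cold_days"`: list with `windows` (per
#'   window: `start`, `end`, `days_total`, `days_present`, `cold_days`),
#'   `mean` and `sd` (sample SD across windows) and `threshold`. Windows
#'   with missing dates are flagged with a warning; a window entirely
#'   outside the series is an error.
#' @export
count_cold_days <- function(daily, threshold = 2, windows = NULL) {
  if (is.null(windows)) windows <- annual_windows(daily)
  if (nrow(windows) == 0) stop("no windows supplied")
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- daily$date >= w$start & daily$date <= w$end
    total <- as.integer(w$end - w$start) + 1L
    present <- sum(sel)
    if (present == 0)
      stop("window ", format(w$start), " .. ", format(w$end),
           " lies entirely outside the series")
    if (present < total)
      warning("window ", format(w$start), " .. ", format(w$end),
              ": only ", present, " of ", total, " days present")
    data.frame(start = w$start, end = w$end, days_total = total,
               days_present = present,
               cold_days = sum(daily$mean_c[sel] <= threshold))
  })
  tab <- do.call(rbind, rows)
  structure(list(windows = tab, mean = mean(tab$cold_days),
                 sd = if (nrow(tab) > 1) stats::sd(tab$cold_days)
                      else NA_real_,
                 threshold = threshold),
            class = "cold_days")
}

#' @export
print.cold_days <- function(x, ...) {
  cat("Cold days (daily mean <= ", x$threshold, " degC) over ",
      nrow(x$windows), " window(s): mean ",
      formatC(x$mean, format = "f", digits = 2),
      if (is.finite(x$sd)) paste0(" +/- ",
                                  formatC(x$sd, format = "f", digits = 2))
      else "", "\n", sep = "")
  print(x$windows, row.names = FALSE)
  invisible(x)
}

#' IPCC RCP warming increments
#'
#' The scalar soil-warming increments used for projection: for each
#' Representative Concentration Pathway an optimistic (OP) and a less
#' optimistic (LOP) global mean surface temperature rise - RCP2.6: +0.3
#' and +1.7; RCP4.5: +1.1 and +2.6; RCP6.0: +1.4 and +3.1; RCP8.5: +2.6
#' and +4.8 degC - plus the unwarmed "Current" baseline.
#'
#' @return A data.frame with `scenario` and `delta_t` (degrees C).
#' @export
rcp_scenarios <- function() {
  data.frame(
    scenario = c("Current", "RCP2.6-OP", "RCP2.6-LOP", "RCP4.5-OP",
                 "RCP4.5-LOP", "RCP6.0-OP", "RCP6.0-LOP", "RCP8.5-OP",
                 "RCP8.5-LOP"),
    delta_t = c(0, 0.3, 1.7, 1.1, 2.6, 1.4, 3.1, 2.6, 4.8),
    stringsAsFactors = FALSE)
}

#' Classify dormancy-release feasibility from mean cold days
#'
#' At least 60 cold days allow full dormancy release; 30 to 60 days
#' release only part of the seed population; fewer than 30 days do not
#' permit completion of dormancy release.
#'
#' @param mean_days Mean number of cold days (>= 0).
#' @param partial_min,full_min Class boundaries (days).
#' @return `"full_release"`, `"partial_release"` or `"insufficient"`
#'   (vectorised).
#' @export
classify_outcome <- function(mean_days, partial_min = 30, full_min = 60) {
  stopifnot(all(mean_days >= 0), partial_min < full_min)
  ifelse(mean_days >= full_min, "full_release",
         ifelse(mean_days >= partial_min, "partial_release",
                "insufficient"))
}

#' Cold-day projection under warming scenarios
#'
#' For each scenario increment, adds `delta_t` to every logger reading,
#' recomputes daily means and per-window cold-day counts, and classifies
#' the dormancy-release outcome. (Adding the increment to readings or to
#' daily means is equivalent for an additive constant.) The `delta_t = 0`
#' scenario reproduces the current counts exactly, and counts are
#' non-increasing in `delta_t`.
#'
#' @param series Logger series (`timestamp`, `temperature_c`).
#' @param scenarios Data.frame of `scenario`/`delta_t`; default
#'   [rcp_scenarios()].
#' @param threshold Cold-day threshold (degrees C).
#' @param windows Optional window table (see [count_cold_days()]).
#' @return A data.frame with one row per scenario: `scenario`, `delta_t`,
#'   `mean_cold_days`, `sd_cold_days`, `outcome`; per-window counts are
#'   attached as attribute `windows` (a named list of `"cold_days"`
#'   objects).
#' @export
apply_scenarios <- function(series, scenarios = rcp_scenarios(),
                            threshold = 2, windows = NULL) {
  stopifnot(all(scenarios$delta_t >= 0))
  if (is.null(windows)) windows <- annual_windows(daily_means(series))
  per_scenario <- lapply(seq_len(nrow(scenarios)), function(i) {
    shifted <- series
    shifted$temperature_c <- shifted$temperature_c + scenarios$delta_t[i]
    count_cold_days(daily_means(shifted), threshold, windows)
  })
  names(per_scenario) <- scenarios$scenario
  out <- data.frame(
    scenario = scenarios$scenario, delta_t = scenarios$delta_t,
    mean_cold_days = vapply(per_scenario, `[[`, numeric(1), "mean"),
    sd_cold_days = vapply(per_scenario, `[[`, numeric(1), "sd"),
    stringsAsFactors = FALSE)
  out$outcome <- classify_outcome(out$mean_cold_days)
  rownames(out) <- NULL
  attr(out, "windows") <- per_scenario
  out
}
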