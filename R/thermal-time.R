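#' Interpolate percentile germination times from a curve
#'
#' The time `t_g` (days) to reach the g-th cumulative germination
#' percentile is interpolated linearly in time between the two bracketing
#' observations of the pooled progress curve (the origin (day 0, 0%) is
#' used as the lower bracket before the first observation). A percentile
#' that coincides exactly with an observed value takes that observation's
#' day (the earliest, if several observations sit at the value). A
#' percentile above the final germination percentage is flagged as not
#' attained.
#'
#' @param curve A [pool_curve()] object.
#' @param percentiles Percentiles g (percent), default 10, 20, ..., 90.
#' @return A data.frame with columns `g`, `t_g`, `rate` (`1/t_g`, per
#'   day), and `attained`; the condition key is carried in attributes
#'   `site`, `pretreatment_days`, `temperature_c`.
#' @export
percentile_times <- function(curve, percentiles = seq(10, 90, by = 10)) {
  if (!inherits(curve, "germination_curve"))
    stop("curve must be a germination_curve (see pool_curve)")
  if (length(curve$day) == 0) stop("empty curve")
  day <- curve$day
  pct <- 100 * curve$cum_fraction
  if (day[1] > 0) {
    day <- c(0, day)
    pct <- c(0, pct)
  }
  final_pct <- pct[length(pct)]
  tol <- 1e-9

  t_g <- vapply(percentiles, function(g) {
    if (g > final_pct + tol) return(NA_real_)
    hit <- which(abs(pct - g) <= tol)
    if (length(hit)) return(day[hit[1]])
    up <- which(pct >= g)[1]
    lo <- up - 1
    day[lo] + (g - pct[lo]) * (day[up] - day[lo]) / (pct[up] - pct[lo])
  }, numeric(1))

  out <- data.frame(g = percentiles, t_g = t_g,
                    rate = ifelse(t_g > 0, 1 / t_g, NA_real_),
                    attained = !is.na(t_g))
  attr(out, "site") <- curve$site
  attr(out, "pretreatment_days") <- curve$pretreatment_days
  attr(out, "temperature_c") <- curve$temperature_c
  out
}

#' Percentile germination rates across incubation temperatures
#'
#' Builds, for one site x pretreatment condition, the table of germination
#' rates `1/t_g` per percentile and incubation temperature that the
#' rate-temperature regressions are fitted to. Temperatures whose curve
#' never attains a percentile contribute no point for it.
#'
#' @param records Long-format germination records.
#' @param site,pretreatment_days Condition key.
#' @param temperatures Temperatures to include (default: all present).
#' @param percentiles Percentiles g (percent).
#' @param basis Denominator basis, see [pool_curve()].
#' @return A data.frame with columns `temperature_c`, `g`, `t_g`, `rate`,
#'   restricted to attained percentiles.
#' @export
percentile_rate_table <- function(records, site, pretreatment_days,
                                  temperatures = NULL,
                                  percentiles = seq(10, 90, by = 10),
                                  basis = "filled") {
  sel <- records$site == site &
    records$pretreatment_days == pretreatment_days
  if (!any(sel)) stop("no records for ", site, "/C", pretreatment_days)
  if (is.null(temperatures))
    temperatures <- sort(unique(records$temperature_c[sel]))
  rows <- lapply(temperatures, function(tc) {
    cv <- pool_curve(records, site, pretreatment_days, tc, basis = basis)
    pt <- percentile_times(cv, percentiles)
    pt <- pt[pt$attained & pt$t_g > 0, c("g", "t_g", "rate")]
    if (nrow(pt) == 0) return(NULL)
    cbind(temperature_c = tc, pt)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(temperature_c = numeric(0), g = numeric(0),
                      t_g = numeric(0), rate = numeric(0))
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares rate-temperature regression for one percentile
#'
#' Fits `1/t_g = (T - T_b) / theta` as a straight line of the germination
#' rate on temperature; the x-intercept estimates the base temperature and
#' the reciprocal slope the thermal-time constant for that percentile.
#'
#' @param rate_table Output of [percentile_rate_table()].
#' @param g Percentile (percent) to fit.
#' @param max_temp Upper temperature bound of the sub-optimal range;
#'   points above it are excluded.
#' @return An object of class `"rate_regression"`: list with `g`, `n`,
#'   `slope`, `intercept`, `x_intercept`, `r_squared`, `p_value` (two-sided
#'   t test on the slope), `sse`, `df_resid` and the fitted points; or
#'   `NULL` when fewer than 3 points are available (fit unavailable, not
#'   fatal).
#' @export
fit_rate_regression <- function(rate_table, g, max_temp = Inf) {
  d <- rate_table[rate_table$g == g & rate_table$temperature_c <= max_temp, ]
  if (nrow(d) < 3) return(NULL)
  fit <- stats::lm(rate ~ temperature_c, data = d)
  # summary.lm warns on an exactly collinear ("perfect") fit; such fits
  # are legitimate here (noise-free synthetic curves)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(
    g = g, n = nrow(d), slope = slope, intercept = intercept,
    x_intercept = -intercept / slope,
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    sse = sum(stats::residuals(fit)^2),
    df_resid = fit$df.residual,
    data = d[, c("temperature_c", "g", "t_g", "rate")]),
    class = "rate_regression")
}

#' Choose the sub-optimal temperature range by pooled residual variance
#'
#' For each candidate upper temperature, all percentiles with at least
#' three rate points at temperatures up to the candidate are fitted by
#' OLS, and the candidate minimising the pooled residual variance
#' (sum of SSE over percentiles divided by the pooled residual df) is
#' chosen; ties go to the wider range.
#'
#' @param rate_table Output of [percentile_rate_table()].
#' @param candidate_max_temps Candidate upper temperatures. Default: all
#'   temperatures present in `rate_table` from the third-lowest upward.
#' @param percentiles Percentiles considered (default: all in the table).
#' @return A list with `suboptimal_max`, `regressions` (per-percentile
#'   [fit_rate_regression()] results at the chosen range), and
#'   `candidates` (a data.frame of candidate, pooled residual variance,
#'   number of fitted percentiles).
#' @export
select_suboptimal_range <- function(rate_table, candidate_max_temps = NULL,
                                    percentiles = NULL) {
  temps <- sort(unique(rate_table$temperature_c))
  if (is.null(candidate_max_temps)) {
    if (length(temps) < 3)
      stop("fewer than 3 temperatures with attained percentiles")
    candidate_max_temps <- temps[temps >= temps[3]]
  }
  candidate_max_temps <- sort(candidate_max_temps)
  if (is.null(percentiles)) percentiles <- sort(unique(rate_table$g))

  cand_rows <- lapply(candidate_max_temps, function(cand) {
    fits <- Filter(Negate(is.null),
                   lapply(percentiles, fit_rate_regression,
                          rate_table = rate_table, max_temp = cand))
    if (length(fits) == 0) return(NULL)
    sse <- sum(vapply(fits, `[[`, numeric(1), "sse"))
    df <- sum(vapply(fits, `[[`, numeric(1), "df_resid"))
    list(cand = cand, resvar = if (df > 0) sse / df else Inf,
         n_percentiles = length(fits), fits = fits)
  })
  cand_rows <- Filter(Negate(is.null), cand_rows)
  if (length(cand_rows) == 0)
    stop("no candidate range yields a valid percentile fit")

  resvar <- vapply(cand_rows, `[[`, numeric(1), "resvar")
  best <- max(which(resvar <= min(resvar) + 1e-12))  # tie -> wider range
  chosen <- cand_rows[[best]]
  list(suboptimal_max = chosen$cand, regressions = chosen$fits,
       candidates = data.frame(
         max_temp = vapply(cand_rows, `[[`, numeric(1), "cand"),
         pooled_resvar = resvar,
         n_percentiles = vapply(cand_rows, `[[`, numeric(1),
                                "n_percentiles")))
}

#' Base temperature as the mean x-intercept across percentiles
#'
#' Averages the x-intercepts of the per-percentile rate regressions whose
#' slope is positive and significant at `alpha` (two-sided t test); the
#' spread across percentiles is reported as the sample SD.
#'
#' @param regressions List of [fit_rate_regression()] objects.
#' @param alpha Significance level for a regression to qualify (default
#'   0.05).
#' @return A list with `Tb_mean`, `Tb_sd`, `percentiles_used` and the
#'   qualifying `x_intercepts`; `Tb_mean` is `NA` (with a `reason`
#'   attribute) when no regression qualifies, as happens when germination
#'   is too sparse to support the fits.
#' @export
estimate_Tb <- function(regressions, alpha = 0.05) {
  regressions <- Filter(Negate(is.null), regressions)
  ok <- vapply(regressions, function(r)
    is.finite(r$p_value) && r$p_value < alpha && r$slope > 0, logical(1))
  if (!any(ok)) {
    out <- list(Tb_mean = NA_real_, Tb_sd = NA_real_,
                percentiles_used = numeric(0), x_intercepts = numeric(0))
    attr(out, "reason") <- "no percentile regression with P < alpha"
    return(out)
  }
  xi <- vapply(regressions[ok], `[[`, numeric(1), "x_intercept")
  gs <- vapply(regressions[ok], `[[`, numeric(1), "g")
  list(Tb_mean = mean(xi),
       Tb_sd = if (length(xi) > 1) stats::sd(xi) else NA_real_,
       percentiles_used = gs, x_intercepts = xi)
}

#' Thermal-time constants from regressions constrained through Tb
#'
#' Refits each percentile's rate-temperature line through the base
#' temperature: least squares through the origin of `1/t_g` on
#' `(T - T_b)`, with slope `b = sum(x*y) / sum(x^2)`. The thermal time is
#' the reciprocal slope, `theta_g = 1/b` (degree-days); `theta50` is the
#' value at g = 50%. Percentiles with a non-positive constrained slope
#' have `theta_g` recorded as `NA`.
#'
#' @param rate_table Output of [percentile_rate_table()].
#' @param T_b Base temperature (degrees C).
#' @param max_temp Upper bound of the sub-optimal range.
#' @param percentiles Percentiles to fit (default: all in the table).
#' @return A list with `table` (data.frame `g`, `slope`, `theta`) and
#'   `theta50` (full precision; round only for reporting).
#' @export
constrained_thermal_time <- function(rate_table, T_b, max_temp = Inf,
                                     percentiles = NULL) {
  if (!is.finite(T_b)) stop("T_b is not available")
  if (is.null(percentiles)) percentiles <- sort(unique(rate_table$g))
  rows <- lapply(percentiles, function(g) {
    d <- rate_table[rate_table$g == g & rate_table$temperature_c <= max_temp, ]
    if (nrow(d) == 0)
      return(data.frame(g = g, slope = NA_real_, theta = NA_real_))
    x <- d$temperature_c - T_b
    y <- d$rate
    b <- sum(x * y) / sum(x^2)
    data.frame(g = g, slope = b,
               theta = if (is.finite(b) && b > 0) 1 / b else NA_real_)
  })
  tab <- do.call(rbind, rows)
  theta50 <- if (50 %in% tab$g) tab$theta[tab$g == 50] else NA_real_
  list(table = tab, theta50 = theta50)
}

#' Full thermal-time analysis of a germination experiment
#'
#' Runs, for every site x pretreatment condition in `records`, the whole
#' estimation chain: pooled curves per temperature, percentile-time
#' interpolation, per-percentile rate-temperature regressions over
#' candidate sub-optimal ranges, range selection by smallest pooled
#' residual variance, base temperature as the mean x-intercept of the
#' significant percentile regressions, and thermal-time constants from
#' refits constrained through Tb. Conditions whose germination is too
#' sparse for any valid fit (typically short stratifications) are reported
#' with `NA` estimates rather than dropped.
#'
#' @param records Long-format germination records.
#' @param percentiles Percentiles g (percent), default 10, ..., 90.
#' @param alpha Significance level for percentile regressions to enter the
#'   Tb mean.
#' @param candidate_max_temps Candidate sub-optimal upper temperatures
#'   (default: chosen per condition from the attained temperatures, third
#'   lowest and upward).
#' @param basis Denominator basis, see [pool_curve()].
#' @return An object of class `"thermal_time_fit"`: list with `summary`
#'   (one row per condition: `site`, `pretreatment_days`, `Tb_mean`,
#'   `Tb_sd`, `suboptimal_max`, `theta50`, `theta50_cd` (rounded to
#'   integer degree-days for reporting), `n_percentiles_used`,
#'   `percentiles_used`) and `details` (per-condition regressions, theta
#'   tables, and exclusion log).
#' @export
thermal_time_analysis <- function(records, percentiles = seq(10, 90, 10),
                                  alpha = 0.05,
                                  candidate_max_temps = NULL,
                                  basis = "filled") {
  conds <- unique(records[, c("site", "pretreatment_days")])
  conds <- conds[order(conds$site, conds$pretreatment_days), ]
  details <- list()
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    site <- conds$site[i]
    strat <- conds$pretreatment_days[i]
    key <- paste0(site, "/C", strat)
    rt <- percentile_rate_table(records, site, strat,
                                percentiles = percentiles, basis = basis)
    log <- character(0)
    res <- list(rate_table = rt)
    n_temps <- length(unique(rt$temperature_c))
    est <- list(Tb_mean = NA_real_, Tb_sd = NA_real_,
                percentiles_used = numeric(0))
    submax <- NA_real_
    theta50 <- NA_real_
    if (n_temps >= 3) {
      sel <- tryCatch(
        select_suboptimal_range(rt, candidate_max_temps, percentiles),
        error = function(e) NULL)
      if (!is.null(sel)) {
        submax <- sel$suboptimal_max
        est <- estimate_Tb(sel$regressions, alpha)
        res$selection <- sel
        if (is.finite(est$Tb_mean)) {
          ctt <- constrained_thermal_time(rt, est$Tb_mean, submax,
                                          percentiles)
          theta50 <- ctt$theta50
          res$theta <- ctt
        } else {
          log <- c(log, "no percentile regression significant at alpha")
        }
      } else {
        log <- c(log, "no candidate sub-optimal range yields a valid fit")
      }
    } else {
      log <- c(log, paste0("only ", n_temps,
                           " temperature(s) with attained percentiles"))
    }
    res$log <- log
    details[[key]] <- res
    rows[[key]] <- data.frame(
      site = site, pretreatment_days = strat,
      Tb_mean = est$Tb_mean, Tb_sd = est$Tb_sd,
      suboptimal_max = if (is.finite(est$Tb_mean)) submax else NA_real_,
      theta50 = theta50,
      theta50_cd = if (is.finite(theta50)) round(theta50) else NA_real_,
      n_percentiles_used = length(est$percentiles_used),
      percentiles_used = paste(est$percentiles_used, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, rows), details = details)
  rownames(out$summary) <- NULL
  class(out) <- "thermal_time_fit"
  out
}

#' @export
print.thermal_time_fit <- function(x, ...) {
  cat("Thermal-time analysis (", nrow(x$summary), " conditions)\n",
      sep = "")
  s <- x$summary
  s$Tb_mean <- round(s$Tb_mean, 2)
  s$Tb_sd <- round(s$Tb_sd, 2)
  s$theta50 <- NULL
  print(s, row.names = FALSE)
  invisible(x)
}
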