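#' Quasi-binomial GLM on final germination proportions
#'
#' Fits a logit-link quasi-binomial GLM of per-dish final germination
#' (successes = germinated, trials = filled seeds) on stratification
#' pre-treatment, incubation temperature and locality with all
#' interactions, and returns the sequential (type-I) analysis of deviance
#' with F tests on the empirical dispersion (Pearson chi-squared divided
#' by the residual df).
#'
#' @param dish_summary Per-dish summary from [per_dish_summary()].
#' @param formula Model formula on the factor columns `pretreatment`,
#'   `temperature` and `locality` (created from `pretreatment_days`,
#'   `temperature_c` and `site`). Default: full factorial.
#' @return An object of class `"deviance_table"`: the anova data.frame
#'   with attributes `dispersion` and `model` (the fitted `glm`).
#' @export
fit_proportion_glm <- function(dish_summary,
                               formula = cbind(germinated, filled - germinated) ~
                                 pretreatment * temperature * locality) {
  d <- dish_summary[dish_summary$filled > 0, ]
  if (nrow(d) < nrow(dish_summary))
    message("dropping ", nrow(dish_summary) - nrow(d),
            " dish(es) with zero filled seeds")
  d$pretreatment <- factor(d$pretreatment_days)
  d$temperature <- factor(d$temperature_c)
  d$locality <- factor(d$site)
  vars <- all.vars(formula)
  for (v in c("pretreatment", "temperature", "locality"))
    if (v %in% vars && nlevels(d[[v]]) < 2)
      stop("factor '", v, "' has fewer than 2 levels")

  fit <- stats::glm(formula, family = stats::quasibinomial(link = "logit"),
                    data = d,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged)
    stop("IRLS did not converge in 100 iterations (deviance trace: ",
         paste(round(fit$deviance, 4), collapse = ", "), ")")
  mu <- stats::fitted(fit)
  if (any(mu > 1 - 1e-8) || any(mu < 1e-8))
    warning("fitted proportions at the boundary; possible separation")
  an <- stats::anova(fit, test = "F")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  tab <- as.data.frame(an)
  structure(tab, dispersion = disp, model = fit,
            class = c("deviance_table", "data.frame"))
}

#' Pairwise t tests with pooled SD and Bonferroni adjustment
#'
#' Compares per-dish final germination percentages between levels of a
#' grouping factor (by default the stratification pre-treatment, pooling
#' over temperatures and localities) with two-sample t tests using the SD
#' pooled across all levels; raw p-values are multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param dish_summary Per-dish summary from [per_dish_summary()].
#' @param factor_col Grouping column, default `"pretreatment_days"`.
#' @param value_col Response column, default `"pct"`.
#' @return A symmetric matrix of Bonferroni-adjusted p-values (diagonal
#'   `NA`), with attribute `method`.
#' @export
pairwise_bonferroni <- function(dish_summary,
                                factor_col = "pretreatment_days",
                                value_col = "pct") {
  d <- dish_summary[!is.na(dish_summary[[value_col]]), ]
  g <- factor(d[[factor_col]])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding level(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    d <- d[!(as.character(g) %in% small), ]
    g <- droplevels(factor(d[[factor_col]]))
  }
  if (nlevels(g) < 2) stop("need at least 2 levels with >= 2 observations")
  pt <- stats::pairwise.t.test(d[[value_col]], g, pool.sd = TRUE,
                               p.adjust.method = "bonferroni")
  lev <- levels(g)
  m <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  m[rownames(pt$p.value), colnames(pt$p.value)] <- pt$p.value
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  attr(m, "method") <- "pairwise t tests, pooled SD, Bonferroni"
  m
}

#' Quasi-Poisson comparison of base-temperature estimates
#'
#' Tests whether the per-percentile base-temperature estimates
#' (x-intercepts) differ between pre-treatments and localities, with a
#' log-link quasi-Poisson GLM and sequential F tests on the empirical
#' dispersion. Because a log link cannot take non-positive responses, the
#' x-intercepts are shifted by `1 + |min|` whenever non-positive values
#' occur; the shift is recorded in the output and an explicit warning is
#' raised, since the scale of the comparison is then shifted too.
#'
#' @param tb_table Data.frame with one row per percentile x condition:
#'   columns `site`, `pretreatment_days`, `x_intercept`.
#' @return A `"deviance_table"` (see [fit_proportion_glm()]) with
#'   attribute `shift`.
#' @export
compare_Tb <- function(tb_table) {
  needed <- c("site", "pretreatment_days", "x_intercept")
  if (!all(needed %in% names(tb_table)))
    stop("tb_table needs columns: ", paste(needed, collapse = ", "))
  if (length(unique(interaction(tb_table$site,
                                tb_table$pretreatment_days))) < 2)
    stop("x-intercepts from at least 2 conditions are required")
  if (stats::sd(tb_table$x_intercept) == 0)
    stop("all x-intercepts identical; model is degenerate")
  y <- tb_table$x_intercept
  shift <- 0
  if (min(y) <= 0) {
    shift <- 1 + abs(min(y))
    warning("x-intercepts span non-positive values; applying log-link ",
            "after shifting by +", round(shift, 4),
            " (comparison is on the shifted scale)")
  }
  d <- data.frame(y = y + shift,
                  pretreatment = factor(tb_table$pretreatment_days),
                  locality = factor(tb_table$site))
  rhs <- if (nlevels(d$locality) > 1) y ~ pretreatment + locality
         else y ~ pretreatment
  fit <- stats::glm(rhs, family = stats::quasipoisson(link = "log"),
                    data = d,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  an <- stats::anova(fit, test = "F")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  tab <- as.data.frame(an)
  structure(tab, dispersion = disp, model = fit, shift = shift,
            class = c("deviance_table", "data.frame"))
}

#' @export
print.deviance_table <- function(x, ...) {
  cat("Analysis of deviance (F tests, empirical dispersion = ",
      formatC(attr(x, "dispersion"), format = "f", digits = 4), ")\n",
      sep = "")
  if (!is.null(attr(x, "shift")) && attr(x, "shift") > 0)
    cat("Response shifted by +", round(attr(x, "shift"), 4),
        " for the log link\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
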