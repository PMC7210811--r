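#' Published germination summary for Gentiana lutea
#'
#' Final germination percentages (mean +/- SD of four dishes, filled-seed
#' basis) for G. lutea seeds from two Sardinian mountain localities
#' (IS, Is Terre Molentes; TM, Trainu Murcunieddu) after 0-90 days of
#' cold stratification at 1 +/- 1 degC, incubated at 5-30 degC. These
#' reported summary values ship with the package as a reference input for
#' desk-scale checks and worked examples.
#'
#' @return A data.frame with columns `site`, `pretreatment_days`,
#'   `temperature_c`, `mean_pct`, `sd_pct`.
#' @export
gentiana_germination_summary <- function() {
  utils::read.csv(system.file("extdata",
                              "gentiana_germination_summary.csv",
                              package = "thermalgerm", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published thermal-time parameters for Gentiana lutea
#'
#' Reported base temperatures (mean +/- SD across percentiles, degrees C)
#' and thermal-time constants theta50 (degree-days) for the two localities
#' after 60 and 90 days of cold stratification, the only pre-treatments
#' with enough germination to support the rate regressions.
#'
#' @return A data.frame with columns `site`, `pretreatment_days`,
#'   `tb_mean_c`, `tb_sd_c`, `theta50_cd`.
#' @export
gentiana_thermal_params <- function() {
  utils::read.csv(system.file("extdata", "gentiana_thermal_params.csv",
                              package = "thermalgerm", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Minimum stratification achieving a germination level
#'
#' From a condition-level germination summary, the shortest
#' cold-stratification duration whose best temperature reaches at least
#' `min_pct` percent germination (in any locality).
#'
#' @param summary Data.frame with `pretreatment_days` and `mean_pct`
#'   (e.g. [gentiana_germination_summary()] or [final_germination()]).
#' @param min_pct Germination level (percent) to reach, default 50.
#' @return The stratification duration in days, or `NA` if no duration
#'   reaches the level.
#' @export
min_stratification_for <- function(summary, min_pct = 50) {
  best <- tapply(summary$mean_pct, summary$pretreatment_days, max)
  ok <- names(best)[best > min_pct]
  if (length(ok) == 0) return(NA_real_)
  min(as.numeric(ok))
}
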