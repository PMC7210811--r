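#' Parameters for the germination simulator
#'
#' Bundles the ground-truth physiology used by [simulate_germination()]:
#' a thermal-time model in which each viable, non-dormant seed carries its
#' own degree-day requirement and germinates once it has accumulated it.
#'
#' Seed-to-seed variation in the thermal-time requirement is lognormal with
#' median `theta50_true` (degrees C day) and log-scale SD `sigma_theta`.
#' Between `T_b_true` and `T_opt_hi` the germination rate of a seed is
#' `(T - T_b_true) / theta_seed`; above the optimal plateau the rate is
#' frozen at its plateau value while the germinable fraction declines
#' linearly to zero at `T_ceiling`. Dormancy release after `s` days of cold
#' stratification follows a logistic curve
#' `plogis((s - strat_half) / strat_slope)`.
#'
#' @param T_b_true Base temperature (degrees C) below which no thermal time
#'   accumulates.
#' @param theta50_true Median thermal-time requirement (degrees C day).
#' @param sigma_theta SD of log thermal time across seeds (dimensionless,
#'   >= 0).
#' @param T_opt_hi Upper edge of the optimal plateau (degrees C).
#' @param T_ceiling Temperature at which the germinable fraction reaches
#'   zero (degrees C).
#' @param strat_half Stratification duration (days) releasing half the
#'   seeds from dormancy.
#' @param strat_slope Logistic scale (days) of dormancy release.
#' @param p_empty Probability that a sown seed is empty (cut test).
#' @param schedule Strictly increasing observation days (days since
#'   sowing). Default mimics scoring three times a week for 98 days.
#' @param rng_seed Integer root seed; per-dish substreams are derived from
#'   it deterministically.
#' @return An object of class `"sim_params"` (a validated list).
#' @seealso [simulate_germination()], [germination_design()]
#' @export
sim_params <- function(T_b_true = 1, theta50_true = 120, sigma_theta = 0.2,
                       T_opt_hi = 20, T_ceiling = 26,
                       strat_half = 55, strat_slope = 12,
                       p_empty = 0.05, schedule = default_schedule(),
                       rng_seed = 1L) {
  p <- list(T_b_true = T_b_true, theta50_true = theta50_true,
            sigma_theta = sigma_theta, T_opt_hi = T_opt_hi,
            T_ceiling = T_ceiling, strat_half = strat_half,
            strat_slope = strat_slope, p_empty = p_empty,
            schedule = as.numeric(schedule), rng_seed = as.integer(rng_seed))
  if (!(p$T_b_true < p$T_opt_hi))
    stop("invalid sim_params: T_b_true must be < T_opt_hi")
  if (!(p$T_opt_hi < p$T_ceiling))
    stop("invalid sim_params: T_opt_hi must be < T_ceiling")
  if (!(p$theta50_true > 0))
    stop("invalid sim_params: theta50_true must be > 0")
  if (p$sigma_theta < 0)
    stop("invalid sim_params: sigma_theta must be >= 0")
  if (p$strat_slope <= 0)
    stop("invalid sim_params: strat_slope must be > 0")
  if (p$p_empty < 0 || p$p_empty >= 1)
    stop("invalid sim_params: p_empty must lie in [0, 1)")
  if (length(p$schedule) < 1 || any(diff(p$schedule) <= 0) ||
      any(p$schedule <= 0))
    stop("invalid sim_params: schedule must be positive and strictly increasing")
  class(p) <- "sim_params"
  p
}

#' Default observation schedule
#'
#' Scoring days approximating three checks per week (Mon/Wed/Fri pattern)
#' over a 98-day germination test.
#'
#' @return Numeric vector of strictly increasing observation days.
#' @export
default_schedule <- function() {
  sort(unique(as.vector(outer(c(2, 4, 7), seq(0, 91, by = 7), "+"))))
}

#' Factorial design of a stratification x temperature germination trial
#'
#' One row per Petri dish. The default reproduces a two-locality trial:
#' 2 sites x 5 cold-stratification durations x 6 incubation temperatures x
#' 4 dishes of 25 seeds (240 dishes, 6,000 seeds).
#'
#' @param sites Character vector of site codes.
#' @param pretreatments Cold-stratification durations (days).
#' @param temperatures Incubation temperatures (degrees C).
#' @param dishes Number of replicate dishes per condition.
#' @param seeds_per_dish Seeds sown per dish.
#' @return A data.frame with columns `site`, `pretreatment_days`,
#'   `temperature_c`, `dish`, `seeds`.
#' @export
germination_design <- function(sites = c("IS", "TM"),
                               pretreatments = c(0, 15, 30, 60, 90),
                               temperatures = c(5, 10, 15, 20, 25, 30),
                               dishes = 4, seeds_per_dish = 25) {
  stopifnot(length(sites) >= 1, length(pretreatments) >= 1,
            length(temperatures) >= 1, dishes >= 1, seeds_per_dish >= 1)
  d <- expand.grid(dish = seq_len(dishes), temperature_c = temperatures,
                   pretreatment_days = pretreatments, site = sites,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("site", "pretreatment_days", "temperature_c", "dish")]
  d$seeds <- as.integer(seeds_per_dish)
  d
}

# Germinable fraction at incubation temperature T: 1 on (T_b, T_opt_hi],
# linear decline to 0 at T_ceiling, 0 outside (T_b, T_ceiling).
germinable_fraction <- function(temp, params) {
  ifelse(temp <= params$T_b_true | temp >= params$T_ceiling, 0,
         ifelse(temp <= params$T_opt_hi, 1,
                (params$T_ceiling - temp) /
                  (params$T_ceiling - params$T_opt_hi)))
}

# Deterministic per-dish substream seed, kept below 2^31.
dish_substream_seed <- function(rng_seed, index) {
  as.integer((as.double(rng_seed) + 999983 * index) %% 2147483647)
}

#' Simulate a cold-stratification x temperature germination experiment
#'
#' Draws per-seed fates under the thermal-time model in `params`: a seed is
#' empty with probability `p_empty`; a filled seed is non-dormant with
#' probability `plogis((s - strat_half) / strat_slope)` for stratification
#' duration `s`; a non-dormant, germinable seed at temperature `T`
#' germinates at `t* = theta_seed / (min(T, T_opt_hi) - T_b_true)` and is
#' scored at the first observation day `>= t*`. Seeds whose event falls
#' after the last observation are recorded as viable ungerminated.
#'
#' @param design Data.frame as returned by [germination_design()].
#' @param params A [sim_params()] object.
#' @param keep_events If `TRUE`, attach a `"events"` attribute holding the
#'   per-seed event times (for auditing the binned counts).
#' @return A long-format data.frame of germination records, one row per
#'   dish x observation day, with columns `site`, `pretreatment_days`,
#'   `temperature_c`, `dish`, `day`, `cum_germinated`, `sown`, `empty`,
#'   `viable_ungerminated`. Identical `design`, `params` and `rng_seed`
#'   reproduce identical output.
#' @export
simulate_germination <- function(design, params, keep_events = FALSE) {
  if (!inherits(params, "sim_params"))
    params <- do.call(sim_params, params)
  if (!is.data.frame(design) || nrow(design) == 0)
    stop("design must be a non-empty data.frame")
  needed <- c("site", "pretreatment_days", "temperature_c", "dish", "seeds")
  if (!all(needed %in% names(design)))
    stop("design is missing columns: ",
         paste(setdiff(needed, names(design)), collapse = ", "))

  sched <- params$schedule
  out <- vector("list", nrow(design))
  events <- if (keep_events) vector("list", nrow(design)) else NULL

  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    n <- as.integer(row$seeds)
    seed_i <- dish_substream_seed(params$rng_seed, i)
    set.seed(seed_i)

    is_empty <- stats::runif(n) < params$p_empty
    p_release <- stats::plogis((row$pretreatment_days - params$strat_half) /
                                 params$strat_slope)
    released <- stats::runif(n) < p_release
    frac <- germinable_fraction(row$temperature_c, params)
    germinable <- stats::runif(n) < frac
    theta <- stats::rlnorm(n, meanlog = log(params$theta50_true),
                           sdlog = params$sigma_theta)

    t_eff <- min(row$temperature_c, params$T_opt_hi) - params$T_b_true
    will_germ <- !is_empty & released & germinable & t_eff > 0 &
      row$temperature_c < params$T_ceiling
    t_star <- ifelse(will_germ, theta / t_eff, Inf)

    obs_idx <- findInterval(t_star, sched, left.open = TRUE) + 1
    germinated_in_test <- will_germ & obs_idx <= length(sched)
    counts <- tabulate(obs_idx[germinated_in_test], nbins = length(sched))
    cum <- cumsum(counts)

    n_empty <- sum(is_empty)
    n_germ <- sum(germinated_in_test)
    out[[i]] <- data.frame(
      site = row$site, pretreatment_days = row$pretreatment_days,
      temperature_c = row$temperature_c, dish = row$dish,
      day = sched, cum_germinated = cum,
      sown = n, empty = n_empty,
      viable_ungerminated = n - n_empty - n_germ,
      stringsAsFactors = FALSE)
    if (keep_events) {
      events[[i]] <- data.frame(
        site = row$site, pretreatment_days = row$pretreatment_days,
        temperature_c = row$temperature_c, dish = row$dish,
        seed = seq_len(n),
        fate = ifelse(is_empty, "empty",
                      ifelse(germinated_in_test, "germinated",
                             "viable_ungerminated")),
        t_event = ifelse(germinated_in_test, t_star, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keep_events)
    attr(res, "events") <- do.call(rbind, events)
  res
}
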