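make_curve <- function(day, pct, n = 100) {
  d <- make_dish(day = day, cum = round(pct / 100 * n), sown = n,
                 empty = 0)
  pool_curve(d)
}

test_that("percentile times interpolate linearly between bracketing observations", {
  cv <- make_curve(day = c(5, 10), pct = c(40, 60))
  pt <- percentile_times(cv, c(10, 40, 50, 70))
  expect_equal(pt$t_g[pt$g == 50], 7.5)
  # exact hit -> that observation's day
  expect_equal(pt$t_g[pt$g == 40], 5)
  # below the first observation -> interpolation from the origin
  expect_equal(pt$t_g[pt$g == 10], 5 * 10 / 40)
  expect_false(pt$attained[pt$g == 70])
  expect_true(is.na(pt$t_g[pt$g == 70]))
})

test_that("an exact percentile hit takes the earliest tied observation", {
  cv <- make_curve(day = c(5, 7, 10), pct = c(40, 40, 60))
  pt <- percentile_times(cv, c(40, 50))
  expect_equal(pt$t_g[pt$g == 40], 5)
  # 50% brackets between the last 40% observation and the 60% one
  expect_equal(pt$t_g[pt$g == 50], 7 + (50 - 40) / (60 - 40) * 3)
})

test_that("a dense simulated curve recovers the closed-form percentile time", {
  # theta50 120, Tb 0, T = 15 -> t50 = 8 days, within one scoring interval
  des <- germination_design(sites = "S", pretreatments = 90,
                            temperatures = 15, dishes = 4,
                            seeds_per_dish = 250)
  p <- sim_params(T_b_true = 0, theta50_true = 120, sigma_theta = 0.15,
                  strat_half = 10, strat_slope = 2, p_empty = 0,
                  schedule = 1:60, rng_seed = 31L)
  rec <- simulate_germination(des, p)
  pt <- percentile_times(pool_curve(rec))
  expect_lt(abs(pt$t_g[pt$g == 50] - 8), 1)
})

test_that("a perfectly linear rate set is fitted exactly", {
  rt <- data.frame(temperature_c = c(5, 10, 15), g = 50,
                   t_g = 1 / c(0.1, 0.2, 0.3), rate = c(0.1, 0.2, 0.3))
  fit <- fit_rate_regression(rt, 50)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(fit$x_intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 3)
})

test_that("fewer than three rate points yields no fit rather than an error", {
  rt <- data.frame(temperature_c = c(5, 10), g = 50, t_g = c(10, 5),
                   rate = c(0.1, 0.2))
  expect_null(fit_rate_regression(rt, 50))
})

test_that("OLS matches the closed-form normal equations, including duplicate temperatures", {
  set.seed(41)
  for (i in 1:5) {
    temps <- sample(c(5, 5, 10, 15, 15, 20), 5)
    rate <- 0.01 * (temps - 2) + rnorm(5, 0, 0.01)
    rt <- data.frame(temperature_c = temps, g = 50, t_g = 1 / rate,
                     rate = rate)
    fit <- fit_rate_regression(rt, 50)
    oracle <- ols_normal_equations(temps, rate)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-6)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-6)
  }
})

test_that("brute-force SSE grid minimisation agrees with the fitted line", {
  temps <- c(5, 10, 15, 20)
  rate <- c(0.031, 0.058, 0.092, 0.118)
  rt <- data.frame(temperature_c = temps, g = 50, t_g = 1 / rate,
                   rate = rate)
  fit <- fit_rate_regression(rt, 50)
  grid <- ols_grid_sse(temps, rate, c(fit$intercept, fit$slope),
                       half_width = 0.005, steps = 4001)
  sse_fit <- sum((rate - fit$intercept - fit$slope * temps)^2)
  sse_grid <- sum((rate - grid["intercept"] - grid["slope"] * temps)^2)
  expect_lte(sse_fit, sse_grid + 1e-12)
})

test_that("range selection drops a supra-optimal temperature that breaks linearity", {
  # linear up to 20 degC, rate collapse at 25 degC
  mk <- function(temps, rates, g) data.frame(temperature_c = temps, g = g,
                                             t_g = 1 / rates, rate = rates)
  rt <- do.call(rbind, lapply(c(30, 50, 70), function(g) {
    base <- 0.008 * (c(5, 10, 15, 20) - 1) * (110 - g) / 60
    mk(c(5, 10, 15, 20, 25), c(base, 0.2 * base[4]), g)
  }))
  sel <- select_suboptimal_range(rt, candidate_max_temps = c(20, 25))
  expect_equal(sel$suboptimal_max, 20)
  expect_lt(sel$candidates$pooled_resvar[sel$candidates$max_temp == 20],
            sel$candidates$pooled_resvar[sel$candidates$max_temp == 25])

  # a single valid candidate is chosen trivially
  sel1 <- select_suboptimal_range(rt, candidate_max_temps = 20)
  expect_equal(sel1$suboptimal_max, 20)
})

test_that("the base temperature is the mean x-intercept of significant percentiles", {
  mk_reg <- function(g, xi, p) structure(
    list(g = g, n = 4, slope = 0.01, intercept = -0.01 * xi,
         x_intercept = xi, r_squared = 0.9, p_value = p, sse = 0,
         df_resid = 2), class = "rate_regression")
  est <- estimate_Tb(list(mk_reg(30, 2, 0.01), mk_reg(50, 4, 0.02),
                          mk_reg(70, 10, 0.2)))
  expect_equal(est$Tb_mean, 3)
  expect_equal(est$Tb_sd, sqrt(2), tolerance = 1e-12)
  expect_equal(est$percentiles_used, c(30, 50))

  none <- estimate_Tb(list(mk_reg(30, 2, 0.5)))
  expect_true(is.na(none$Tb_mean))
  expect_match(attr(none, "reason"), "alpha")
})

test_that("thermal time is the reciprocal origin-constrained slope", {
  # single point: T 15, Tb 0, t50 8 d -> theta = 120
  rt1 <- data.frame(temperature_c = 15, g = 50, t_g = 8, rate = 1 / 8)
  ct1 <- constrained_thermal_time(rt1, T_b = 0)
  expect_equal(ct1$theta50, 120, tolerance = 1e-12)

  # two points, hand arithmetic: b = (10/12 + 15/8)/325 -> theta = 120
  rt2 <- data.frame(temperature_c = c(10, 15), g = 50, t_g = c(12, 8),
                    rate = c(1 / 12, 1 / 8))
  ct2 <- constrained_thermal_time(rt2, T_b = 0)
  b_hand <- (10 / 12 + 15 / 8) / 325
  expect_equal(ct2$table$slope[1], b_hand, tolerance = 1e-12)
  expect_equal(ct2$theta50, 1 / b_hand, tolerance = 1e-12)
  expect_equal(ct2$theta50, 120, tolerance = 1e-3)

  # numerical SSE minimisation agrees with the closed form
  b_num <- origin_slope_numeric(rt2$temperature_c - 0, rt2$rate)
  expect_equal(ct2$table$slope[1], b_num, tolerance = 1e-6)
})

test_that("exactly linear input rates are reproduced by the fitted model", {
  Tb <- 2
  theta <- c(`30` = 100, `50` = 120, `70` = 150)
  rt <- do.call(rbind, lapply(names(theta), function(g)
    data.frame(temperature_c = c(5, 10, 15, 20), g = as.numeric(g),
               t_g = theta[[g]] / (c(5, 10, 15, 20) - Tb),
               rate = (c(5, 10, 15, 20) - Tb) / theta[[g]])))
  sel <- select_suboptimal_range(rt, candidate_max_temps = c(15, 20))
  expect_equal(sel$suboptimal_max, 20)  # tie in resvar (~0) -> wider range
  est <- estimate_Tb(sel$regressions)
  expect_equal(est$Tb_mean, Tb, tolerance = 1e-8)
  ct <- constrained_thermal_time(rt, est$Tb_mean, sel$suboptimal_max)
  expect_equal(ct$table$theta, unname(theta), tolerance = 1e-8)
  # predicted times reproduce the input exactly
  pred_t50 <- ct$theta50 / (c(5, 10, 15, 20) - est$Tb_mean)
  expect_equal(pred_t50, rt$t_g[rt$g == 50], tolerance = 1e-8)
})

test_that("full-pipeline estimates recover the simulator ground truth", {
  rec <- simulate_germination(recovery_design(seeds = 150),
                              recovery_params(rng_seed = 44L))
  tt <- thermal_time_analysis(rec)
  s <- tt$summary
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$Tb_mean - 1), 0.75)
  expect_lt(abs(s$theta50 - 120) / 120, 0.12)
})

test_that("shortening stratification never adds qualifying percentiles", {
  des <- germination_design(sites = "S", pretreatments = c(15, 30, 60, 90),
                            temperatures = c(5, 10, 15, 20), dishes = 4,
                            seeds_per_dish = 50)
  p <- sim_params(rng_seed = 46L, schedule = 1:98)
  tt <- thermal_time_analysis(simulate_germination(des, p))
  s <- tt$summary[order(tt$summary$pretreatment_days), ]
  expect_true(all(diff(s$n_percentiles_used) >= 0))
})
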