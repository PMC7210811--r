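mk_summary <- function(germ, filled, pre, temp = 15, site = "S") {
  data.frame(site = site, pretreatment_days = pre, temperature_c = temp,
             dish = seq_along(germ), sown = filled, empty = 0,
             filled = filled, germinated = germ,
             viable_ungerminated = filled - germ,
             pct = 100 * germ / filled, stringsAsFactors = FALSE)
}

test_that("a factor with identical group proportions explains no deviance", {
  d <- rbind(mk_summary(c(10, 12, 11), 25, pre = 0),
             mk_summary(c(10, 12, 11), 25, pre = 90))
  tab <- fit_proportion_glm(d, cbind(germinated, filled - germinated) ~
                              pretreatment)
  expect_lt(tab["pretreatment", "Deviance"], 1e-8)
  expect_lt(tab["pretreatment", "F"], 1e-6)
})

test_that("a one-factor quasi-binomial fit reproduces the observed group proportions", {
  d <- rbind(mk_summary(c(5, 8, 6), 25, pre = 0),
             mk_summary(c(20, 22, 21), 25, pre = 90))
  tab <- fit_proportion_glm(d, cbind(germinated, filled - germinated) ~
                              pretreatment)
  fit <- attr(tab, "model")
  mu <- tapply(fitted(fit), d$pretreatment_days, unique)
  obs <- tapply(d$germinated, d$pretreatment_days, sum) /
    tapply(d$filled, d$pretreatment_days, sum)
  expect_equal(unname(unlist(mu)), unname(obs), tolerance = 1e-7)
})

test_that("sequential term deviances add up to the null deviance", {
  des <- germination_design(pretreatments = c(0, 90),
                            temperatures = c(10, 25), dishes = 3)
  rec <- simulate_germination(des, sim_params(rng_seed = 51L))
  # the C0 cells sit at 0% germination, so the boundary flag is expected
  tab <- suppressWarnings(fit_proportion_glm(per_dish_summary(rec)))
  fit <- attr(tab, "model")
  expect_equal(sum(tab$Deviance, na.rm = TRUE) + fit$deviance,
               fit$null.deviance, tolerance = 1e-8)
  # residual df strictly decreasing down the table
  expect_true(all(diff(tab$`Resid. Df`) < 0))
})

test_that("the IRLS solution maximises the binomial likelihood on a 2x2 design", {
  d <- rbind(mk_summary(c(3, 5), 20, pre = 0, site = "A"),
             mk_summary(c(9, 11), 20, pre = 0, site = "B"),
             mk_summary(c(12, 10), 20, pre = 90, site = "A"),
             mk_summary(c(17, 18), 20, pre = 90, site = "B"))
  tab <- fit_proportion_glm(d, cbind(germinated, filled - germinated) ~
                              pretreatment + locality)
  fit <- attr(tab, "model")
  loglik <- function(beta) {
    eta <- beta[1] + beta[2] * (d$pretreatment_days == 90) +
      beta[3] * (d$site == "B")
    mu <- plogis(eta)
    sum(d$germinated * log(mu) + (d$filled - d$germinated) * log(1 - mu))
  }
  direct <- optim(c(0, 0, 0), function(b) -loglik(b), method = "BFGS",
                  control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit)), direct$par, tolerance = 1e-4)
})

test_that("a strong dormancy-release effect is detected in nearly all simulations", {
  n_sig <- 0
  for (k in 1:200) {
    set.seed(6000 + k)
    g0 <- rbinom(4, 25, 0.02)
    g1 <- rbinom(4, 25, 0.90)
    d <- rbind(mk_summary(g0, 25, pre = 0), mk_summary(g1, 25, pre = 90))
    tab <- suppressWarnings(
      fit_proportion_glm(d, cbind(germinated, filled - germinated) ~
                           pretreatment))
    if (tab["pretreatment", "Pr(>F)"] < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / 200, 0.95)
})

test_that("Bonferroni-adjusted p-values dominate raw ones and cap at 1", {
  set.seed(61)
  d <- do.call(rbind, lapply(c(0, 15, 30, 60, 90), function(pre)
    mk_summary(rbinom(4, 25, plogis((pre - 55) / 12)), 25, pre = pre)))
  adj <- pairwise_bonferroni(d)
  expect_true(isSymmetric(unclass(adj)))
  expect_true(all(adj[!is.na(adj)] <= 1 & adj[!is.na(adj)] >= 0))
  raw <- stats::pairwise.t.test(d$pct, factor(d$pretreatment_days),
                                pool.sd = TRUE, p.adjust.method = "none")
  common <- !is.na(raw$p.value)
  expect_true(all(adj[rownames(raw$p.value),
                      colnames(raw$p.value)][common] >=
                    raw$p.value[common] - 1e-12))
})

test_that("identical groups are non-significant and a distinct group is flagged", {
  base <- c(10.0, 10.2, 9.8, 10.1)
  d <- rbind(mk_summary(1:4 * 0 + 10, 100, pre = 0),
             mk_summary(1:4 * 0 + 10, 100, pre = 15),
             mk_summary(1:4 * 0 + 20, 100, pre = 30))
  d$pct <- c(base, base, base + 10)  # means {10, 10, 20}, tiny SD
  adj <- pairwise_bonferroni(d)
  expect_equal(adj["0", "15"], 1)
  expect_lt(adj["0", "30"], 0.05)
  expect_lt(adj["15", "30"], 0.05)
  # hand check of the pooled-SD t statistic for the significant pair
  sp <- sqrt(mean(c(var(base), var(base), var(base + 10))))
  t_stat <- (mean(base + 10) - mean(base)) / (sp * sqrt(2 / 4))
  p_raw <- 2 * pt(-abs(t_stat), df = 9)
  expect_equal(adj["0", "30"], min(1, 3 * p_raw), tolerance = 1e-9)
})

test_that("base-temperature comparison shifts for the log link and detects effects", {
  tb <- data.frame(site = rep(c("A", "B"), each = 6),
                   pretreatment_days = rep(c(60, 90, 60, 90), each = 3),
                   x_intercept = c(3.1, 2.9, 3.3, -2.1, -1.8, -2.2,
                                   2.8, 3.2, 3.0, -1.9, -2.3, -2.0))
  expect_warning(tab <- compare_Tb(tb), "shift")
  expect_gt(attr(tab, "shift"), 1)
  expect_lt(tab["pretreatment", "Pr(>F)"], 0.05)

  # identical per-condition values across conditions -> F ~ 0
  tb2 <- data.frame(site = "A", pretreatment_days = rep(c(60, 90), each = 3),
                    x_intercept = rep(c(2, 3, 4), 2))
  tab2 <- compare_Tb(tb2)
  expect_lt(tab2["pretreatment", "F"], 1e-8)

  # fully degenerate input
  tb3 <- data.frame(site = "A", pretreatment_days = rep(c(60, 90), each = 2),
                    x_intercept = rep(2, 4))
  expect_error(compare_Tb(tb3), "degenerate")
})

test_that("a strong base-temperature difference is detected in nearly all simulations", {
  n_sig <- 0
  for (k in 1:200) {
    set.seed(7000 + k)
    tb <- data.frame(site = "A",
                     pretreatment_days = rep(c(60, 90), each = 5),
                     x_intercept = c(rnorm(5, 3, 1), rnorm(5, -2, 1)))
    tab <- suppressWarnings(compare_Tb(tb))
    if (tab["pretreatment", "Pr(>F)"] < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / 200, 0.95)
})
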