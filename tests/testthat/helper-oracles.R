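# Independent fitting oracles used across tests: closed-form normal
# equations and numerical SSE minimisation, kept separate from the
# package's lm()-based fitting path.

ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

ols_grid_sse <- function(x, y, center, half_width = 1, steps = 2001) {
  # brute-force SSE minimisation on a 2-d grid around `center`
  a <- seq(center[1] - half_width, center[1] + half_width,
           length.out = steps)
  b <- seq(center[2] - half_width, center[2] + half_width,
           length.out = steps)
  sse_a <- function(ai) min(vapply(b, function(bi)
    sum((y - ai - bi * x)^2), numeric(1)))
  best_a <- a[which.min(vapply(a, sse_a, numeric(1)))]
  best_b <- b[which.min(vapply(b, function(bi)
    sum((y - best_a - bi * x)^2), numeric(1)))]
  c(intercept = best_a, slope = best_b)
}

origin_slope_numeric <- function(x, y) {
  # 1-d SSE minimisation for a line through the origin
  stats::optimize(function(b) sum((y - b * x)^2),
                  interval = c(-10, 10), tol = 1e-12)$minimum
}

# Brute-force per-seed rebinning: given event times and a schedule,
# cumulative counts at each observation day.
rebin_events <- function(t_event, schedule) {
  t_event <- t_event[is.finite(t_event)]
  vapply(schedule, function(d) sum(t_event <= d), numeric(1))
}
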