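p_ref <- gompertz_params(a0 = 20, af = 5, mumax = -6, lag = 10)

test_that("Gompertz curve has the right plateaus and monotonicity", {
  ## pre-lag plateau within 1% of a0
  expect_lt(abs(gompertz_a(0, p_ref) - 20) / 20, 0.01)
  ## long-time asymptote within 0.1% of af
  expect_lt(abs(gompertz_a(1000, p_ref) - 5) / 5, 0.001)
  ## monotone non-increasing for decay parameters
  a <- gompertz_a(seq(0, 30, by = 0.05), p_ref)
  expect_true(all(diff(a) <= 0))
  ## degenerate a0 = af returns the constant
  pc <- gompertz_params(10, 10, -1, 2)
  expect_equal(gompertz_a(c(0, 5, 50), pc), rep(10, 3))
  ## parameter validation
  expect_error(gompertz_params(20, 5, -6, -1), "lag-nonnegative")
  expect_error(gompertz_params(20, 5, 2, 1), "mumax-sign")
  expect_error(gompertz_params(5, 20, -6, 1), "af-le-a0")
})

test_that("inflection tangent slope equals mumax in the Zwietering scaling", {
  ## with denom_scale = 1 the steepest tangent is exactly mumax; verified by
  ## numerically differentiating the curve
  tt <- seq(0, 30, by = 1e-3)
  a <- gompertz_a(tt, p_ref, denom_scale = 1)
  slope <- min(diff(a) / diff(tt))
  expect_equal(slope, p_ref$mumax, tolerance = 1e-6)
  ## with the default log-10 scale the realized slope is mumax/ln(10)
  a10 <- gompertz_a(tt, p_ref)
  expect_equal(min(diff(a10) / diff(tt)), p_ref$mumax / log(10),
               tolerance = 1e-5)
})

test_that("factor regressions evaluate their published term sets", {
  cond <- storage_conditions(6, 20, aging_d = 7, angle_deg = 45)
  ## all coefficients zero: 10^0 = 1 day, mumax = -10^0 = -1
  reg0 <- factor_regression(rep(0, 6), rep(0, 6))
  expect_equal(lag_from_factors(reg0, cond), 1)
  expect_equal(mumax_from_factors(reg0, cond), -1)
  ## intercept only
  expect_equal(lag_from_factors(factor_regression(c(1, rep(0, 5)),
                                                  rep(0, 6)), cond), 10)
  expect_equal(mumax_from_factors(factor_regression(rep(0, 6),
                                                    c(-1, rep(0, 5))), cond),
               -0.1)
  ## random coefficients against an independent one-line evaluation
  set.seed(3)
  for (rep in 1:10) {
    b <- rnorm(6, 0, 0.01); cc <- rnorm(6, 0, 0.01)
    reg <- factor_regression(b, cc)
    cond <- storage_conditions(sample(c(2, 6, 10), 1),
                               sample(c(0, 20, 100), 1),
                               sample(c(0, 7, 14), 1),
                               sample(c(0, 45, 90), 1))
    p <- cond$pO2_pct; T_C <- cond$T_C; M <- cond$aging_d; A <- cond$angle_deg
    expect_equal(lag_from_factors(reg, cond),
                 10^(b[1] + b[2] * p^2 + b[3] * p * A + b[4] * T_C * p +
                       b[5] * A^2 + b[6] * p))
    expect_equal(mumax_from_factors(reg, cond),
                 -10^(cc[1] + cc[2] * p + cc[3] * p^2 + cc[4] * M^2 +
                        cc[5] * p * M + cc[6] * M * A))
  }
})

test_that("Gompertz fit recovers noise-free and noisy curves", {
  tt <- seq(0, 15, by = 1 / 96)           # 15-min sampling over 15 d
  a <- gompertz_a(tt, p_ref)
  fit <- fit_gompertz(tt, a)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  for (nm in c("a0", "af", "mumax", "lag"))
    expect_lt(abs(fit$params[[nm]] - p_ref[[nm]]) / abs(p_ref[[nm]]), 1e-3)
  expect_lt(fit$rss, 1e-10)

  ## one noisy replicate (the multi-seed study lives in the acceptance suite)
  set.seed(99)
  fitn <- fit_gompertz(tt, a + rnorm(length(a), 0, 0.02 * p_ref$a0))
  expect_lt(abs(fitn$params$lag - 10) / 10, 0.05)
  expect_lt(abs(fitn$params$mumax - (-6)) / 6, 0.05)

  ## round trip over a grid of realistic parameter values
  for (p in list(gompertz_params(20, 5, -3, 4),
                 gompertz_params(18, 6, -8, 12),
                 gompertz_params(1, 0.25, -0.3, 8))) {
    f <- fit_gompertz(tt, gompertz_a(tt, p))
    expect_equal(unlist(f$params), unlist(p), tolerance = 1e-3)
  }

  ## methods on the fitted object
  expect_named(coef(fit), c("a0", "af", "mumax", "lag"))
  expect_equal(predict(fit, newdata = c(0, 15)),
               gompertz_a(c(0, 15), fit$params), tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-4)
})

test_that("constant series yields a flagged degenerate fit", {
  expect_warning(fit <- fit_gompertz(seq(0, 15, by = 0.5),
                                     rep(1, 31)), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(fit$params$a0, fit$params$af)
  expect_error(fit_gompertz(1:5, rep(1, 5)), "min-points")
})

test_that("factor regression is recovered exactly from noise-free lags", {
  truth <- default_truth()
  design <- make_design("definitive-screening")
  conds <- lapply(seq_len(nrow(design)), function(i)
    storage_conditions(design$T_C[i], design$pO2_pct[i],
                       design$aging_d[i], design$angle_deg[i]))
  table <- data.frame(design,
                      lag_d = sapply(conds, lag_from_factors,
                                     reg = truth$reg),
                      mumax = sapply(conds, mumax_from_factors,
                                     reg = truth$reg))
  est <- fit_factor_regression(table)
  expect_equal(est$b, truth$reg$b, tolerance = 1e-8)
  expect_equal(est$c, truth$reg$c, tolerance = 1e-8)

  ## noisy recovery keeps the sign pattern of the large coefficients
  set.seed(12)
  tn <- table
  tn$lag_d <- tn$lag_d * exp(rnorm(13, 0, 0.05))
  tn$mumax <- tn$mumax * exp(rnorm(13, 0, 0.05))
  estn <- fit_factor_regression(tn)
  big <- abs(truth$reg$b) > 1e-3
  expect_equal(sign(estn$b[big]), sign(truth$reg$b[big]))

  ## single condition: rank-deficiency error naming confounded terms
  one <- table[rep(1, 7), ]
  expect_error(fit_factor_regression(one), "min-conditions")
  few <- table[1:6, ]
  few$pO2_pct <- 20                       # collapses every pO2 term
  expect_error(fit_factor_regression(few), "rank-deficient|min-conditions")
})

test_that("phenomenological prediction composes the pieces", {
  truth <- default_truth()
  cond2 <- storage_conditions(2, 20)
  cond6 <- storage_conditions(6, 20)
  times <- seq(0, 15, by = 0.25)
  ck2 <- predict_phenom(truth$reg, cond2, truth$a0, truth$af, times)
  expect_s3_class(ck2, "color_kinetics")
  expect_equal(ck2$source, "gompertz-model")
  ## matches the hand-composed evaluation
  p <- gompertz_params(truth$a0, truth$af,
                       mumax_from_factors(truth$reg, cond2),
                       lag_from_factors(truth$reg, cond2))
  expect_equal(ck2$values, pmin(gompertz_a(times, p) / truth$a0, 1))
  ## bounded below by af/a0 and above by 1; tends to af/a0
  expect_true(all(ck2$values <= 1 & ck2$values > truth$af / truth$a0 - 1e-9))
  far <- predict_phenom(truth$reg, cond2, truth$a0, truth$af, c(0, 1000))
  expect_equal(far$values[2], truth$af / truth$a0, tolerance = 1e-6)

  ## af = a0 gives the constant-1 series
  flat <- predict_phenom(truth$reg, cond2, 20, 20, times)
  expect_true(all(flat$values == 1))

  ## longer lag at 2 degC: the 0.6 crossing happens later than at 6 degC
  ck6 <- predict_phenom(truth$reg, cond6, truth$a0, truth$af, times)
  expect_gt(crossing_time_h(ck2, 0.6), crossing_time_h(ck6, 0.6))
})
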