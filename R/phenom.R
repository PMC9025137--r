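#' Gompertz parameters for the redness time course
#'
#' The phenomenological model describes a*(t) with a modified
#' (Zwietering-style) Gompertz curve: an initial plateau of duration `lag`,
#' a decay whose steepest tangent has slope proportional to `mumax`, and a
#' final plateau at `af`.
#'
#' @param a0 initial a* value.
#' @param af final a* value (`af <= a0` for browning).
#' @param mumax maximum rate of change of a*, a*-units per day (<= 0 for
#'   decay). Note the realized tangent slope also depends on `denom_scale`
#'   in [gompertz_a()]; fitted values are only comparable under one fixed
#'   choice of that constant.
#' @param lag lag time before the decay, days (>= 0).
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(a0, af, mumax, lag) {
  if (!is_number(lag) || lag < 0)
    stop_validation("lag-nonnegative", "lag must be >= 0")
  if (!is_number(mumax) || mumax > 0)
    stop_validation("mumax-sign", "mumax must be <= 0 for browning")
  if (af > a0)
    stop_validation("af-le-a0", "af must be <= a0 for browning")
  structure(list(a0 = a0, af = af, mumax = mumax, lag = lag),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz: a0 = %.4g, af = %.4g, mumax = %.4g /d, lag = %.4g d\n",
              x$a0, x$af, x$mumax, x$lag))
  invisible(x)
}

#' Modified Gompertz redness curve
#'
#' Evaluates
#' `a*(t) = a0 + (af - a0) * exp(-exp(mumax * e * (lag - t) / ((af - a0) * denom_scale) + 1))`.
#' With `denom_scale = 1` this is the classical Zwietering modified Gompertz,
#' whose steepest tangent has slope exactly `mumax` and crosses the initial
#' plateau at `t = lag`. The default `denom_scale = log(10)` keeps an extra
#' log-10 factor in the denominator (the convention the surrounding
#' regressions were built with); under it the realized steepest slope is
#' `mumax / log(10)`.
#'
#' @param t times, days (>= 0).
#' @param params a [gompertz_params()].
#' @param denom_scale multiplicative constant on the `(af - a0)` denominator.
#' @return a*(t); the constant `a0` when `af == a0`.
#' @export
gompertz_a <- function(t, params, denom_scale = log(10)) {
  stopifnot(inherits(params, "gompertz_params"))
  a0 <- params$a0; af <- params$af
  if (af == a0) return(rep(a0, length(t)))
  u <- params$mumax * exp(1) * (params$lag - t) /
    ((af - a0) * denom_scale) + 1
  a0 + (af - a0) * exp(-exp(u))
}

#' Factor regressions for lag and maximum rate
#'
#' The two Gompertz shape parameters are regressed (on a log-10 scale) on
#' the four storage factors using fixed term sets identified on the
#' storage-experiment design: `log10(lag) = b0 + b1 pO2^2 + b2 pO2*Angle +
#' b3 T*pO2 + b4 Angle^2 + b5 pO2` and `log10(-mumax) = c0 + c1 pO2 +
#' c2 pO2^2 + c3 Mat^2 + c4 pO2*Mat + c5 Mat*Angle`, where `Mat` is the
#' aging (maturation) time in days. Factors enter in natural units
#' (degC, %, days, degrees).
#'
#' @param b,c numeric coefficient vectors of length 6 (intercept first).
#' @return An object of class `factor_regression`.
#' @export
factor_regression <- function(b, c) {
  stopifnot(length(b) == 6, length(c) == 6,
            all(is.finite(b)), all(is.finite(c)))
  structure(list(b = as.numeric(b), c = as.numeric(c)),
            class = "factor_regression")
}

#' @export
print.factor_regression <- function(x, ...) {
  cat("factor regression (log10 scale, natural units)\n")
  cat("  lag terms   1, pO2^2, pO2*Angle, T*pO2, Angle^2, pO2:\n   ",
      paste(signif(x$b, 6), collapse = ", "), "\n")
  cat("  mumax terms 1, pO2, pO2^2, Mat^2, pO2*Mat, Mat*Angle:\n   ",
      paste(signif(x$c, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.factor_regression <- function(object, ...) {
  list(b = object$b, c = object$c)
}

#' @noRd
lag_design_row <- function(cond) {
  with(cond, c(1, pO2_pct^2, pO2_pct * angle_deg, T_C * pO2_pct,
               angle_deg^2, pO2_pct))
}

#' @noRd
mumax_design_row <- function(cond) {
  with(cond, c(1, pO2_pct, pO2_pct^2, aging_d^2, pO2_pct * aging_d,
               aging_d * angle_deg))
}

#' Lag time predicted from the storage factors
#'
#' @param reg a [factor_regression()].
#' @param cond a [storage_conditions()].
#' @return Lag in days (always positive: 10 to the regression combination).
#' @export
lag_from_factors <- function(reg, cond) {
  stopifnot(inherits(reg, "factor_regression"),
            inherits(cond, "storage_conditions"))
  10^sum(reg$b * lag_design_row(cond))
}

#' Maximum redness decay rate predicted from the storage factors
#'
#' @inheritParams lag_from_factors
#' @return mumax in a*-units per day (always negative).
#' @export
mumax_from_factors <- function(reg, cond) {
  stopifnot(inherits(reg, "factor_regression"),
            inherits(cond, "storage_conditions"))
  -10^sum(reg$c * mumax_design_row(cond))
}

#' Fit the Gompertz model to one redness series
#'
#' Nonlinear least squares over (a0, af, mumax, lag) with a
#' Levenberg-Marquardt solver, bounds `lag` in \[0, max(t)\] and
#' `mumax <= 0`. Starting values come from simple heuristics on the series
#' (head/tail means, steepest finite-difference slope, plateau departure).
#' An (almost) constant series cannot identify the shape parameters; it is
#' returned as a flagged degenerate fit with `af = a0` instead of an
#' optimizer failure.
#'
#' @param x a [color_kinetics()] (times converted to days internally), or a
#'   numeric vector of times in days.
#' @param a redness values (only when `x` is numeric).
#' @param denom_scale see [gompertz_a()].
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return An object of class `gompertz_fit` with components `params`
#'   ([gompertz_params()]), `rss`, `data`, `degenerate`, `converged` and the
#'   solver `info`. Methods: `print`, `coef`, `summary`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @export
fit_gompertz <- function(x, a = NULL, denom_scale = log(10),
                         control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (inherits(x, "color_kinetics")) {
    t_d <- x$times_h / 24
    a <- x$values
  } else {
    t_d <- as.numeric(x)
  }
  if (length(t_d) < 8)
    stop_validation("min-points", "need at least 8 time points")
  if (length(t_d) != length(a)) stop("times and values differ in length")
  t_max <- max(t_d)

  rng <- diff(range(a))
  if (rng < 1e-3 * max(abs(mean(a)), 1e-12)) {
    p <- gompertz_params(a0 = mean(a), af = mean(a), mumax = 0, lag = 0)
    warning("constant series: degenerate Gompertz fit (af = a0)",
            call. = FALSE)
    return(structure(list(params = p, rss = sum((a - mean(a))^2),
                          data = list(t_d = t_d, a = a),
                          denom_scale = denom_scale,
                          degenerate = TRUE, converged = TRUE,
                          info = "degenerate"),
                     class = "gompertz_fit"))
  }

  nhead <- max(3L, ceiling(length(a) * 0.05))
  a0_0 <- mean(utils::head(a, nhead))
  af_0 <- mean(utils::tail(a, nhead))
  if (af_0 >= a0_0) af_0 <- min(a)
  ## noise-robust slope start: time taken to fall from 25% to 75% of the
  ## total drop (level crossings are far less noise-sensitive than raw
  ## finite differences at dense sampling)
  drop <- a0_0 - af_0
  t_hi <- t_d[which(a < a0_0 - 0.25 * drop)[1]]
  t_lo <- t_d[which(a < a0_0 - 0.75 * drop)[1]]
  slope_0 <- if (!is.na(t_hi) && !is.na(t_lo) && t_lo > t_hi)
    -0.5 * drop / (t_lo - t_hi) else -drop / t_max
  mumax_0 <- slope_0 * denom_scale
  lag_0 <- if (!is.na(t_hi)) max(t_hi - 0.25 * drop / abs(slope_0), 0)
    else t_max / 2

  fn <- function(par) {
    p <- list(a0 = par[1], af = par[2], mumax = par[3], lag = par[4])
    u <- p$mumax * exp(1) * (p$lag - t_d) / ((p$af - p$a0) * denom_scale) + 1
    a - (p$a0 + (p$af - p$a0) * exp(-exp(u)))
  }
  fit <- minpack.lm::nls.lm(
    par = c(a0 = a0_0, af = af_0, mumax = mumax_0, lag = lag_0),
    fn = fn,
    lower = c(-Inf, -Inf, -Inf, 0),
    upper = c(Inf, Inf, 0, t_max),
    control = control)
  par <- fit$par
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("Gompertz fit did not converge (", fit$message,
            "); returning best-so-far parameters", call. = FALSE)
  p <- gompertz_params(a0 = par[["a0"]], af = min(par[["af"]], par[["a0"]]),
                       mumax = min(par[["mumax"]], 0), lag = par[["lag"]])
  degenerate <- par[["lag"]] >= t_max - 1e-9 || par[["a0"]] == par[["af"]]
  structure(list(params = p, rss = sum(fit$fvec^2),
                 data = list(t_d = t_d, a = a), denom_scale = denom_scale,
                 degenerate = degenerate, converged = converged,
                 info = fit$message),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz fit", if (x$degenerate) "(degenerate)" else "",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$params)
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, length(x$data$t_d)))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  t_d <- if (is.null(newdata)) object$data$t_d else as.numeric(newdata)
  gompertz_a(t_d, object$params, denom_scale = object$denom_scale)
}

#' @export
fitted.gompertz_fit <- function(object, ...) predict(object)

#' @export
residuals.gompertz_fit <- function(object, ...) {
  object$data$a - fitted(object)
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  cat("Gompertz nonlinear least-squares fit\n")
  print(object$params)
  n <- length(object$data$t_d)
  cat(sprintf("  n = %d, RSS = %.4g, residual sd = %.4g\n",
              n, object$rss, sqrt(object$rss / max(n - 4, 1))))
  cat(sprintf("  denominator scale = %.6g; degenerate = %s; %s\n",
              object$denom_scale, object$degenerate, object$info))
  invisible(object)
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  graphics::plot(x$data$t_d, x$data$a, pch = 16, cex = 0.4,
                 xlab = "time (d)", ylab = "a*", ...)
  tt <- seq(min(x$data$t_d), max(x$data$t_d), length.out = 400)
  graphics::lines(tt, gompertz_a(tt, x$params, x$denom_scale), col = 2,
                  lwd = 2)
  invisible(x)
}

#' Fit the factor regressions for lag and mumax
#'
#' Ordinary least squares of `log10(lag)` and `log10(-mumax)` on the fixed
#' term sets of [factor_regression()], over a table of per-condition
#' Gompertz estimates (one row per storage run).
#'
#' @param table data.frame with columns `T_C`, `pO2_pct`, `aging_d`,
#'   `angle_deg`, `lag_d` (> 0) and `mumax` (< 0).
#' @return A [factor_regression()] with attributes `fit_lag` and `fit_mumax`
#'   holding the residuals and fitted values of the two regressions.
#' @export
fit_factor_regression <- function(table) {
  need <- c("T_C", "pO2_pct", "aging_d", "angle_deg", "lag_d", "mumax")
  if (!all(need %in% names(table)))
    stop_parse("table", "need columns %s", paste(need, collapse = ", "))
  conds <- nrow(unique(table[, c("T_C", "pO2_pct", "aging_d", "angle_deg")]))
  if (conds < 6)
    stop_validation("min-conditions",
                    "need >= 6 distinct conditions, got %d", conds)
  if (any(table$lag_d <= 0) || any(table$mumax >= 0))
    stop_validation("log-domain", "lag_d must be > 0 and mumax < 0")

  rows <- lapply(seq_len(nrow(table)), function(i)
    storage_conditions(table$T_C[i], table$pO2_pct[i],
                       table$aging_d[i], table$angle_deg[i]))
  ols <- function(X, y, terms) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      drop <- terms[setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)])]
      stop_validation("rank-deficient",
                      "confounded terms on this design: %s",
                      paste(drop, collapse = ", "))
    }
    fit <- stats::lm.fit(X, y)
    list(coef = fit$coefficients, residuals = fit$residuals,
         fitted = fit$fitted.values)
  }
  Xl <- t(vapply(rows, lag_design_row, numeric(6)))
  Xm <- t(vapply(rows, mumax_design_row, numeric(6)))
  fl <- ols(Xl, log10(table$lag_d),
            c("1", "pO2^2", "pO2*Angle", "T*pO2", "Angle^2", "pO2"))
  fm <- ols(Xm, log10(-table$mumax),
            c("1", "pO2", "pO2^2", "Mat^2", "pO2*Mat", "Mat*Angle"))
  out <- factor_regression(fl$coef, fm$coef)
  attr(out, "fit_lag") <- fl
  attr(out, "fit_mumax") <- fm
  out
}

#' Predict a normalized redness series from the phenomenological model
#'
#' Composes [lag_from_factors()], [mumax_from_factors()] and [gompertz_a()]:
#' the two shape parameters come from the factor regressions at the given
#' storage condition, the amplitude from `a0` and `af`, and the result is
#' returned normalized by `a0`.
#'
#' @param reg a [factor_regression()].
#' @param cond a [storage_conditions()].
#' @param a0,af initial and final a*.
#' @param times_d output times, days.
#' @param denom_scale see [gompertz_a()].
#' @return A [color_kinetics()] with source `"gompertz-model"`.
#' @export
predict_phenom <- function(reg, cond, a0, af,
                           times_d = seq(0, 15, by = 1 / 96),
                           denom_scale = log(10)) {
  p <- gompertz_params(a0 = a0, af = af,
                       mumax = if (af == a0) 0 else mumax_from_factors(reg, cond),
                       lag = lag_from_factors(reg, cond))
  vals <- gompertz_a(times_d, p, denom_scale) / a0
  color_kinetics(times_d * 24, pmin(vals, 1), cond,
                 source = "gompertz-model",
                 meta = list(lag_d = p$lag, mumax = p$mumax))
}
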