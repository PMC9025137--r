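#' Oxymyoglobin ratio at the meat surface
#'
#' Computes MbO2/(MMb + Mb), the quantity the color threshold operates on.
#' With the three forms constrained to sum to 1 this equals
#' MbO2/(1 - MbO2), so only the oxymyoglobin fraction matters; both
#' arguments are still taken so the sum constraint can be verified.
#'
#' @param mbo2,mmb,mb fractions of the three myoglobin forms (vectors of a
#'   common length). Must be non-negative and sum to 1 within `tol`.
#' @param tol tolerance on the sum constraint.
#' @return MbO2/(MMb + Mb); `Inf` where MbO2 = 1.
#' @export
myoglobin_ratio <- function(mbo2, mmb, mb, tol = 1e-6) {
  s <- mbo2 + mmb + mb
  if (any(abs(s - 1) > tol))
    stop_validation("fraction-sum",
                    "myoglobin fractions sum to %.8f (tolerance %g)",
                    s[which.max(abs(s - 1))], tol)
  if (any(pmin(mbo2, mmb, mb) < -tol))
    stop_validation("fraction-nonnegative", "fractions must be >= 0")
  denom <- 1 - pmin(mbo2, 1)
  ifelse(denom <= 0, Inf, mbo2 / denom)
}

#' Map the surface myoglobin ratio to normalized redness
#'
#' Implements the threshold color rule: the normalized redness a*/a*0 stays
#' at 1 while the surface ratio r = MbO2/(MMb + Mb) is at or above the
#' threshold S, and follows the ratio (normalized by its value at S, i.e.
#' r/S) once it falls below. The normalized form is continuous at r = S and
#' bounded in \[0, 1\]. `rule = "literal"` instead returns r itself below the
#' threshold (the raw piecewise rule, discontinuous at S and retained only
#' for comparison). `smooth = TRUE` opts into a soft-threshold variant,
#' a*/a*0 = (r/S) / (1 + (r/S)^p)^(1/p), a smooth lower bound of
#' min(r/S, 1) whose sharpness grows with `smoothness`; it acknowledges that
#' a single sharp threshold is an idealization.
#'
#' @param r surface ratio(s), >= 0.
#' @param S threshold, > 0.
#' @param rule `"normalized"` (default) or `"literal"`.
#' @param smooth logical; use the smooth variant (only with the normalized
#'   rule).
#' @param smoothness exponent p of the smooth variant.
#' @return a*/a*0 values in \[0, 1\].
#' @export
color_from_ratio <- function(r, S, rule = c("normalized", "literal"),
                             smooth = FALSE, smoothness = 8) {
  rule <- match.arg(rule)
  if (!is_number(S) || S <= 0) stop_validation("S-positive", "S must be > 0")
  if (any(r < 0)) stop_validation("ratio-nonnegative", "r must be >= 0")
  if (rule == "literal") return(ifelse(r >= S, 1, r))
  z <- r / S
  if (smooth) z / (1 + z^smoothness)^(1 / smoothness) else pmin(z, 1)
}

#' Redness kinetics container
#'
#' A time series of normalized redness a*/a*0 under one storage condition.
#' Observed and synthetic series may slightly overshoot 1 (measurement
#' noise); model output may not.
#'
#' @param times_h strictly increasing storage times, hours.
#' @param values a*/a*0 values.
#' @param conditions a [storage_conditions()].
#' @param source one of `"observed"`, `"rd-model"`, `"gompertz-model"`,
#'   `"synthetic"`.
#' @param meta optional named list of extra metadata (e.g. seed, sigma).
#' @return An object of class `color_kinetics`.
#' @export
color_kinetics <- function(times_h, values, conditions,
                           source = c("observed", "rd-model",
                                      "gompertz-model", "synthetic"),
                           meta = list()) {
  source <- match.arg(source)
  stopifnot(inherits(conditions, "storage_conditions"),
            length(times_h) == length(values))
  if (any(diff(times_h) <= 0))
    stop_validation("times-increasing", "times must be strictly increasing")
  upper <- if (source %in% c("observed", "synthetic")) 1.05 else 1 + 1e-12
  if (any(values < 0) || any(values > upper))
    stop_validation("value-range",
                    "a*/a*0 outside [0, %.2f] for source '%s'", upper, source)
  structure(list(times_h = as.numeric(times_h),
                 values = as.numeric(values),
                 conditions = conditions, source = source, meta = meta),
            class = "color_kinetics")
}

#' @export
print.color_kinetics <- function(x, ...) {
  cat(sprintf("color kinetics (%s): %d points over %.3g d, %s\n",
              x$source, length(x$times_h), max(x$times_h) / 24,
              format(x$conditions)))
  invisible(x)
}

#' @export
as.data.frame.color_kinetics <- function(x, ...) {
  data.frame(time_h = x$times_h, a_ratio = x$values)
}

#' @export
plot.color_kinetics <- function(x, ...) {
  graphics::plot(x$times_h / 24, x$values, type = "l",
                 xlab = "storage time (d)", ylab = "a*/a*0",
                 ylim = c(0, 1.05), main = format(x$conditions), ...)
  invisible(x)
}

#' Predict normalized redness from a reaction-diffusion trajectory
#'
#' Applies [myoglobin_ratio()] and [color_from_ratio()] to the surface node
#' at each output time, converting the simulated myoglobin composition into
#' an a*/a*0 series.
#'
#' @param traj an [simulate_rd()] trajectory whose scheme contains the
#'   species `Mb`, `MbO2` and `MMb`.
#' @param S color threshold on MbO2/(MMb + Mb).
#' @inheritParams color_from_ratio
#' @return A [color_kinetics()] with source `"rd-model"`.
#' @export
predict_color <- function(traj, S = 2, rule = c("normalized", "literal"),
                          smooth = FALSE, smoothness = 8) {
  stopifnot(inherits(traj, "rd_trajectory"))
  need <- c("Mb", "MbO2", "MMb")
  missing_sp <- setdiff(need, traj$species)
  if (length(missing_sp))
    stop("scheme lacks myoglobin species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  r <- myoglobin_ratio(surface_timeseries(traj, "MbO2"),
                       surface_timeseries(traj, "MMb"),
                       surface_timeseries(traj, "Mb"))
  vals <- color_from_ratio(r, S, rule = rule, smooth = smooth,
                           smoothness = smoothness)
  color_kinetics(traj$times_s / 3600, pmin(vals, 1), traj$conditions,
                 source = "rd-model", meta = list(S = S))
}
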