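## order-6 conference matrix (Paley construction, q = 5): C'C = 5 I.
## Folding it over and adding a centre run yields the 13-run three-level
## definitive screening design; four-factor studies use its first four
## columns, the standard recommendation for fewer than six factors.
#' @noRd
conference_c6 <- function() {
  chi <- function(x) {
    x <- x %% 5
    ifelse(x == 0, 0, ifelse(x %in% c(1, 4), 1, -1))
  }
  Q <- outer(0:4, 0:4, function(i, j) chi(j - i))
  rbind(c(0, rep(1, 5)), cbind(rep(1, 5), Q))
}

## factor levels of the storage experiment
.design_levels <- list(T_C = c(2, 6, 10), pO2_pct = c(0, 20, 100),
                       aging_d = c(0, 7, 14), angle_deg = c(0, 45, 90))

#' Storage-experiment design tables
#'
#' Builds the run table of a storage experiment over the four factors
#' temperature (2/6/10 degC), headspace oxygen (0/20/100%), aging (0/7/14 d)
#' and cutting angle (0/45/90 deg). `"definitive-screening"` returns the
#' standard 13-run three-level definitive screening design (fold-over of an
#' order-6 conference matrix plus a centre run, first four columns), which
#' estimates linear and quadratic effects in few runs; `"full-factorial"`
#' returns all 81 level combinations; `"custom"` validates and echoes a
#' user-supplied run table.
#'
#' @param kind design kind.
#' @param runs for `kind = "custom"`: data.frame with columns `T_C`,
#'   `pO2_pct`, `aging_d`, `angle_deg`, every entry drawn from the factor
#'   levels above.
#' @return A data.frame of class `design_table` with one row per run.
#' @export
make_design <- function(kind = c("definitive-screening", "full-factorial",
                                 "custom"), runs = NULL) {
  kind <- match.arg(kind)
  lv <- .design_levels
  if (kind == "definitive-screening") {
    coded <- rbind(conference_c6(), -conference_c6(), 0)[, 1:4]
    out <- data.frame(T_C = lv$T_C[coded[, 1] + 2],
                      pO2_pct = lv$pO2_pct[coded[, 2] + 2],
                      aging_d = lv$aging_d[coded[, 3] + 2],
                      angle_deg = lv$angle_deg[coded[, 4] + 2])
  } else if (kind == "full-factorial") {
    out <- expand.grid(T_C = lv$T_C, pO2_pct = lv$pO2_pct,
                       aging_d = lv$aging_d, angle_deg = lv$angle_deg,
                       KEEP.OUT.ATTRS = FALSE)
  } else {
    if (is.null(runs)) stop("kind = 'custom' needs a `runs` table",
                            call. = FALSE)
    out <- as.data.frame(runs)[, names(lv)]
    for (f in names(lv))
      if (!all(out[[f]] %in% lv[[f]]))
        stop_validation("factor-levels", "%s contains values outside {%s}",
                        f, paste(lv[[f]], collapse = ", "))
    if (anyDuplicated(out))
      warning("duplicate runs in custom design (replicates?)", call. = FALSE)
  }
  class(out) <- c("design_table", "data.frame")
  out
}

#' Additive measurement-noise model for synthetic kinetics
#'
#' @param sigma standard deviation of i.i.d. Gaussian noise added to a*/a*0.
#' @param seed RNG seed making a generated dataset reproducible (the
#'   caller's RNG state is left untouched).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.02, seed = NULL) {
  if (!is_number(sigma) || sigma < 0)
    stop_validation("sigma-nonnegative", "sigma must be >= 0")
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

#' Default generating truth for synthetic storage kinetics
#'
#' Fabricated factor-regression coefficients plus amplitude (`a0 = 20`,
#' `af = 5` in a*-units) used as ground truth by the synthetic generator.
#' They are chosen to reproduce realistic storage behaviour: lag around
#' 10 d at 2 degC / 20% O2 shrinking to about 6 d at 10 degC, oxygen
#' enrichment extending the lag at low temperature, short lag without
#' oxygen, and decay rates giving a clear three-phase curve inside a 15-day
#' window. They are synthetic stand-ins -- the experimentally fitted
#' coefficients were never published -- and every generated file is labelled
#' accordingly.
#'
#' @return A list with elements `reg` ([factor_regression()]), `a0`, `af`.
#' @export
default_truth <- function() {
  list(reg = factor_regression(
    b = c(0.15, -4.1075e-4, 1e-5, -1.25e-3, -1e-5, 5.322e-2),
    c = c(1.001, -5.3475e-3, 2.4875e-5, -5e-4, -1e-4, 1e-5)),
    a0 = 20, af = 5)
}

#' Generate synthetic redness kinetics over a design
#'
#' For every run of the design, composes the factor regressions and the
#' Gompertz curve into a noise-free a*/a*0 series sampled on a regular grid
#' (default every 15 min for 15 days, 1441 points), then adds i.i.d.
#' Gaussian noise and clips to \[0, 1.05\]. The generated kinetics show the
#' three phases of the measured curves: a lag plateau near 1, a decreasing
#' exponential phase, and a final plateau near `af/a0`. Generation is
#' deterministic given the noise seed. The truth must give lags inside
#' \[1, 14\] days over the design, otherwise an error points at the first
#' offending run.
#'
#' @param design a [make_design()] table.
#' @param truth list with `reg`, `a0`, `af` (see [default_truth()]).
#' @param sampling_min sampling interval, minutes.
#' @param days series duration, days.
#' @param noise a [noise_model()].
#' @param denom_scale see [gompertz_a()].
#' @return A named list of [color_kinetics()] (source `"synthetic"`), one
#'   per design row, each carrying its true `lag_d` and `mumax` in `meta`.
#' @export
synth_kinetics <- function(design, truth = default_truth(),
                           sampling_min = 15, days = 15,
                           noise = noise_model(),
                           denom_scale = log(10)) {
  stopifnot(inherits(design, "design_table") || is.data.frame(design),
            inherits(noise, "noise_model"))
  conds <- lapply(seq_len(nrow(design)), function(i)
    storage_conditions(design$T_C[i], design$pO2_pct[i],
                       design$aging_d[i], design$angle_deg[i]))
  lags <- vapply(conds, function(cc) lag_from_factors(truth$reg, cc),
                 numeric(1))
  bad <- which(lags < 1 | lags > 14)
  if (length(bad))
    stop_validation("lag-range",
                    "truth gives lag = %.3g d at %s (must be in [1, 14] d)",
                    lags[bad[1]], format(conds[[bad[1]]]))

  times_d <- seq(0, days, by = sampling_min / (24 * 60))
  runs <- with_seed(noise$seed, lapply(seq_along(conds), function(i) {
    cc <- conds[[i]]
    mu <- mumax_from_factors(truth$reg, cc)
    p <- gompertz_params(truth$a0, truth$af, mu, lags[i])
    vals <- gompertz_a(times_d, p, denom_scale) / truth$a0
    if (noise$sigma > 0)
      vals <- vals + stats::rnorm(length(vals), 0, noise$sigma)
    vals <- pmin(pmax(vals, 0), 1.05)
    color_kinetics(times_d * 24, vals, cc, source = "synthetic",
                   meta = list(lag_d = lags[i], mumax = mu,
                               sigma = noise$sigma))
  }))
  names(runs) <- sprintf("run_%02d", seq_along(runs))
  runs
}

#' Generate self-consistency kinetics from the reaction-diffusion model
#'
#' Runs the reaction-diffusion simulator plus the threshold color map for
#' every design row at a fixed (S, Ea) and adds optional Gaussian noise: the
#' data-generating route of the calibration recovery studies, where the
#' generating parameters are known exactly.
#'
#' @param scheme a [reaction_scheme()].
#' @param design a [make_design()] table (aging and angle are carried as
#'   metadata; the mechanistic model responds to temperature and oxygen).
#' @param S,Ea_kJ_mol generating color threshold and activation energy.
#' @param noise a [noise_model()]; default noise-free.
#' @param n_nodes,depth_m grid specification.
#' @param times_h output/sampling times, hours.
#' @param ... further arguments to [simulate_rd()].
#' @return A named list of [color_kinetics()] (source `"synthetic"`).
#' @export
synth_from_rd <- function(scheme, design, S = 2, Ea_kJ_mol = 32.5,
                          noise = noise_model(sigma = 0),
                          n_nodes = 400, depth_m = 0.02,
                          times_h = seq(0, 15 * 24, by = 1), ...) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  grid <- spatial_grid(depth_m, n_nodes)
  conds <- lapply(seq_len(nrow(design)), function(i)
    storage_conditions(design$T_C[i], design$pO2_pct[i],
                       design$aging_d[i], design$angle_deg[i]))
  runs <- with_seed(noise$seed, lapply(conds, function(cc) {
    traj <- simulate_rd(scheme, grid, cc, times_s = times_h * 3600,
                        Ea_J_mol = Ea_kJ_mol * 1000, ...)
    ck <- predict_color(traj, S = S)
    vals <- ck$values
    if (noise$sigma > 0)
      vals <- pmin(pmax(vals + stats::rnorm(length(vals), 0, noise$sigma),
                        0), 1.05)
    color_kinetics(times_h, vals, cc, source = "synthetic",
                   meta = list(S = S, Ea_kJ_mol = Ea_kJ_mol,
                               sigma = noise$sigma))
  }))
  names(runs) <- sprintf("run_%02d", seq_along(runs))
  runs
}
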