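#' Root of the residual sum of squares between two redness series
#'
#' The fit statistic of the calibration report: the prediction is linearly
#' interpolated to the observation times and the square root of the summed
#' squared differences is returned. The prediction must cover the
#' observation time span (no extrapolation).
#'
#' @param obs,pred [color_kinetics()] objects (or lists with `times_h` and
#'   `values`).
#' @return A non-negative scalar.
#' @export
rss_root <- function(obs, pred) {
  if (min(pred$times_h) > min(obs$times_h) ||
      max(pred$times_h) < max(obs$times_h))
    stop_validation("time-cover",
                    "prediction does not cover the observation span")
  pi <- stats::approx(pred$times_h, pred$values, xout = obs$times_h)$y
  sqrt(sum((obs$values - pi)^2))
}

## surface ratio series for one condition at one Ea, interpolated to the
## observation times. The trajectory does not depend on S, so one simulation
## serves every S candidate.
#' @noRd
ratio_at_times <- function(scheme, grid, cond, obs_times_h, Ea_J_mol, ...) {
  times_s <- sort(unique(c(0, obs_times_h * 3600)))
  traj <- simulate_rd(scheme, grid, cond, times_s, Ea_J_mol = Ea_J_mol, ...)
  mbo2 <- surface_timeseries(traj, "MbO2")
  r <- mbo2 / pmax(1 - mbo2, .Machine$double.eps)
  stats::approx(times_s / 3600, r, xout = obs_times_h)$y
}

#' Staged least-squares identification of the color threshold and
#' activation energy
#'
#' Identifies the color threshold `S` and the single activation energy `Ea`
#' of the reaction-diffusion model against observed (or synthetic) a*/a*0
#' kinetics, pooling the squared residuals over every available storage
#' condition with equal weight. Three stages mirror how the parameters were
#' originally ranged on progressively finer grids:
#'
#' 1. **Coarse scan** -- direct calculation on the coarse mesh over every
#'    `S_candidates` x `Ea_grid_kJ` pair (one simulation per Ea and
#'    condition; the color map is re-applied per S). The best `shortlist`
#'    thresholds move on.
#' 2. **Levenberg-Marquardt refinement** of Ea at each shortlisted S, still
#'    on the coarse mesh, starting from that threshold's best grid Ea.
#' 3. **Fine-mesh verification** -- the per-condition root-RSS table is
#'    recomputed on the fine mesh at each refined (S, Ea); the pair with the
#'    smallest mean wins, ties broken toward the smaller S.
#'
#' @param scheme a [reaction_scheme()].
#' @param dataset list of [color_kinetics()] spanning at least two storage
#'   conditions.
#' @param S_candidates integer thresholds to scan.
#' @param Ea_grid_kJ stage-1 activation-energy grid, kJ mol-1; also used as
#'   box bounds for the LM stage.
#' @param coarse_nodes,fine_nodes mesh sizes for the scan/refinement and the
#'   verification stages.
#' @param depth_m slab depth, metres.
#' @param shortlist how many thresholds to carry into stages 2-3.
#' @param rule color rule passed to [color_from_ratio()].
#' @param ... further arguments to [simulate_rd()].
#' @return An object of class `rd_calibration`: the selected `S` and
#'   `Ea_kJ_mol`, the per-condition root-RSS table (`per_condition`) and its
#'   mean (`mean_rss_root`) on the fine mesh, the meshes used, the stage-1
#'   scan table (`stage1`), per-candidate refinement results (`stage2`) and
#'   the fine-mesh table for every shortlisted configuration (`stage3`,
#'   feeding [table1_report()]).
#' @export
calibrate_rd <- function(scheme, dataset, S_candidates = 1:4,
                         Ea_grid_kJ = seq(25, 40, by = 2.5),
                         coarse_nodes = 100, fine_nodes = 400,
                         depth_m = 0.02, shortlist = 2,
                         rule = "normalized", ...) {
  stopifnot(length(dataset) >= 1)
  conds <- lapply(dataset, `[[`, "conditions")
  if (nrow(unique(do.call(rbind, lapply(conds, function(x)
    data.frame(x$T_C, x$pO2_pct))))) < 2)
    stop_validation("min-conditions", "dataset must span >= 2 conditions")

  coarse <- spatial_grid(depth_m, coarse_nodes)
  fine <- spatial_grid(depth_m, fine_nodes)

  pooled_rss_root <- function(ratios, S) {
    ss <- 0
    for (i in seq_along(dataset)) {
      pred <- color_from_ratio(ratios[[i]], S, rule = rule)
      ss <- ss + sum((dataset[[i]]$values - pred)^2)
    }
    sqrt(ss)
  }

  ## stage 1: coarse grid scan -----------------------------------------
  stage1 <- expand.grid(S = S_candidates, Ea_kJ = Ea_grid_kJ)
  stage1$rss_root <- NA_real_
  for (Ea in Ea_grid_kJ) {
    ratios <- lapply(dataset, function(obs)
      ratio_at_times(scheme, coarse, obs$conditions, obs$times_h,
                     Ea_J_mol = Ea * 1000, ...))
    for (S in S_candidates)
      stage1$rss_root[stage1$S == S & stage1$Ea_kJ == Ea] <-
        pooled_rss_root(ratios, S)
  }
  if (diff(range(stage1$rss_root)) < 1e-10)
    warning("objective is insensitive to S and Ea over the scanned grid ",
            "(flat residuals); returning the minimal-RSS candidate",
            call. = FALSE)

  best_per_S <- do.call(rbind, lapply(split(stage1, stage1$S), function(d)
    d[which.min(d$rss_root), ]))
  best_per_S <- best_per_S[order(best_per_S$rss_root, best_per_S$S), ]
  keep <- utils::head(best_per_S, shortlist)

  ## stage 2: LM refinement of Ea at each shortlisted S -----------------
  Ea_lo <- min(Ea_grid_kJ)
  Ea_hi <- max(Ea_grid_kJ)
  nudge <- 1e-3 * (Ea_hi - Ea_lo)      # keep the LM start strictly inside
  stage2 <- lapply(seq_len(nrow(keep)), function(i) {
    S <- keep$S[i]
    resid_fn <- function(par) {
      unlist(lapply(dataset, function(obs) {
        r <- ratio_at_times(scheme, coarse, obs$conditions, obs$times_h,
                            Ea_J_mol = par[1] * 1000, ...)
        obs$values - color_from_ratio(r, S, rule = rule)
      }), use.names = FALSE)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(Ea_kJ = min(max(keep$Ea_kJ[i],
                                                 Ea_lo + nudge),
                                             Ea_hi - nudge)),
                         fn = resid_fn,
                         lower = Ea_lo, upper = Ea_hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 50, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("LM refinement failed at S = ", S, " (", conditionMessage(fit),
              "); candidate skipped", call. = FALSE)
      return(NULL)
    }
    list(S = S, Ea_kJ = unname(fit$par[1]), rss_root = sqrt(fit$deviance),
         info = fit$message)
  })
  stage2 <- Filter(Negate(is.null), stage2)
  if (!length(stage2))
    stop("all LM refinements failed; no calibration candidate survives",
         call. = FALSE)

  ## stage 3: fine-mesh verification ------------------------------------
  cond_label <- vapply(conds, format, character(1))
  stage3 <- lapply(stage2, function(cand) {
    per <- vapply(seq_along(dataset), function(i) {
      obs <- dataset[[i]]
      r <- ratio_at_times(scheme, fine, obs$conditions, obs$times_h,
                          Ea_J_mol = cand$Ea_kJ * 1000, ...)
      pred <- color_kinetics(obs$times_h,
                             color_from_ratio(r, cand$S, rule = rule),
                             obs$conditions, source = "rd-model")
      rss_root(obs, pred)
    }, numeric(1))
    names(per) <- cond_label
    c(cand, list(per_condition = per, mean_rss_root = mean(per),
                 mesh = fine_nodes))
  })

  means <- vapply(stage3, `[[`, numeric(1), "mean_rss_root")
  Ss <- vapply(stage3, `[[`, numeric(1), "S")
  pick <- order(means, Ss)[1]              # ties -> smaller S
  sel <- stage3[[pick]]

  structure(list(
    S = sel$S, Ea_kJ_mol = sel$Ea_kJ,
    per_condition = data.frame(
      T_C = vapply(conds, `[[`, numeric(1), "T_C"),
      pO2_pct = vapply(conds, `[[`, numeric(1), "pO2_pct"),
      rss_root = unname(sel$per_condition),
      row.names = NULL),
    mean_rss_root = sel$mean_rss_root,
    mesh_used = c(coarse = coarse_nodes, fine = fine_nodes),
    stage1 = stage1, stage2 = stage2, stage3 = stage3,
    conditions = conds
  ), class = "rd_calibration")
}

#' @export
print.rd_calibration <- function(x, ...) {
  cat(sprintf("reaction-diffusion calibration: S = %g, Ea = %.3f kJ/mol\n",
              x$S, x$Ea_kJ_mol))
  cat(sprintf("  mean root-RSS = %.4g on the %d-node mesh (%d conditions)\n",
              x$mean_rss_root, x$mesh_used[["fine"]],
              nrow(x$per_condition)))
  invisible(x)
}

#' @export
summary.rd_calibration <- function(object, ...) {
  print(object)
  cat("\nper-condition root-RSS (fine mesh, selected parameters):\n")
  print(object$per_condition, row.names = FALSE)
  cat("\nstage-1 coarse scan (best Ea per S):\n")
  s1 <- object$stage1
  best <- do.call(rbind, lapply(split(s1, s1$S), function(d)
    d[which.min(d$rss_root), ]))
  print(best, row.names = FALSE)
  invisible(object)
}

#' Quality-of-fit table across evaluated configurations
#'
#' Formats the per-condition root-RSS of every configuration the fine-mesh
#' verification evaluated, one column per (S, Ea, mesh) configuration, one
#' row per (O2, T) condition, plus a mean row -- the layout of the
#' calibration quality-of-fit report.
#'
#' @param result an [calibrate_rd()] result.
#' @return A data.frame with condition columns `pO2_pct`, `T_C`, one numeric
#'   column per configuration and a final `"mean"` row.
#' @export
table1_report <- function(result) {
  stopifnot(inherits(result, "rd_calibration"))
  if (!length(result$stage3) ||
      !length(result$stage3[[1]]$per_condition))
    stop("empty per-condition map; nothing to report", call. = FALSE)
  conds <- result$conditions
  df <- data.frame(
    pO2_pct = vapply(conds, `[[`, numeric(1), "pO2_pct"),
    T_C = vapply(conds, `[[`, numeric(1), "T_C"))
  ord <- order(df$pO2_pct, df$T_C)
  df <- df[ord, ]
  for (cand in result$stage3) {
    col <- sprintf("S=%g,Ea=%.3g,mesh=%d", cand$S, cand$Ea_kJ, cand$mesh)
    df[[col]] <- unname(cand$per_condition)[ord]
  }
  mean_row <- df[1, ]
  mean_row$pO2_pct <- NA
  mean_row$T_C <- NA
  for (j in 3:ncol(df)) mean_row[[j]] <- mean(df[[j]])
  out <- rbind(df, mean_row)
  rownames(out) <- c(paste0("cond", seq_len(nrow(df))), "mean")
  out
}
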