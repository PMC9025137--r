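#' Uniform 1-D depth grid for the meat slab
#'
#' Nodes are uniformly spaced with `x = 0` at the exposed surface and
#' increasing into the meat. The default slab depth of 0.02 m reflects the
#' 2-3 cm thickness of the ribeye steaks the models were developed for.
#'
#' @param depth_m total slab depth, metres (> 0).
#' @param n_nodes number of grid nodes (>= 10); 100 or 200 for coarse
#'   parameter scans, 400 for final surface-color computations.
#' @return An object of class `spatial_grid` with elements `depth_m`,
#'   `n_nodes`, `dx` and node positions `x`.
#' @export
spatial_grid <- function(depth_m = 0.02, n_nodes = 400) {
  if (!is_number(depth_m) || depth_m <= 0)
    stop_validation("depth-positive", "depth_m must be > 0")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 10)
    stop_validation("min-nodes", "n_nodes must be >= 10")
  structure(list(
    depth_m = depth_m, n_nodes = n_nodes,
    dx = depth_m / (n_nodes - 1),
    x = seq(0, depth_m, length.out = n_nodes)
  ), class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("1-D grid: %d nodes over %.4g m (dx = %.3g m)\n",
              x$n_nodes, x$depth_m, x$dx))
  invisible(x)
}

#' Storage conditions for one packaged-meat run
#'
#' @param T_C storage temperature, degrees C. Values outside the cold-chain
#'   range -2 to 25 degC trigger a warning.
#' @param pO2_pct headspace oxygen content, percent (0-100).
#' @param aging_d post-mortem aging time at packaging, days.
#' @param angle_deg cutting angle relative to the muscle-fibre direction,
#'   degrees.
#' @return An object of class `storage_conditions`.
#' @export
storage_conditions <- function(T_C, pO2_pct, aging_d = 14, angle_deg = 0) {
  if (!is_number(T_C)) stop_validation("T", "T_C must be a finite number")
  if (!is_number(pO2_pct) || pO2_pct < 0 || pO2_pct > 100)
    stop_validation("pO2-range", "pO2_pct must be in [0, 100]")
  if (T_C < -2 || T_C > 25)
    warning("T_C = ", T_C, " degC is outside the usual cold-storage range ",
            "(-2 to 25 degC)", call. = FALSE)
  structure(list(T_C = T_C, pO2_pct = pO2_pct,
                 aging_d = aging_d, angle_deg = angle_deg),
            class = "storage_conditions")
}

#' @export
print.storage_conditions <- function(x, ...) {
  cat(sprintf("storage: %.3g degC, %.3g%% O2, aged %.3g d, angle %.3g deg\n",
              x$T_C, x$pO2_pct, x$aging_d, x$angle_deg))
  invisible(x)
}

#' @export
format.storage_conditions <- function(x, ...) {
  sprintf("T=%gC/O2=%g%%", x$T_C, x$pO2_pct)
}
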