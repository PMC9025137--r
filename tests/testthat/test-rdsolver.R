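grid100 <- spatial_grid(0.02, 100)
day_s <- 86400

test_that("grid and conditions validate their invariants", {
  g <- spatial_grid(0.02, 100)
  expect_equal(g$dx, 0.02 / 99)
  expect_equal(g$x[c(1, 100)], c(0, 0.02))
  expect_error(spatial_grid(0, 100), "depth-positive")
  expect_error(spatial_grid(0.02, 5), "min-nodes")
  expect_error(storage_conditions(2, 120), "pO2-range")
  expect_warning(storage_conditions(30, 20), "cold-storage")
})

test_that("initial state follows the post-blooming profile", {
  sch <- default_scheme()
  st <- initial_state(grid100, sch)
  expect_equal(st$C[c("Mb", "MbO2", "MMb"), 1], c(Mb = 0.05, MbO2 = 0.90,
                                                  MMb = 0.05))
  expect_equal(st$C[c("Mb", "MbO2", "MMb"), 100], c(Mb = 0.95, MbO2 = 0,
                                                    MMb = 0.05))
  ## myoglobin fractions sum to 1 at every node
  expect_equal(colSums(st$C[c("Mb", "MbO2", "MMb"), ]), rep(1, 100))
  ## O2 zero below the surface node
  expect_true(all(st$C["O2", -1] == 0))

  uni <- initial_state(grid100, sch, uniform_profile(c(Mb = 0.2, MbO2 = 0.5,
                                                       MMb = 0.3)))
  expect_true(all(uni$C["MbO2", ] == 0.5))

  expect_error(initial_state(grid100, sch,
                             bloom_profile(surface = c(Mb = 0.5, MbO2 = 0.6,
                                                       MMb = 0.1))),
               "profile-sum")
})

test_that("frozen system stays at its initial state", {
  sch <- scheme_with_k(0, D_O2 = 0)
  times <- c(0, 1, 5, 10) * day_s
  init <- initial_state(grid100, sch)
  traj <- simulate_rd(sch, grid100, storage_conditions(2, 20), times,
                      init = init)
  for (i in seq_along(times)) {
    st <- get_state(traj, i)
    expect_equal(st$C[c("Mb", "MbO2", "MMb"), ],
                 init$C[c("Mb", "MbO2", "MMb"), ], tolerance = 1e-12)
  }
  ## surface series constant at the initial surface value
  expect_equal(surface_timeseries(traj, "MbO2"), rep(0.90, length(times)))
  expect_error(surface_timeseries(traj, "Xy"), "unknown species")
})

test_that("pure diffusion matches the semi-infinite erfc solution", {
  sch <- scheme_with_k(0)                     # D_O2 = 1e-10 kept
  grid400 <- spatial_grid(0.02, 400)
  times <- c(0, 1800, 5400, 10800, 21600)
  traj <- simulate_rd(sch, grid400, storage_conditions(2, 20), times)
  Cs <- sch$o2_solubility * 20
  for (i in 3:5) {
    num <- get_state(traj, i)$C["O2", ]
    ana <- Cs * erfc_ref(grid400$x / (2 * sqrt(sch$D_O2 * times[i])))
    sel <- ana >= 0.05 * Cs
    expect_lt(max(abs(num[sel] - ana[sel]) / ana[sel]), 0.01)
  }
})

test_that("with D = 0 and uniform init every node matches a 0-D ODE oracle", {
  sch <- default_scheme()
  sch$D_O2 <- 0
  comp <- c(Mb = 0.3, MbO2 = 0.5, MMb = 0.2)
  init <- initial_state(grid100, sch, uniform_profile(comp))
  init$C["O2", ] <- 0.1                       # uniform dissolved oxygen
  cond <- storage_conditions(2, 0.1 / sch$o2_solubility)  # match surface BC
  times <- seq(0, 5 * day_s, by = 6 * 3600)
  ## tolerances well below the 1e-6 comparison threshold
  traj <- simulate_rd(sch, grid100, cond, times, init = init,
                      rtol = 1e-9, atol = 1e-14)

  ## independent 0-D integration: hand-written RHS for the default scheme
  k <- arrhenius_scale(sch, 275.15)
  rhs0 <- function(t, y, p) {
    r <- c(k[1] * y[1] * y[4], k[2] * y[2], k[3] * y[1], k[4] * y[2],
           k[5] * y[3])
    list(c(-r[1] + r[2] - r[3] + r[5],
           r[1] - r[2] - r[4],
           r[3] + r[4] - r[5],
           -r[1] + r[2]))
  }
  ref <- deSolve::ode(c(0.3, 0.5, 0.2, 0.1), times, rhs0, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  for (s in seq_along(traj$species)) {
    blk <- myocolor:::species_block(traj, traj$species[s])
    for (node in c(1, 50, 100))
      expect_equal(blk[, node], unname(ref[, 1 + s]), tolerance = 1e-6)
  }
})

test_that("myoglobin is conserved and O2 bounded along trajectories", {
  times <- seq(0, 15 * day_s, by = 6 * 3600)
  for (cond in list(storage_conditions(2, 20), storage_conditions(10, 100))) {
    traj <- simulate_rd(default_scheme(), grid100, cond, times)
    s <- myocolor:::species_block(traj, "Mb") +
      myocolor:::species_block(traj, "MbO2") +
      myocolor:::species_block(traj, "MMb")
    expect_lt(max(abs(s - 1)), 1e-6)
    expect_true(all(traj$y >= 0))
  }
  ## O2 bounded above by the boundary value when nothing produces O2
  sch <- scheme_no_o2_production()
  traj <- simulate_rd(sch, grid100, storage_conditions(2, 20), times)
  o2 <- myocolor:::species_block(traj, "O2")
  expect_true(all(o2 <= sch$o2_solubility * 20 + 1e-9))
  expect_true(all(o2 >= 0))
})

test_that("solution is tolerance-controlled, not step-limited", {
  times <- seq(0, 15 * day_s, by = 6 * 3600)
  cond <- storage_conditions(2, 20)
  t1 <- simulate_rd(default_scheme(), grid100, cond, times)
  t2 <- simulate_rd(default_scheme(), grid100, cond, times,
                    rtol = 1e-8, atol = 1e-14)
  r <- function(traj) {
    m <- surface_timeseries(traj, "MbO2")
    m / (1 - m)
  }
  expect_lt(max(abs(r(t1) - r(t2))), 1e-4)
})

test_that("browning accelerates monotonically with storage temperature", {
  times <- seq(0, 15 * day_s, by = 3600)
  lag_days <- sapply(c(2, 6, 10), function(T_C) {
    traj <- simulate_rd(default_scheme(), grid100,
                        storage_conditions(T_C, 20), times)
    ck <- predict_color(traj, S = 2)
    crossing_time_h(ck, 1 - 1e-9) / 24
  })
  expect_true(all(diff(lag_days) < 0))
})

test_that("mesh refinement study reports non-increasing differences", {
  mc <- mesh_convergence(default_scheme(), storage_conditions(2, 20),
                         node_counts = c(50, 100, 200),
                         times_s = seq(0, 10 * day_s, by = 2 * 3600))
  ## surface chemistry is local under the Dirichlet boundary, so the series
  ## is already converged on coarse grids: differences either shrink with
  ## refinement or sit below the integration-tolerance floor
  expect_true(all(diff(mc$diffs) <= 0) || max(mc$diffs) < 1e-6)
  ## identical node counts give exactly zero difference
  mc0 <- mesh_convergence(default_scheme(), storage_conditions(2, 20),
                          node_counts = c(60, 60),
                          times_s = seq(0, day_s, by = 2 * 3600))
  expect_equal(mc0$diffs, 0)
  expect_error(mesh_convergence(default_scheme(),
                                storage_conditions(2, 20), 100),
               "node-counts")
})

test_that("simulation rejects invalid inputs", {
  sch <- default_scheme()
  expect_error(simulate_rd(sch, grid100, storage_conditions(2, 20),
                           c(0, 10, 5)), "times")
  expect_error(simulate_rd(sch, grid100, storage_conditions(2, 20),
                           c(0, 31 * day_s)), "times-span")
})
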