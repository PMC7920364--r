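p <- default_dimensionless_parameters()

test_that("the all-zero state is a fixed point without treatment sources", {
  grid <- build_grid(transwell_geometry(), h = 0.05)
  st <- new_state(grid)
  out <- solver_step(st, 0.01, p)
  expect_equal(out$fields, st$fields)
  expect_equal(out$t, 0.01)
})

test_that("a single macro step reproduces exponential decay to high order", {
  grid <- build_grid(transwell_geometry(), h = 0.05)
  pz <- scenario_overrides(diffusion_only_params(), list(mu_C = 0.23112))
  st <- new_state(grid, C = 1)
  dt <- 1e-3
  out <- solver_step(st, dt, pz)
  expect_equal(out$fields[, "C"], rep(exp(-0.23112 * dt), 20),
               tolerance = 1e-10)
})

test_that("trajectories are deterministic and sampling-invariant", {
  sc <- make_scenario("tan", t_end = 2, output_times = c(0, 1, 2))
  t1 <- run_scenario(sc, h = 0.02)
  t2 <- run_scenario(sc, h = 0.02)
  expect_identical(t1$states, t2$states)
  # the adaptive step sequence never depends on the output schedule (dense
  # output), so a denser schedule leaves shared snapshots bit-identical
  sc2 <- make_scenario("tan", t_end = 2, output_times = seq(0, 2, by = 0.5))
  t3 <- run_scenario(sc2, h = 0.02)
  expect_identical(state_at(t3, 1), state_at(t1, 1))
  expect_identical(state_at(t3, 2), state_at(t1, 2))
})

test_that("a zero-length run returns the initial state only", {
  sc <- make_scenario("control", t_end = 0, output_times = 0)
  tr <- run_scenario(sc, h = 0.05)
  expect_equal(tr$times, 0)
  expect_equal(state_at(tr, 0), initial_state(sc, tr$grid)$fields)
})

test_that("trajectory invariants hold on a production run", {
  tr <- cached_run("tan")
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$times[1], 0)
  expect_equal(max(tr$times), 22)
  # non-negativity of every field at every output time
  expect_true(all(vapply(tr$states, function(f) all(f >= 0), logical(1))))
  # ECM is monotone non-increasing everywhere
  rho <- sapply(tr$states, function(f) f[, "rho"])
  expect_true(all(diff(t(rho)) <= 1e-12))
})

test_that("failed nonlinear solves reject the step and collapse is a hard error", {
  grid <- build_grid(transwell_geometry(), h = 0.05)
  st <- new_state(grid, n = 0.5, N1 = 0.5, G = 1)
  # an absurdly large fixed step cannot converge: dt halving must bottom out
  cfg <- solver_config(dt_init = 1e6, dt_min = 1e6, dt_max = 1e6,
                       newton_maxit = 2)
  expect_error(run_simulation(st, 2e6, p, cfg), "dt_min")
})

test_that("N1 + N2 is conserved under pure phenotype transition", {
  pz <- scenario_overrides(transport_only_params(), list(lambda_12 = 0.16))
  # hold TGF-beta fixed (no production, no decay) so only the transfer acts
  grid <- build_grid(transwell_geometry(), h = 0.02)
  st <- new_state(grid, N1 = 1, G = 2)
  tr <- run_simulation(st, 5, pz, solver_config(dt_max = 1e-2))
  f <- state_at(tr, 5)
  expect_equal(sum(f[, "N1"] + f[, "N2"]) * grid$h, 1, tolerance = 1e-10)
  expect_gt(sum(f[, "N2"]), 0)   # the transfer really happened
})

test_that("self-convergence on a smooth problem has order >= 1 in time and space", {
  # smooth initial data, no steep fronts: diffusion + full kinetics
  smooth_run <- function(h, dt) {
    grid <- build_grid(transwell_geometry(), h = h)
    x <- grid$cell_centers
    st <- new_state(grid, n = 0.4 + 0.2 * sin(pi * x),
                    N1 = 0.5 + 0.2 * cos(pi * x),
                    C = 0.1, G = 0.5, E = 0.2, rho = 0)
    cfg <- solver_config(dt_init = dt, dt_max = dt, dt_min = dt / 1e6)
    run_simulation(st, 1, p, cfg)
  }
  # time refinement at fixed grid
  u1 <- state_at(smooth_run(0.02, 4e-3), 1)
  u2 <- state_at(smooth_run(0.02, 2e-3), 1)
  u4 <- state_at(smooth_run(0.02, 1e-3), 1)
  e1 <- max(abs(u1 - u2)); e2 <- max(abs(u2 - u4))
  expect_gte(log2(e1 / e2), 1)
  # space refinement (compare integrated masses, which live on all grids)
  msum <- function(h) total_mass(state_at(smooth_run(h, 1e-3), 1), h)
  m1 <- msum(0.05); m2 <- msum(0.025); m4 <- msum(0.0125)
  eh1 <- max(abs(m1 - m2)); eh2 <- max(abs(m2 - m4))
  expect_gte(log2(eh1 / eh2), 1)
})
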