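p <- default_dimensionless_parameters()

test_that("diffusive flux matches two-point formulas", {
  h <- 0.25
  expect_equal(diffusive_flux(rep(2, 4), 1, h), rep(0, 5))
  u <- seq(0.125, 0.875, by = 0.25)           # u = x on cell centers
  fl <- diffusive_flux(u, 0.3, h)
  expect_equal(fl[2:4], rep(-0.3, 3))
  expect_equal(fl[c(1, 5)], c(0, 0))          # sealed exterior
  checker <- c(0, 1, 0, 1)
  expect_equal(diffusive_flux(checker, 0.5, h)[2:4],
               c(-0.5, 0.5, -0.5) / h)
})

test_that("saturating taxis flux is upwinded and saturates at chi/sigma", {
  h <- 0.1
  u <- rep(2, 4)
  expect_equal(saturating_taxis_flux(u, rep(1, 4), 1, 1, 1, h), rep(0, 5))
  # direct evaluation: gradient 3 across each face
  s <- c(0, 0.3, 0.6, 0.9)
  fl <- saturating_taxis_flux(u, s, 1, 1, 1, h)
  expect_equal(fl[2:4], rep(2 * 3 / (1 + 3), 3))
  # saturation: enormous gradients give speed chi/sigma times upwind value
  s2 <- c(0, 1e9, 2e9, 3e9)
  fl2 <- saturating_taxis_flux(u, s2, 1.5, 1, 2, h)
  expect_equal(fl2[2:4], rep(1.5 / 2 * 2, 3), tolerance = 1e-6)
  # upwinding picks the donor cell
  u3 <- c(1, 0, 0, 5)
  up <- saturating_taxis_flux(u3, s, 1, 1, 1, h)    # flow to the right
  expect_equal(up[2], 1 * 3 / 4)                    # donor = left cell
  dn <- saturating_taxis_flux(u3, rev(s), 1, 1, 1, h)
  expect_equal(dn[4], -5 * 3 / 4)                   # donor = right cell
  # mask: face active when either side is inside the region
  m <- c(0, 1, 1, 0)
  fm <- saturating_taxis_flux(u, s, 1, 1, 1, h, mask = m)
  expect_equal(fm[2:4], rep(1.5, 3))
  fm0 <- saturating_taxis_flux(u, s, 1, 1, 1, h, mask = c(0, 0, 1, 1))
  expect_equal(fm0[2], 0)
  expect_error(saturating_taxis_flux(u, s, 1, 0, 1, h), "delta")
})

test_that("membrane jump law and discrete divergence telescope", {
  expect_equal(membrane_flux(1, 1, 50), 0)
  expect_equal(membrane_flux(1, 0, 0), 0)
  expect_equal(membrane_flux(1, 0, 785), 785)
  h <- 0.2
  expect_equal(divergence(rep(3, 6), h), rep(0, 5))
  fl <- c(0, 0, 1, 0, 0, 0)
  expect_equal(divergence(fl, h), c(0, -1 / h, 1 / h, 0, 0))
  set.seed(1)
  rfl <- c(0, rnorm(4), 0)
  expect_equal(sum(divergence(rfl, h)) * h, 0, tolerance = 1e-14)
})

test_that("transport conserves total mass and gamma = 0 seals the chambers", {
  pz <- transport_only_params()
  grid <- build_grid(transwell_geometry(), h = 0.02)
  set.seed(11)
  init <- lapply(1:11, function(i) runif(50, 0, 2))
  names(init) <- c("n", "N1", "N2", "rho", "C", "G", "E", "D", "P", "M", "A")
  st <- do.call(new_state, c(list(grid), init))
  tr <- run_simulation(st, c(0.5, 1), pz, solver_config(dt_max = 5e-3))
  m0 <- total_mass(st$fields, grid$h)
  m1 <- total_mass(state_at(tr, 1), grid$h)
  expect_equal(m1, m0, tolerance = 1e-12)
  expect_true(all(state_at(tr, 1) >= 0))     # positivity under upwind + CFL
  # sealed membrane: per-chamber masses constant for every variable
  ps <- scenario_overrides(pz, list(gamma_c = 0, gamma_m = 0))
  trs <- run_simulation(st, 1, ps, solver_config(dt_max = 5e-3))
  lo <- lower_chamber_mask(grid)
  for (v in colnames(st$fields)) {
    expect_equal(sum(state_at(trs, 1)[, v] * lo), sum(st$fields[, v] * lo),
                 tolerance = 1e-12)
  }
})

test_that("large permeability approaches the closed-form single-domain solution", {
  # cosine mode on [0,1] under Neumann walls decays as exp(-D (2 pi k)^2 t)
  pz <- scenario_overrides(diffusion_only_params(),
                           list(gamma_c = 1e6, gamma_m = 1e6))
  grid <- build_grid(transwell_geometry(), h = 0.01)
  x <- grid$cell_centers
  st <- new_state(grid, C = 1 + 0.5 * cos(2 * pi * x))
  tr <- run_simulation(st, 1, pz, solver_config(dt_max = 5e-3))
  DC <- pz$D_C
  exact <- 1 + 0.5 * cos(2 * pi * x) * exp(-DC * (2 * pi)^2 * 1)
  got <- state_at(tr, 1)[, "C"]
  expect_lt(max(abs(got - exact)) / max(abs(exact)), 1e-3)
  # decay-rate check within 1%
  amp <- 2 * sum(got * cos(2 * pi * x)) * grid$h / 0.5
  rate <- -log(amp) / (DC * (2 * pi)^2)
  expect_lt(abs(rate - 1), 0.01)
})
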