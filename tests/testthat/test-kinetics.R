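p <- default_dimensionless_parameters()

test_that("tumor net production reproduces limiting cases", {
  expect_equal(tumor_reaction(0, 1, 1, p), 0)
  # logistic saturation at carrying capacity, no NE, no killing
  expect_equal(tumor_reaction(p$n0, 0, 0, p), 0)
  # Hill factor is 1/2 at half-saturation
  n <- p$n0 / 2
  expect_equal(tumor_reaction(n, p$k_E, 0, p),
               p$r * (1 + p$r_E / 2) * p$n0 / 4, tolerance = 1e-12)
  # N1 killing is linear in both densities
  expect_equal(tumor_reaction(1, 0, 2, scenario_overrides(p, list(r = 0))),
               -2 * p$mu_n, tolerance = 1e-12)
})

test_that("phenotype transition transfers mass exactly", {
  rates <- neutrophil_reactions(c(1, 0.5), c(0.2, 0), 0, p)
  expect_equal(rates$N1, p$lambda_1 * c(1, 0.5))   # no conversion without TGF-beta
  expect_equal(rates$N2, p$lambda_2 * c(0.2, 0))
  expect_equal(neutrophil_reactions(0, 3, 5, p)$N1, 0)
  p0 <- scenario_overrides(p, list(lambda_1 = 0, lambda_2 = 0))
  r0 <- neutrophil_reactions(1.3, 0.4, 2.5, p0)
  expect_equal(r0$N1 + r0$N2, 0)                   # pure transfer
})

test_that("ECM proteolysis acts only on the matrix region and only with proteases", {
  S <- c(0, 1, 1, 0)
  expect_equal(ecm_decay(rep(1, 4), 0, 0, rep(1, 4), p, S), rep(0, 4))
  p1 <- scenario_overrides(p, list(mu_rho1 = 1, mu_rho2 = 0))
  out <- ecm_decay(rep(1, 4), rep(2, 4), 0, rep(0.5, 4), p1, S)
  expect_equal(out, c(0, -1, -1, 0))
})

test_that("molecular kinetics match direct evaluation and steady states", {
  z <- rep(0, 3)
  quiet <- chemokine_reactions(z, z, z, z, z, z, z, z, z, p, rep(1, 3))
  expect_true(all(vapply(quiet, function(v) all(v == 0), logical(1))))
  # constant sources appear only when the treatment is on
  on <- chemokine_reactions(z, z, z, z, z, z, z, z, z, p, c(1, 0, 1),
                            treatments = list(dnase = TRUE, timp = TRUE,
                                              antibody = TRUE))
  expect_equal(on$D, p$lambda_D * c(1, 0, 1))
  expect_equal(on$M, rep(p$lambda_M, 3))
  expect_equal(on$A, rep(p$lambda_A, 3))
  # NE inhibition sits at half strength when DNase is at its Hill constant
  r1 <- chemokine_reactions(0, 0, 0, 0, 1, p$K_D, 0, 0, 0, p, 1)
  expect_equal(r1$E, -p$mu_E - p$mu_ED / 2, tolerance = 1e-12)
  # well-mixed steady state of NE under constant N2 and no inhibitor
  N2 <- 0.7
  Estar <- p$lambda_E * N2 / p$mu_E
  expect_equal(chemokine_reactions(0, N2, 0, 0, Estar, 0, 0, 0, 0, p, 1)$E, 0,
               tolerance = 1e-12)
  # with no antibody consumption the TGF-beta equation reduces to source/decay
  pa <- scenario_overrides(p, list(mu_AG = 0))
  ga <- chemokine_reactions(1, 0, 0, 2, 0, 0, 0, 0, 5, pa, 1)$G
  g0 <- chemokine_reactions(1, 0, 0, 2, 0, 0, 0, 0, 0, pa, 1)$G
  expect_equal(ga, g0)
})

test_that("kinetics are quasi-positive: no field is driven negative from zero", {
  set.seed(7)
  pt <- scenario_overrides(p, list(lambda_D = 1, lambda_M = 1, lambda_A = 1))
  for (i in 1:50) {
    u <- stats::runif(11, 0, 5)
    nm <- c("n", "N1", "N2", "rho", "C", "G", "E", "D", "P", "M", "A")
    names(u) <- nm
    # rho is the documented exception: its zeroth-order sink has no
    # rho-dependence, which is why the solver clamps it at zero
    for (f in setdiff(nm, "rho")) {
      v <- u; v[f] <- 0
      tr <- tumor_reaction(v["n"], v["E"], v["N1"], pt)
      nr <- neutrophil_reactions(v["N1"], v["N2"], v["G"], pt)
      er <- ecm_decay(v["rho"], v["E"], v["P"], v["n"], pt, 1)
      cr <- chemokine_reactions(v["n"], v["N2"], v["C"], v["G"], v["E"],
                                v["D"], v["P"], v["M"], v["A"], pt, 1,
                                treatments = list(dnase = TRUE, timp = TRUE,
                                                  antibody = TRUE))
      rate_of <- c(n = unname(tr), N1 = unname(nr$N1), N2 = unname(nr$N2),
                   rho = unname(er), C = unname(cr$C), G = unname(cr$G),
                   E = unname(cr$E), D = unname(cr$D), P = unname(cr$P),
                   M = unname(cr$M), A = unname(cr$A))
      expect_gte(rate_of[f], 0)
    }
  }
})

test_that("well-mixed solver reduction matches an independent stiff ODE solve", {
  skip_if_not_installed("deSolve")
  geom <- transwell_geometry(ecm_interval = c(0, 1))
  grid <- build_grid(geom, h = 0.25)
  pz <- scenario_overrides(p, list(
    D_n = 0, D_1 = 0, D_2 = 0, D_C = 0, D_G = 0, D_E = 0, D_P = 0, D_D = 0,
    D_M = 0, D_A = 0, chi_E = 0, chi_rho = 0, chi_1C = 0, chi_2C = 0))
  y0 <- c(n = 0.4, N1 = 0.5, N2 = 0.1, rho = 0.8, C = 0.1, G = 0.2, E = 0.3,
          D = 0.2, P = 0.1, M = 0.3, A = 0.1)
  st <- do.call(new_state, c(list(grid), as.list(y0)))
  tr <- run_simulation(st, 1, pz, solver_config(dt_init = 1e-4, dt_max = 5e-4),
                       treatments = list(dnase = TRUE, timp = TRUE,
                                         antibody = TRUE))
  got <- state_at(tr, 1)[1, ]
  rhs <- function(t, y, pp) {
    with(as.list(y), {
      hE <- E^2 / (pp$k_E^2 + E^2)
      hD <- D^2 / (pp$K_D^2 + D^2)
      hM <- M^2 / (pp$K_M^2 + M^2)
      list(c(
        pp$r * (1 + pp$r_E * hE) * n * (1 - n / pp$n0) - pp$mu_n * N1 * n,
        pp$lambda_1 * N1 - pp$lambda_12 * G * N1,
        pp$lambda_12 * G * N1 + pp$lambda_2 * N2,
        -(pp$mu_rho1 * E + pp$mu_rho2 * P) * n,
        pp$lambda_C * n - pp$mu_C * C,
        pp$lambda_G * n - pp$mu_G * G - pp$mu_AG * A * G,
        pp$lambda_E * N2 - pp$mu_E * E - pp$mu_ED * E * hD,
        pp$lambda_D - pp$mu_D * D,
        pp$lambda_P * N2 - pp$mu_PM * P * hM - pp$mu_P * P,
        pp$lambda_M - pp$mu_M * M,
        pp$lambda_A - pp$mu_A * A))
    })
  }
  ref <- deSolve::ode(y0, c(0, 1), rhs, pz, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(got - ref[2, -1])), 1e-8)
})
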