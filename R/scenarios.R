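#' Build an in-silico transwell experiment
#'
#' Scenario names map onto the wet-lab arms of the invasion assay:
#' \describe{
#'   \item{`control`}{Tumor cells seeded uniformly in the upper chamber
#'     above the ECM layer; plain medium (no neutrophils) in the lower
#'     chamber; no treatment.}
#'   \item{`tan`}{As `control`, plus N1 neutrophils seeded uniformly in the
#'     lower chamber (tumor-associated neutrophil co-culture).}
#'   \item{`tan_dnase`}{`tan` with the DNase I source active on the
#'     injection region (the lower well).}
#'   \item{`ab`}{`tan` with the TGF-beta antibody source active.}
#'   \item{`ab_dnase`}{`tan` with both antibody and DNase I.}
#'   \item{`timp`}{`tan` with the TIMP source active.}
#'   \item{`timp_ab`}{`tan` with TIMP and antibody.}
#'   \item{`cxcl8_ko`}{`tan` with CXCL8 secretion silenced
#'     (`lambda_C = 0`), the full-knockdown comparator.}
#' }
#' All molecular fields start at zero; the ECM starts at `rho0` on the
#' matrix region. The assay endpoint is `t_end = 22` (hours).
#'
#' @param name One of the scenario names above.
#' @param overrides Named parameter overrides applied on top of the
#'   scenario (e.g. `list(r = 1.5)` or `list(lambda_12 = 1.6e-1)`).
#' @param n0_upper,N1_lower,rho0 Initial magnitudes of tumor, N1 and ECM.
#' @param t_end Final time.
#' @param output_times Output schedule; defaults to hourly.
#' @param lambda_A Antibody injection rate used when the antibody arm is
#'   active (dimensionless; the published high dose is 10).
#' @return A list of class `transwell_scenario`.
#' @export
make_scenario <- function(name = c("control", "tan", "tan_dnase", "ab",
                                   "ab_dnase", "timp", "timp_ab",
                                   "cxcl8_ko"),
                          overrides = list(), n0_upper = 1, N1_lower = 1,
                          rho0 = 1, t_end = 22, output_times = NULL,
                          lambda_A = 10) {
  name <- match.arg(name)
  stopifnot(n0_upper >= 0, N1_lower >= 0, rho0 >= 0, t_end >= 0)
  treatments <- list(
    dnase = name %in% c("tan_dnase", "ab_dnase"),
    timp = name %in% c("timp", "timp_ab"),
    antibody = name %in% c("ab", "ab_dnase", "timp_ab")
  )
  ov <- as.list(overrides)
  if (identical(name, "cxcl8_ko")) ov$lambda_C <- 0
  if (treatments$antibody && is.null(ov$lambda_A)) ov$lambda_A <- lambda_A
  if (is.null(output_times)) output_times <- seq(0, t_end, by = min(1, t_end))
  output_times <- sort(unique(c(output_times, t_end)))
  structure(
    list(name = name,
         seed_neutrophils = !identical(name, "control"),
         treatments = treatments,
         overrides = ov,
         n0_upper = n0_upper, N1_lower = N1_lower, rho0 = rho0,
         t_end = t_end, output_times = output_times),
    class = "transwell_scenario"
  )
}

#' @export
print.transwell_scenario <- function(x, ...) {
  on <- names(Filter(isTRUE, x$treatments))
  cat(sprintf("<transwell_scenario> '%s', t_end = %g%s%s\n", x$name, x$t_end,
              if (length(on)) paste0(", treatments: ", paste(on, collapse = "+")) else "",
              if (length(x$overrides)) paste0(", overrides: ",
                paste(names(x$overrides), unlist(x$overrides), sep = "=",
                      collapse = ", ")) else ""))
  invisible(x)
}

#' Initial state of a scenario
#'
#' Tumor cells occupy the part of the upper chamber above the ECM layer;
#' N1 neutrophils (if seeded) fill the lower chamber; the ECM field is
#' `rho0` on the matrix region; every molecular field starts at zero.
#'
#' @param scenario A [make_scenario()].
#' @param grid A [build_grid()] mesh.
#' @return A [new_state()].
#' @export
initial_state <- function(scenario, grid) {
  geom <- grid$geometry
  upper_free <- c(geom$ecm_interval[2], geom$x_max)
  new_state(grid,
            n = scenario$n0_upper * region_mask(grid, upper_free),
            N1 = if (scenario$seed_neutrophils)
              scenario$N1_lower * lower_chamber_mask(grid) else 0,
            rho = scenario$rho0 * region_mask(grid, geom$ecm_interval))
}

#' Run a scenario end to end
#'
#' Builds the initial state, applies the scenario's parameter overrides and
#' treatment switches, and integrates to `t_end`.
#'
#' @param scenario A [make_scenario()].
#' @param p Dimensionless parameters (default
#'   [default_dimensionless_parameters()]).
#' @param geometry A [transwell_geometry()].
#' @param h Cell width.
#' @param cfg A [solver_config()].
#' @param neutrophils_cross Membrane permeability switch for neutrophils.
#' @return A `transwell_trajectory` (with the scenario attached as
#'   attribute `scenario`).
#' @export
run_scenario <- function(scenario, p = default_dimensionless_parameters(),
                         geometry = transwell_geometry(), h = 0.01,
                         cfg = solver_config(), neutrophils_cross = FALSE) {
  stopifnot(inherits(scenario, "transwell_scenario"))
  p <- scenario_overrides(p, scenario$overrides)
  grid <- build_grid(geometry, h)
  st <- initial_state(scenario, grid)
  traj <- run_simulation(st, scenario$output_times, p, cfg,
                         treatments = scenario$treatments,
                         neutrophils_cross = neutrophils_cross)
  attr(traj, "scenario") <- scenario
  attr(traj, "parameters") <- p
  traj
}

#' Chamber-integrated population
#'
#' Midpoint-rule integral `sum(field * mask * h)` of a per-cell field over
#' a masked region.
#'
#' @param field Per-cell values.
#' @param mask 0/1 region indicator (same length).
#' @param h Cell width.
#' @return Scalar integral.
#' @export
integrate_population <- function(field, mask, h) {
  stopifnot(length(field) == length(mask))
  sum(field * mask * h)
}

#' Observable time series of a trajectory
#'
#' Domain-integrated populations of each field (`n_hat`, `N1_hat`, ...,
#' using the midpoint rule), the ECM integral over the matrix region
#' (`rho_hat`), and the invasive tumor population `n_lower` (tumor mass in
#' the lower chamber), at every output time.
#'
#' @param trajectory A `transwell_trajectory`.
#' @return A data frame with one row per output time.
#' @export
observables <- function(trajectory) {
  grid <- trajectory$grid
  h <- grid$h
  low <- lower_chamber_mask(grid)
  smask <- region_mask(grid, grid$geometry$ecm_interval)
  ones <- rep(1, grid$n_cells)
  rows <- lapply(seq_along(trajectory$times), function(i) {
    f <- trajectory$states[[i]]
    data.frame(
      t = trajectory$times[i],
      n_hat = integrate_population(f[, "n"], ones, h),
      N1_hat = integrate_population(f[, "N1"], ones, h),
      N2_hat = integrate_population(f[, "N2"], ones, h),
      rho_hat = integrate_population(f[, "rho"], smask, h),
      C_hat = integrate_population(f[, "C"], ones, h),
      G_hat = integrate_population(f[, "G"], ones, h),
      E_hat = integrate_population(f[, "E"], ones, h),
      D_hat = integrate_population(f[, "D"], ones, h),
      P_hat = integrate_population(f[, "P"], ones, h),
      M_hat = integrate_population(f[, "M"], ones, h),
      A_hat = integrate_population(f[, "A"], ones, h),
      n_lower = integrate_population(f[, "n"], low, h)
    )
  })
  do.call(rbind, rows)
}

#' Signed percent change
#'
#' `100 * (treated - reference) / reference`; negative values are
#' reductions. The percent *reduction* reported for treatments is
#' `-percent_change(...)`.
#'
#' @param treated,reference Scalars; `reference > 0`.
#' @return Signed percent.
#' @export
percent_change <- function(treated, reference) {
  stopifnot(reference > 0)
  100 * (treated - reference) / reference
}

#' TGF-beta dose sweep
#'
#' Runs the neutrophil co-culture scenario with TGF-beta supplied as the
#' independent variable: tumor secretion of TGF-beta is silenced and a
#' uniform exogenous source proportional to the dose level drives the
#' TGF-beta field instead. Reports the invasive tumor population and the
#' N1/N2 populations at the endpoint. At dose zero there is no TGF-beta at
#' all, so the N1 phenotype stays dominant (non-invasive state); high doses
#' drive the N1-to-N2 switch and the invasive state.
#'
#' @param levels Non-negative dose levels.
#' @param source_per_level Supply rate corresponding to one dose unit.
#' @param ... Passed to [run_scenario()].
#' @return Data frame with columns `level`, `n_lower`, `N1_hat`, `N2_hat`.
#' @export
tgfb_sweep <- function(levels, source_per_level = 0.1, ...) {
  stopifnot(all(levels >= 0))
  rows <- lapply(levels, function(lv) {
    sc <- make_scenario("tan", overrides = list(
      lambda_G = 0, g_source = lv * source_per_level))
    obs <- observables(run_scenario(sc, ...))
    tail_row <- obs[nrow(obs), ]
    data.frame(level = lv, n_lower = tail_row$n_lower,
               N1_hat = tail_row$N1_hat, N2_hat = tail_row$N2_hat)
  })
  do.call(rbind, rows)
}

#' Sweep of the N1-to-N2 transition rate
#'
#' Runs the co-culture scenario across a set of `lambda_12` values and
#' reports endpoint observables; larger transition rates produce more N2
#' neutrophils, more NET/NE, and more invasive tumor cells.
#'
#' @param values `lambda_12` values (the published sweep is
#'   `c(1.6e-4, 1.6e-3, 1.6e-2, 1.6e-1)`).
#' @param ... Passed to [run_scenario()].
#' @return Data frame with one row per value.
#' @export
lambda12_sweep <- function(values = c(1.6e-4, 1.6e-3, 1.6e-2, 1.6e-1), ...) {
  rows <- lapply(values, function(v) {
    sc <- make_scenario("tan", overrides = list(lambda_12 = v))
    obs <- observables(run_scenario(sc, ...))
    tail_row <- obs[nrow(obs), ]
    cbind(data.frame(lambda_12 = v), tail_row[, -1])
  })
  do.call(rbind, rows)
}
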