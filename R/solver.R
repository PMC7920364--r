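#' Solver configuration
#'
#' Controls the fractional-step integrator. One macro step of size `dt` is a
#' Strang split: an implicit (damped-Newton, backward-Euler) kinetics half
#' step, an explicit upwind transport step sub-cycled per variable under the
#' CFL restriction `dt_sub <= cfl / (2 D/h^2 + w_max/h)` (with `w_max` the
#' saturated taxis speed), and a second kinetics half step. The macro step
#' adapts to the cost of the nonlinear solves: after `grow_after`
#' consecutive cheap Newton solves it grows by `grow_factor` (capped at
#' `dt_max`); a failed Newton solve rejects the step and halves `dt`, and
#' `dt < dt_min` is a hard failure that reports the time reached.
#'
#' @param dt_init Initial macro step (default `1e-4`).
#' @param dt_min Hard lower bound on the macro step.
#' @param dt_max Upper bound on the macro step; also bounds the splitting
#'   error.
#' @param newton_tol Residual tolerance of the pointwise nonlinear solves.
#' @param newton_maxit Maximum Newton iterations before a step is rejected.
#' @param cfl CFL safety factor of the explicit transport sub-steps.
#' @param grow_after Consecutive cheap solves required before growing `dt`.
#' @param grow_factor Growth multiplier.
#' @param blowup_warn Magnitude above which a field triggers a one-time
#'   warning (the N2 equation is exponentially growing by construction and
#'   is deliberately uncapped).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(dt_init = 1e-4, dt_min = 1e-10, dt_max = 2e-2,
                          newton_tol = 1e-8, newton_maxit = 25, cfl = 0.9,
                          grow_after = 5, grow_factor = 1.5,
                          blowup_warn = 1e6) {
  stopifnot(dt_min > 0, dt_min <= dt_init, dt_init <= dt_max,
            newton_tol > 0, newton_maxit >= 1, cfl > 0, cfl <= 1)
  structure(list(dt_init = dt_init, dt_min = dt_min, dt_max = dt_max,
                 newton_tol = newton_tol, newton_maxit = newton_maxit,
                 cfl = cfl, grow_after = grow_after,
                 grow_factor = grow_factor, blowup_warn = blowup_warn),
            class = "solver_config")
}

#' Construct a model state
#'
#' A state is the eleven per-cell fields at one time: cell densities `n`
#' (tumor), `N1`, `N2` (neutrophil phenotypes), ECM `rho` (zero outside the
#' matrix region), and concentrations `C` (CXCL8), `G` (TGF-beta), `E`
#' (NET/NE), `D` (DNase I), `P` (MMP), `M` (TIMP), `A` (antibody).
#'
#' @param grid A [build_grid()] mesh.
#' @param ... Named per-field initial values: scalars are recycled, vectors
#'   must have length `grid$n_cells`. Unnamed fields start at zero.
#' @param t Initial time (default 0).
#' @return A list of class `transwell_state` with elements `fields` (matrix
#'   `n_cells x 11`), `t` and `grid`.
#' @export
new_state <- function(grid, ..., t = 0) {
  stopifnot(inherits(grid, "transwell_grid"))
  nc <- grid$n_cells
  fields <- matrix(0, nrow = nc, ncol = length(FIELDS),
                   dimnames = list(NULL, FIELDS))
  init <- list(...)
  bad <- setdiff(names(init), FIELDS)
  if (length(bad)) {
    stop("unknown field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(init)) {
    v <- init[[nm]]
    stopifnot(length(v) %in% c(1L, nc))
    fields[, nm] <- v
  }
  if (any(fields < 0)) stop("initial fields must be non-negative", call. = FALSE)
  structure(list(fields = fields, t = t, grid = grid),
            class = "transwell_state")
}

# flatten a parameter_set into the fixed-order vector the C++ core expects
.core_param_vector <- function(p, treatments = list()) {
  lamD <- if (isTRUE(treatments$dnase)) p$lambda_D else 0
  lamM <- if (isTRUE(treatments$timp)) p$lambda_M else 0
  lamA <- if (isTRUE(treatments$antibody)) p$lambda_A else 0
  c(p$D_n, p$D_1, p$D_2, p$D_C, p$D_G, p$D_E, p$D_D, p$D_P, p$D_M, p$D_A,
    p$r, p$r_E, p$k_E, p$m_growth, p$n0, p$mu_n,
    p$lambda_1, p$lambda_12, p$lambda_2,
    p$lambda_C, p$mu_C,
    p$lambda_G, p$mu_G, p$mu_AG, p$g_source,
    p$lambda_E, p$mu_E, p$mu_ED, p$K_D, p$l_hill,
    lamD, p$mu_D,
    p$lambda_P, p$mu_PM, p$K_M, p$m_mmp, p$mu_P,
    lamM, p$mu_M, lamA, p$mu_A,
    p$mu_rho1, p$mu_rho2,
    p$chi_E, p$delta_E, p$sigma_E,
    p$chi_rho, p$delta_rho, p$sigma_rho,
    p$chi_1C, p$delta_1, p$chi_2C, p$delta_2, p$sigma_C)
}

.core_gamma_vector <- function(p, neutrophils_cross = FALSE) {
  g <- permeability_map(p, neutrophils_cross)
  out <- numeric(length(FIELDS))
  names(out) <- FIELDS
  out[names(g)] <- g
  unname(out)
}

#' Advance the state by one fractional step
#'
#' A single Strang-split macro step (see [solver_config()]). Exposed mainly
#' for testing and diagnosis; [run_simulation()] drives the adaptive loop.
#'
#' @param state A [new_state()].
#' @param dt Macro step size.
#' @param p A dimensionless `parameter_set`.
#' @param cfg A [solver_config()].
#' @param treatments List of logical flags `dnase`, `timp`, `antibody`.
#' @param neutrophils_cross Membrane permeability switch for `N1`/`N2`.
#' @return The advanced `transwell_state`.
#' @export
solver_step <- function(state, dt, p, cfg = solver_config(),
                        treatments = list(), neutrophils_cross = FALSE) {
  stopifnot(inherits(state, "transwell_state"), dt > 0)
  grid <- state$grid
  smask <- region_mask(grid, grid$geometry$ecm_interval)
  imask <- region_mask(grid, grid$geometry$injection_interval)
  res <- .core_step(state$fields, dt, .core_param_vector(p, treatments),
                    .core_gamma_vector(p, neutrophils_cross), smask, imask,
                    grid$h, grid$membrane_face_index, cfg$newton_tol,
                    cfg$newton_maxit, cfg$cfl)
  if (!isTRUE(res$ok)) {
    stop("nonlinear kinetics solve failed at t = ", state$t,
         " with dt = ", dt, " (reduce dt)", call. = FALSE)
  }
  st <- state
  st$fields <- res$state
  dimnames(st$fields) <- list(NULL, FIELDS)
  st$t <- state$t + dt
  st
}

#' Run the simulation to a set of output times
#'
#' Drives the adaptive fractional-step loop from the initial state to the
#' last requested output time, snapshotting the state at each output time
#' (steps are clipped to land on them exactly). The model is deterministic:
#' identical inputs give bit-identical trajectories.
#'
#' @inheritParams solver_step
#' @param output_times Increasing times at which to record the state; the
#'   initial time is always included.
#' @return A `transwell_trajectory`: list with `times`, `states` (list of
#'   field matrices), `grid` and solver `stats`.
#' @export
run_simulation <- function(state, output_times, p, cfg = solver_config(),
                           treatments = list(), neutrophils_cross = FALSE) {
  stopifnot(inherits(state, "transwell_state"))
  output_times <- sort(unique(c(state$t, as.numeric(output_times))))
  if (any(output_times < state$t)) {
    stop("output times must not precede the initial time", call. = FALSE)
  }
  grid <- state$grid
  smask <- region_mask(grid, grid$geometry$ecm_interval)
  imask <- region_mask(grid, grid$geometry$injection_interval)
  res <- .core_run(state$fields, state$t, output_times,
                   .core_param_vector(p, treatments),
                   .core_gamma_vector(p, neutrophils_cross), smask, imask,
                   grid$h, grid$membrane_face_index,
                   cfg$dt_init, cfg$dt_min, cfg$dt_max, cfg$newton_tol,
                   cfg$newton_maxit, cfg$cfl, cfg$grow_after,
                   cfg$grow_factor, cfg$blowup_warn)
  if (isTRUE(res$error)) {
    stop("time step collapsed below dt_min at t = ", res$t_reached,
         " after ", res$steps, " steps (", res$rejections, " rejections)",
         call. = FALSE)
  }
  if (isTRUE(res$blowup_warning)) {
    warning("a field exceeded the blow-up guard magnitude ",
            cfg$blowup_warn, call. = FALSE)
  }
  states <- lapply(res$snapshots, function(m) {
    dimnames(m) <- list(NULL, FIELDS)
    m
  })
  structure(list(times = output_times, states = states, grid = grid,
                 stats = list(steps = res$steps,
                              rejections = res$rejections)),
            class = "transwell_trajectory")
}

#' @export
print.transwell_trajectory <- function(x, ...) {
  cat(sprintf("<transwell_trajectory> %d snapshots, t in [%g, %g], %g steps (%g rejections)\n",
              length(x$times), min(x$times), max(x$times),
              x$stats$steps, x$stats$rejections))
  invisible(x)
}

#' Extract the state at a trajectory time
#'
#' @param trajectory A `transwell_trajectory`.
#' @param t A time contained in `trajectory$times`.
#' @return The field matrix at `t`.
#' @export
state_at <- function(trajectory, t) {
  i <- which(abs(trajectory$times - t) <= 1e-9)
  if (length(i) != 1) stop("time ", t, " is not a trajectory output time", call. = FALSE)
  trajectory$states[[i]]
}
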