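#' Finite-volume spatial operators
#'
#' Face-flux builders and the discrete divergence for the uniform
#' cell-centered mesh. Fluxes are vectors of length `n_cells + 1` indexed by
#' face; positive flux points in +x (lower chamber to upper chamber).
#' Exterior faces always carry zero flux (no-flux closure of the chamber
#' walls), and the membrane face is governed by the permeability jump law,
#' not by these operators: [membrane_flux()] supplies that single value.
#'
#' @name transport
NULL

#' Diffusive face flux
#'
#' Two-point flux `-D (u_right - u_left)/h` on interior faces, zero on
#' exterior faces.
#'
#' @param u Per-cell field.
#' @param Dcoef Non-negative diffusivity.
#' @param h Cell width.
#' @return Face flux vector of length `length(u) + 1`.
#' @rdname transport
#' @export
diffusive_flux <- function(u, Dcoef, h) {
  stopifnot(Dcoef >= 0)
  nc <- length(u)
  flux <- numeric(nc + 1)
  flux[2:nc] <- -Dcoef * diff(u) / h
  flux
}

#' Saturating taxis face flux
#'
#' Upwind flux for chemotaxis or haptotaxis with gradient saturation:
#' at each interior face the advective velocity is
#' `w = chi * g / (delta + sigma * |g|)` with `g` the two-point gradient of
#' the attractant `s` across the face, and the flux is `w` times the upwind
#' value of the carried field `u`. For small gradients this reduces to the
#' classical linear taxis flux `chi u g / delta`; for large gradients the
#' speed saturates at `chi/sigma`, which prevents blow-up. A per-cell mask
#' restricts where the flux operates (all ones for chemotaxis, the ECM
#' indicator for haptotaxis); a face is active if the mask is 1 on at least
#' one side, so the faces bounding the closed ECM interval are active and
#' intact matrix exerts its full edge attraction (cells at the gel boundary
#' engage the matrix; this is what makes the undegraded ECM layer a
#' haptotactic barrier that proteolysis must dissolve).
#'
#' @param s Attractant field.
#' @param chi Taxis sensitivity.
#' @param delta Positive saturation scale (units of a gradient).
#' @param sigma Dimensionless saturation weight.
#' @param mask Optional 0/1 per-cell mask.
#' @rdname transport
#' @export
saturating_taxis_flux <- function(u, s, chi, delta, sigma, h, mask = NULL) {
  if (delta <= 0) stop("taxis saturation scale delta must be > 0", call. = FALSE)
  nc <- length(u)
  stopifnot(length(s) == nc)
  flux <- numeric(nc + 1)
  g <- diff(s) / h
  w <- chi * g / (delta + sigma * abs(g))
  up <- ifelse(w > 0, u[-nc], u[-1])
  f <- w * up
  if (!is.null(mask)) f <- f * (mask[-nc] > 0 | mask[-1] > 0)
  flux[2:nc] <- f[seq_len(nc - 1)]
  flux
}

#' Membrane permeability flux
#'
#' Flux across the semi-permeable membrane for one variable:
#' `gamma_u * (u_lower - u_upper)`, positive into the upper chamber. Flux is
#' continuous across the membrane and proportional to the concentration
#' jump; this single value replaces the diffusive and tactic flux at the
#' membrane face. `gamma_u = 0` seals the chambers.
#'
#' @param u_lower,u_upper Field values in the cells adjacent to the
#'   membrane.
#' @param gamma_u Non-negative permeability.
#' @rdname transport
#' @export
membrane_flux <- function(u_lower, u_upper, gamma_u) {
  stopifnot(gamma_u >= 0)
  gamma_u * (u_lower - u_upper)
}

#' Discrete divergence
#'
#' Per-cell rate `-(flux_right - flux_left)/h`. With zero exterior fluxes
#' the rates telescope: total mass `sum(rate) * h` is conserved to machine
#' precision.
#'
#' @param flux Face flux vector (length `n_cells + 1`).
#' @rdname transport
#' @export
divergence <- function(flux, h) {
  -diff(flux) / h
}
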