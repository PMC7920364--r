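#' Pointwise kinetics of the transwell model
#'
#' The non-transport right-hand sides, evaluated elementwise on per-cell
#' fields. These are the reaction terms the fractional-step solver
#' integrates implicitly; they are exposed so each biological process can be
#' inspected and tested in isolation.
#'
#' @name kinetics
NULL

.hill <- function(x, K, m) {
  xm <- x^m
  out <- xm / (K^m + xm)
  out[x <= 0] <- 0
  out
}

#' Tumor cell net production
#'
#' Logistic growth at base rate `r`, boosted by neutrophil elastase through
#' a Hill factor of amplitude `r_E` (half-saturation `k_E`, exponent
#' `m_growth`), minus killing by N1 neutrophils at rate `mu_n`:
#' `r (1 + r_E E^m/(k_E^m + E^m)) n (1 - n/n0) - mu_n N1 n`.
#'
#' @param n,E,N1 Non-negative fields (tumor, NET/NE, N1 neutrophils).
#' @param p A `parameter_set`.
#' @return Rate field, same shape as `n`.
#' @rdname kinetics
#' @export
tumor_reaction <- function(n, E, N1, p) {
  boost <- 1 + p$r_E * .hill(E, p$k_E, p$m_growth)
  p$r * boost * n * (1 - n / p$n0) - p$mu_n * N1 * n
}

#' Neutrophil phenotype kinetics
#'
#' N1 proliferates at `lambda_1` and converts to N2 at rate `lambda_12 * G`
#' (TGF-beta-driven); N2 receives the converts and proliferates at
#' `lambda_2`. The transition term transfers mass exactly: with
#' `lambda_1 = lambda_2 = 0` the two rates sum to zero pointwise.
#'
#' @param N1,N2,G Non-negative fields.
#' @rdname kinetics
#' @return For `neutrophil_reactions`, a list with elements `N1` and `N2`.
#' @export
neutrophil_reactions <- function(N1, N2, G, p) {
  trans <- p$lambda_12 * G * N1
  list(N1 = p$lambda_1 * N1 - trans,
       N2 = trans + p$lambda_2 * N2)
}

#' ECM proteolysis
#'
#' Zeroth-order (in ECM) degradation by NE and MMP wherever tumor cells are
#' present, restricted to the matrix region `S`:
#' `-(mu_rho1 E + mu_rho2 P) n` on `S`, 0 elsewhere. The rate has no
#' intrinsic floor, so the solver clamps the ECM field at zero after each
#' step.
#'
#' @param rho,P Non-negative fields (ECM, MMP).
#' @param S_mask 0/1 indicator of the ECM region.
#' @rdname kinetics
#' @export
ecm_decay <- function(rho, E, P, n, p, S_mask) {
  -(p$mu_rho1 * E + p$mu_rho2 * P) * n * S_mask
}

#' Molecular field kinetics
#'
#' Source/decay terms of the seven molecular fields. Tumor cells secrete
#' CXCL8 and TGF-beta; N2 neutrophils secrete NET/NE and MMP; DNase I, TIMP
#' and the TGF-beta antibody enter as constant sources when the respective
#' treatment is active (DNase I only on the injection region). NE is
#' additionally consumed by DNase I and MMP by TIMP, both through Hill
#' inhibition factors; TGF-beta is consumed by the antibody at rate
#' `mu_AG * A`. `p$g_source` adds an exogenous uniform TGF-beta supply
#' (dose-sweep experiments).
#'
#' @param C,G,D,M,A Non-negative fields (CXCL8, TGF-beta, DNase I, TIMP,
#'   antibody).
#' @param omega_I_mask 0/1 indicator of the DNase injection region.
#' @param treatments List of logical flags `dnase`, `timp`, `antibody`.
#' @rdname kinetics
#' @return For `chemokine_reactions`, a named list of rate fields
#'   `C, G, E, D, P, M, A`.
#' @export
chemokine_reactions <- function(n, N2, C, G, E, D, P, M, A, p, omega_I_mask,
                                treatments = list(dnase = FALSE, timp = FALSE,
                                                  antibody = FALSE)) {
  lamD <- if (isTRUE(treatments$dnase)) p$lambda_D else 0
  lamM <- if (isTRUE(treatments$timp)) p$lambda_M else 0
  lamA <- if (isTRUE(treatments$antibody)) p$lambda_A else 0
  list(
    C = p$lambda_C * n - p$mu_C * C,
    G = p$lambda_G * n - p$mu_G * G - p$mu_AG * A * G + p$g_source,
    E = p$lambda_E * N2 - p$mu_E * E - p$mu_ED * E * .hill(D, p$K_D, p$l_hill),
    D = lamD * omega_I_mask - p$mu_D * D,
    P = p$lambda_P * N2 - p$mu_PM * P * .hill(M, p$K_M, p$m_mmp) - p$mu_P * P,
    M = lamM - p$mu_M * M,
    A = lamA - p$mu_A * A
  )
}
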