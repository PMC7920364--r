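---
title: "A taxis–reaction–diffusion model of neutrophil-assisted tumor invasion in a transwell assay"
author: "transwellsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A taxis-reaction-diffusion model of neutrophil-assisted tumor invasion in a transwell assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transwellsim)
```

## The experiment and the model

A Boyden transwell invasion assay places tumor cells in an upper chamber on
top of a Matrigel-coated, semi-permeable insert, with neutrophils (or plain
medium, the control) in the lower well. Over 22 hours, tumor-associated
neutrophils (TANs) can more than double the number of tumor cells that cross
the insert: tumor-secreted CXCL8 attracts neutrophils to the insert,
tumor-secreted TGF-β converts the anti-tumor N1 phenotype into the
tumor-promoting N2 phenotype, and N2 cells release neutrophil elastase
(NE, carried together with NETs as one field) and MMPs that degrade the
matrix, boost tumor proliferation and guide tumor chemotaxis. DNase I
(digesting NET/NE), TIMP (inhibiting MMP), a TGF-β-neutralizing antibody and
CXCL8 knockdown each cut parts of this loop.

`transwellsim` implements this system as eleven coupled fields on a
one-dimensional domain `[0, 1]`: lower chamber `[0, 0.5)`, upper chamber
`(0.5, 1]`, a zero-thickness semi-permeable membrane at `x = 0.5`, and an
ECM (gel) layer on `S = [0.35, 0.65]`. The fields are tumor density `n`,
neutrophil densities `N1`, `N2`, matrix density `rho` (on `S` only), and the
concentrations `C` (CXCL8), `G` (TGF-β), `E` (NET/NE), `D` (DNase I),
`P` (MMP), `M` (TIMP) and `A` (antibody).

Tumor cells move by random motility, by chemotaxis up NE gradients and by
haptotaxis up matrix gradients, with a gradient-saturating flux

$$ J = -D_n \nabla n
   + \chi_E\, n\, \frac{\nabla E}{\delta_E + \sigma_E |\nabla E|}
   + \chi_\rho\, I_S\, n\, \frac{\nabla \rho}{\delta_\rho + \sigma_\rho |\nabla \rho|}, $$

and proliferate logistically at rate `r`, boosted by NE through a Hill
factor `1 + r_E E^m/(k_E^m + E^m)` and killed by N1 at rate `mu_n N1 n`.
N1 proliferates slowly and converts to N2 at rate `lambda_12 * G`; N2
proliferates and secretes NE and MMP. The matrix obeys the spatially local
law `d rho/dt = -(mu_rho1 E + mu_rho2 P) n` on `S` and is clamped at zero
(the law has no intrinsic floor). The molecular fields diffuse, decay, and
are produced by tumor (`C`, `G`) or N2 (`E`, `P`); DNase I consumes NE and
TIMP consumes MMP through Hill inhibition terms; the antibody consumes
TGF-β bilinearly. The chamber walls are no-flux; at the membrane every
transported variable obeys the jump law `J = gamma_u (u_lower - u_upper)`
with permeability `gamma_c` for cells and `gamma` for molecules.

## Nondimensionalization and the calibrated defaults

The simulator runs in dimensionless form. Two anchors pin the scales
robustly:

* `T_ref = 3600 s`. The dimensionless tumor growth rate then equals
  `3.3e-4 * 3600 = 1.188`, the bottom of the published dimensionless
  growth-rate sweep `[1.2, 1.5]` — strong evidence the model's native time
  unit is one hour, with the assay endpoint at `t = 22`.
* Reference magnitudes of the inhibitor fields equal their Hill constants
  (`D_ref = K_D`, `M_ref = K_M`): the published injection rates then become
  `lambda_D = 1.0125` and `lambda_M = 1.0009` — both almost exactly one,
  which is unlikely to be a coincidence.

The length scale is `L_ref = 2 cm` (chamber depth mapped to the unit
domain). Shorter choices make the logistic tumor front (speed
`2 sqrt(r D_n)` per hour) sweep the whole domain well before 22 h in every
arm, erasing all treatment contrasts; at `L_ref = 2 cm` the control front
reaches the membrane only in the second half of the assay, which is what
the published density profiles show.

All first-order rates, diffusivities, Hill exponents, the NE growth-boost
amplitude and the membrane permeabilities are taken directly from the
published dimensional tables under these scales. The remaining couplings —
taxis sensitivities (printed as velocities whose magnitude, under any scale
consistent with the diffusivities, would render taxis numerically
invisible), the gradient-saturation scales, the secretion rates of `C`,
`G`, `E`, `P`, and the bimolecular couplings `mu_n`, `mu_rho1`, `mu_rho2`,
`mu_AG` (whose reference magnitudes the tables do not determine) — were
calibrated **once** against the published simulation outcomes and then
frozen; they are listed in `?default_dimensionless_parameters`. Two ranged
parameters: `mu_ED` uses the geometric midpoint of its published range;
`mu_PM` uses the upper end of its range, because the midpoint caps the
achievable MMP suppression at ~64% while the reported TIMP effect is an
82% reduction.

The calibrated regime has a definite mechanical anatomy:

* an **N1 killing wall**: CXCL8 chemotaxis piles N1 against the lower face
  of the membrane, where `mu_n` is large enough that nothing crosses until
  TGF-β converts the pile to N2 (8–12 h in co-culture);
* a **haptotactic conveyor**: NE- and MMP-mediated degradation creates
  matrix gradients that pull tumor cells through the gel
  (`chi_rho = 0.085`, with `delta_rho = 5` so that only genuine
  degradation fronts, not noise-level dips, engage the conveyor);
* an **NE growth boost** acting on sub-capacity invaders.

Control lacks all three (no neutrophils), which is what produces the
~2-fold co-culture/control contrast; each treatment removes a subset.

## Numerical scheme

Finite volumes on a uniform mesh (`h = 0.01`, 100 cells; the membrane
coincides exactly with a face). Time stepping is a Strang split:

1. half-step kinetics: pointwise implicit trapezoidal rule solved by a
   damped Newton iteration (analytic 11×11 Jacobian, tolerance `1e-8`);
   second order, so the composition of two consecutive half-steps keeps the
   split second order. `rho` is clamped at zero afterwards.
2. full-step transport: explicit upwind diffusion–taxis fluxes, sub-cycled
   per variable under the positivity-preserving CFL bound
   `dt <= cfl / (2 D / h^2 + w_max / h)` with `w_max` the saturated taxis
   speed. At the membrane face, the discrete flux is *replaced* by the
   permeability jump law, integrated exactly over each sub-step as a
   pairwise exponential relaxation — unconditionally stable, exactly
   conservative, and correct in both limits (`gamma = 0` seals the
   chambers; `gamma -> infinity` reproduces a single-domain solve, which
   the test suite verifies against the closed-form cosine-mode solution).
3. half-step kinetics.

The macro step adapts to the cost of the nonlinear solves (growing 1.5×
after five consecutive cheap solves, halving on failure, hard failure below
`dt_min`), starting from `dt = 1e-4`. Snapshots use dense output (linear
interpolation inside the containing step), so the step sequence never
depends on the output schedule and refining the schedule leaves shared
snapshots bit-identical. The model has no randomness anywhere; every run is
exactly reproducible from its manifest.

Region membership is by cell center; a taxis face is active when at least
one adjacent cell lies in the region. Because the ECM interval is closed,
its boundary faces are therefore active — this matters: with boundary faces
excluded, a spatially uniform intact gel would exert no haptotactic force
at all and proteolysis would have no effect on invasion.

Two departures from the obvious defaults deserve note. First, the membrane
is sealed to both neutrophil phenotypes by default
(`neutrophils_cross = FALSE`): with the published cell permeability the
membrane is effectively transparent, and permeable neutrophils flood the
upper chamber within hours, reversing the NE gradient — the assay schematic
and the published density profiles both show neutrophils confined to the
lower chamber. The flag restores the permeable variant. Second, the TGF-β
dose sweep (`tgfb_sweep()`) silences tumor TGF-β secretion and drives `G`
entirely by the exogenous dose: the published sweep includes dose zero with
an N1-dominant outcome, which is only possible if the dose replaces, rather
than supplements, tumor-derived TGF-β.

## Scenarios and observables

`make_scenario()` builds the experimental arms: `control`, `tan`
(N1 seeded at density 1 in the lower chamber), `tan_dnase`, `ab`
(antibody source at the published high dose `lambda_A = 10`), `ab_dnase`,
`timp`, `timp_ab`, and `cxcl8_ko` (`lambda_C = 0`). Initial data: tumor at
carrying capacity on the upper chamber above the gel, matrix at 1 on `S`,
all molecular fields at zero. Observables are midpoint-rule integrals; the
*invasive* population is tumor mass in the lower chamber at `t = 22`.

```{r example, eval = FALSE}
ctrl <- run_scenario(make_scenario("control"))
tan  <- run_scenario(make_scenario("tan"))
obs  <- observables(tan)
tail(obs[, c("t", "n_hat", "n_lower", "N1_hat", "N2_hat", "E_hat")], 1)
observables(ctrl)$n_lower[23]          # ~0.084
obs$n_lower[23]                        # ~0.146  (~1.7-fold)
```

## What the simulations do and do not show

The model reproduces, at the published grid and endpoint: the ~2-fold
co-culture/control invasion ratio; the ~50% DNase I reduction; the
~62% antibody reduction at growth rate 1.5; the ~82% MMP suppression by
TIMP; the >48% invasiveness drop between the extremes of the N1→N2
transition-rate sweep (monotone across the sweep); and the ~40% NE
reduction under CXCL8 knockdown. Orderings (co-culture above control,
every treatment strictly below its reference, monotone dose responses for
the antibody and the transition rate, the N1→N2 dominance switch across
the TGF-β dose sweep) hold exactly.

Four published quantities are *not* reproduced at this calibration, for
structural reasons worth recording:

* **TIMP's 26% invasion reduction.** MMP has near-zero diffusivity and its
  N2 source can neither cross the membrane nor chemotax away from it, so
  MMP degradation acts entirely below the membrane, where repositioning
  invaders cannot change the lower-chamber count; NE covers every matrix
  region MMP reaches. TIMP's effect on invasion is ~1% (strictly positive,
  so the ordering holds) even though its 75% MMP suppression reproduces.
* **The antibody-alone reduction (36% reported).** Here the antibody acts
  by prolonging the N1 killing wall, and that mechanism is *stronger* at
  the default growth rate than at `r = 1.5` — the reported opposite
  ordering (36% vs 62%) would require the NE growth boost to dominate on a
  sub-capacity tumor, but the upper chamber sits at carrying capacity.
  Consequently the antibody+DNase combination also lands slightly above
  its reported 66%.
* **The >87% TIMP+antibody synergy** cannot exceed antibody-alone by much
  once the TIMP channel is ~0.
* **The ~50% TGF-β drop under CXCL8 knockdown.** Total TGF-β is pinned by
  the (static, capacity-saturated) upper-chamber tumor; the knockdown
  changes it by ~2%, and the small residual is dominated by killing-burn
  timing at the membrane. A sub-capacity growing tumor would be needed.

Two numerical limitations: the logistic invasion fronts have width
`sqrt(D_n/r) ≈ 0.004`, narrower than the published cell size `h = 0.01`,
so front positions (and hence invasive masses) shift by `O(h)` under grid
refinement — all headline numbers are defined at the published grid; and
the taxis speeds of *tumor* cells must remain below `~D_n/h`, because a
stronger pull piles cells above carrying capacity against the membrane
where logistic crowding destroys the excess — neutrophils, which have no
crowding term, are free to pile (that pile *is* the killing wall).

Test-suite problem sizes: unit and property tests use 20–100 cells and
horizons of 1–5 h; the ordering, sweep and endpoint checks run the full
100-cell, 22-h scenarios (a run takes well under a second).
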