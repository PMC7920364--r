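Package: transwellsim
Title: Simulation of Neutrophil-Assisted Tumor Invasion in a Transwell Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of tumor cell invasion through the
    matrix-coated semi-permeable insert of a Boyden transwell chamber,
    driven by tumor-associated neutrophils. The model couples eleven
    taxis-reaction-diffusion fields (tumor cells, N1/N2 neutrophils,
    extracellular matrix, CXCL8, TGF-beta, NET/neutrophil elastase,
    DNase I, MMP, TIMP and a TGF-beta antibody) on a one-dimensional
    two-chamber domain joined by a semi-permeable membrane. A
    finite-volume fractional-step solver with saturating chemotaxis and
    haptotaxis fluxes, implicit pointwise kinetics and adaptive time
    stepping advances the system. Scenario builders reproduce control,
    neutrophil co-culture, DNase I, TIMP, TGF-beta antibody and CXCL8
    knockdown experiments, and observable helpers compute
    chamber-integrated populations, fold-changes and percent reductions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
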