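Package: mesocluster
Title: Thermodynamics and Reaction-Diffusion Stabilization of Mesoscale Solute Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for mesoscale solute-rich clusters
    in small-molecule solutions, the putative precursors of two-step crystal
    nucleation. Fits the osmotic virial expansion to static-light-scattering
    Debye plots and integrates it to the per-molecule excess free energy;
    solves monomer-dimer speciation and fits the dimerization constant to
    concentration-dependent 13C chemical shifts in fast exchange; extracts
    diffusion coefficients from DOSY gradient-attenuation data and propagates
    them between species through Stokes-Einstein inverse-radius scaling;
    solves the steady-state spherical reaction-diffusion model of monomer and
    dimer density fields around a cluster, including the dimer decay length
    and the decay-rate constant implied by the cluster size; and integrates
    the cluster-radius evolution equation to its stable fixed point. A seeded
    synthetic-data module regenerates every data type the pipeline consumes so
    the whole analysis chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
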