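Package: calfluct
Title: Spatial Stochastic Simulation of NCX-Driven Calcium Fluctuations in
    Perisynaptic Astrocytic Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based morphometrics of tripartite-synapse neuropil volumes
    (extracellular-space correction, astrocytic surface-to-volume ratio,
    pre- and postsynaptic astrocytic coverage), a synthetic geometry
    generator emulating electron-microscopy-derived synapse populations,
    Markov kinetic models of the astrocytic glutamate transporter (EAAT)
    and the sodium-calcium exchanger (NCX), a discrete-particle
    reaction-diffusion engine for extracellular glutamate and intracellular
    calcium at microsecond resolution, and the spectral readouts (100-500 Hz
    band power, regression against surface-to-volume ratio, one-way ANOVA)
    used to characterise spontaneous astrocytic calcium fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
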