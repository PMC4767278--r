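Package: wcresonance
Title: Resonance of Delay-Coupled Wilson-Cowan Cortical Sheet Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a patch of cortical sheet as a two-dimensional lattice of
    loosely coupled Wilson-Cowan excitatory/inhibitory neural mass units with
    distance-dependent connectivity, per-edge transmission delays, macrocolumn-
    shared stochastic input, and lateral inhibition of the surround. Provides
    steady-state-drive protocols that probe network resonance with periodic
    pulse-train stimulation over grids of driving frequencies, area-normalized
    power spectra, steady-state evoked response statistics, and bootstrap
    estimates of resonance curves, together with runnable experiments showing
    how resonance frequency falls as activated network size, excitatory node
    degree, and transmission delay grow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
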