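Package: engramnet
Type: Package
Title: Homeostatic Structural Plasticity and Memory Engrams in Recurrent Spiking Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and theory of memory-engram formation by homeostatic
    structural plasticity. Provides a clock-driven simulator of recurrent
    networks of current-based leaky integrate-and-fire neurons whose
    excitatory-to-excitatory wiring is remodelled by calcium-based firing-rate
    homeostasis (growth and random pairing of axonal and dendritic synaptic
    elements), the matching population mean-field theory (Siegert transfer
    function, interspike-interval irregularity, shot-noise calcium statistics,
    rectified-Gaussian element growth rates, Wilson-Cowan rate dynamics with
    plastic connectivity flow), analytic stability tools (line attractor,
    Jacobian eigenstructure, oscillation boundary, critical engram
    connectivity, slow-manifold memory decay time, synaptic turnover), and the
    stimulation and readout protocols used to grow networks, encode engrams by
    conditioning or repeated stimulation, and quantify pattern completion and
    memory decay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
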