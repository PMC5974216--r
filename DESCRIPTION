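Package: lifbench
Title: Dual-Backend Leaky Integrate-and-Fire Simulation and Accuracy Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates networks of leaky integrate-and-fire neurons with
    current-based exponential synapses under two families of numerical
    backends: a high-accuracy reference integrator (exact subthreshold
    propagation with optional off-grid threshold crossing) and an emulation
    of digital neuromorphic hardware (s16.15 fixed-point state, 16-bit
    quantized synaptic weights with a dynamic binary point,
    piecewise-constant-current integration, and 16-slot synaptic delay ring
    buffers with delay extension).  Provides the accuracy statistic suite
    used to cross-validate simulators: single-neuron cross-correlation
    histograms, membrane-potential correlations, accumulated spike-time
    lead/lag and warped RMSE, and network-level distributions of firing
    rates, interspike-interval irregularity and pairwise spike-count
    correlations compared via smoothed-histogram Kullback-Leibler
    divergence.  Includes a ring-buffer weight-scaling bound, a CPU-cycle
    cost model for slowed-down real-time execution, and seeded
    synthetic-network generators for desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
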