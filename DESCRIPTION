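Package: thetacomp
Title: Septo-Hippocampal Circuit Model of Theta Phase Precession and
    Sequence Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a minimal CA1 circuit in which spontaneously active
    interneurons integrate an 8 Hz septal pacemaker drive with spatial input
    from place cells, generating theta phase precession and compressed theta
    sequences. Provides the reduced Adler phase-oscillator analytics (phase
    locking, frequency pulling, closed-form trajectories and the underlying
    phase-response-curve averaging), a seeded leaky integrate-and-fire network
    simulator with conductance synapses, speed-dependence laws, dorsoventral
    parameter sets and perturbation protocols, the measurement pipeline for
    precession frequency and phase-position statistics, and combinatorial
    capacity calculations for constrained place-field maps, cell assemblies
    and phase sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
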