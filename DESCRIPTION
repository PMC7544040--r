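Package: critasync
Title: Tuning Binary Excitatory-Inhibitory Networks from Criticality to
    Asynchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a recurrent network of probabilistic
    binary neurons with excitatory and inhibitory populations. Provides the
    closed-form eigenvalue theory of the random connectivity matrix (outlier
    eigenvalue, bulk spectral radius, crossover of the two along the
    largest-eigenvalue-equals-one boundary), a fast simulator of the
    discrete-time probabilistic dynamics, branching-function analysis
    (empirical and semi-analytic), neuronal avalanche detection with
    power-law deviation statistics (kappa) and discrete maximum-likelihood
    exponent fits, and excitation-inhibition balance diagnostics (E/I
    tension, input cross-correlograms, asynchrony index, inter-spike-interval
    coefficient of variation). Includes parameter-sweep drivers that map the
    synchronous-to-asynchronous continuum along the critical boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
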