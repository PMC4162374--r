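Package: hetnet
Title: Heterogeneous Sparse Excitatory-Inhibitory Spiking Networks and
    Their Mean-Field Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sparse networks of leaky integrate-and-fire neurons
    with excitatory and inhibitory populations whose firing thresholds are
    drawn from population-specific Gaussian distributions (quenched
    heterogeneity), and solves the matching diffusion-approximation
    mean-field theory. Provides the Siegert first-passage transfer
    function, Gauss-Hermite averaging over threshold heterogeneity,
    self-consistent excitatory/inhibitory fixed points and f-I curves;
    analyses of divisive gain control by inhibitory heterogeneity,
    synchronization onset and phase diagrams, and transmission of slow
    sinusoidal signals measured by the zero-lag input-output covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    Matrix,
    methods,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
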