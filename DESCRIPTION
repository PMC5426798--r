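Package: eicorr
Title: Correlation-Firing Rate Relationships in Recurrent
    Excitatory-Inhibitory Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for asking when pairwise spike-count correlations
    increase with firing rate in recurrent excitatory-inhibitory networks
    of conductance-based leaky integrate-and-fire neurons.  Provides a
    synthetic network generator with heterogeneous spiking thresholds, a
    fast Euler-Maruyama Monte-Carlo simulator, a Fokker-Planck threshold
    integration engine for single-cell rates, spectra and susceptibilities,
    a linear-response prediction of the full cross-spectral matrix, a
    graph-motif decomposition of predicted correlations, correlation
    susceptibility analysis, and a shifted rank-one approximation of the
    correlation matrix.  Pair- and cell-level results are returned as
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
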