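Package: tdanet
Title: Topological Analysis of Spectral Dependence Networks in Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the topology of frequency-specific dependence
    networks estimated from multichannel time series such as EEG. Simulates
    mixtures of latent AR(2) oscillators with controllable spectral peaks and
    sensor noise, estimates band-limited coherence from the smoothed
    periodogram and converts it to a dependence distance, computes persistent
    homology of the resulting weighted network via the Vietoris-Rips clique
    filtration (boundary-matrix reduction over GF(2)), summarises diagrams as
    persistence landscapes with means and L2 norms, and tests for group-level
    topological differences with a permutation test on a landscape discrepancy
    statistic. Also provides sub-level-set persistence of smoothed univariate
    series and time-delay embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
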