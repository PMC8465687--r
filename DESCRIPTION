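Package: netgc
Title: Granger Causality Between Time Series of Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Granger causality between time series of networks. Each
    graph in a series is summarised by a scalar feature (the spectral radius
    of its adjacency matrix, or a mean centrality), the resulting feature
    series are modelled with a vector autoregression fitted by ordinary
    least squares, and directed non-causality is tested with a Wald
    chi-squared test or a residual-resampling parametric bootstrap. Includes
    generators for five classical random graph families (Erdos-Renyi,
    geometric, regular, Watts-Strogatz, Barabasi-Albert) with known
    spectral-radius forms, a latent-VAR simulation framework for type-I
    error and power studies, and a front-end that builds time-varying
    Pearson correlation graphs from multivariate signals such as fMRI
    region time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
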