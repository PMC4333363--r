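Package: hospwait
Title: Agent-Based Simulation of Hospital Choice and Surgical Wait-Time Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A discrete-time, agent-based simulator of regional surgical
    service utilization. Patients generated in cities choose among hospitals
    using gravity-style selection rules driven by driving time, physician
    supply, and periodically released median wait times; hospitals serve
    priority queues with adaptive daily service rates. The package provides
    the statistical machinery used to detect self-organized regularities in
    the resulting wait-time series: range-normalized variation series,
    continuous power-law fitting by maximum likelihood with
    Kolmogorov-Smirnov cutoff selection and semiparametric bootstrap
    goodness-of-fit, a Monte-Carlo Lilliefors normality test,
    Kullback-Leibler divergence between binned samples, Gini coefficients,
    and regional flow-share error metrics. A synthetic calibration generator
    produces Ontario-like city/hospital bundles so the full pipeline runs
    without any proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nortest
Config/testthat/edition: 3
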