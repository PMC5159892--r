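Package: gpgrowth
Title: Nonparametric Inference of Time Derivatives and Growth Rates with
    Gaussian Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a smooth latent function together with its first and
    second time derivatives from noisy time-series data using Gaussian-process
    regression with analytic derivative covariances.  Designed for microbial
    growth curves from plate readers: replicates are pooled, measurement noise
    may be constant or empirically estimated from the across-replicate
    variance, and summary statistics of growth (maximum specific growth rate,
    lag time, doubling time) are reported with sampling-based error estimates.
    Includes a synthetic growth-curve generator (weighted Gompertz plus
    Richards models with multiplicative log-normal noise) and a smoothing
    spline baseline for benchmarking derivative inference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
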