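Package: monotonet
Title: Signed Regulatory Network Inference from Time Series Under
    Monotone ODE Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed (positive/negative) direct causal regulations
    among observed components of a dynamical system from multiple
    time-series replicates, assuming only that the dynamics follow a
    general monotonic ordinary differential equation model. Provides
    regulation-detection regions, functions and scores computed over
    ordered time-point pairs, total regulation scores with noise-adaptive
    thresholds, a regulation-delta test for ineffective components, and a
    surrogate-shuffle test (one-tailed Z tests combined by Fisher's
    method) to separate direct from chain-induced indirect regulation.
    Ships a monotone-network ODE simulator (driven inputs, Hill and
    linear kinetics, multiplicative measurement noise) so the full
    pipeline is testable without external data, together with time-series
    preprocessing (Fourier/spline fitting, differentiation, period
    estimation, moving-window segmentation) and F-beta network
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
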