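Package: cueabc
Title: Approximate Bayesian Computation for Cue-Based Retrieval Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates retrieval latency and accuracy in a simplified
    cue-based (ACT-R style) model of memory retrieval during sentence
    processing, and estimates the model's latency factor from observed
    reading-time interference effects by Approximate Bayesian Computation
    with rejection sampling. Provides activation, spreading-activation,
    mismatch-penalty and latency computations; a Monte-Carlo simulator of
    mean interference effects for two-condition designs; a Beta-prior
    rejection sampler with a one-standard-deviation acceptance band; prior
    and posterior predictive distributions of the predicted effect; and
    packaged fixtures for classic agreement and reflexive interference
    targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
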