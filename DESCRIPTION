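Package: btsforecast
Title: Hybrid Ensemble Forecasting of DNA-Derived Biological Time Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Treats DNA sequences as time series ("biological time sequences")
    and forecasts them with a hybrid ensemble: spectral, chaos-game (CGR) and
    Z-curve numerical encoders; windowing, chronological splitting and
    normalization; a single-sequence ARFIMA branch with fractional
    differencing and particle-swarm order search; a multi-sequence
    one-dimensional convolutional LSTM branch with self-adaptive per-channel
    pre-training and particle-swarm hyperparameter search; convex fusion of
    the two branches with validation-learned weights; and an evaluation suite
    (MAPE, squared correlation, accuracy growth rate, Diebold-Mariano test,
    residual-variance stability). Includes synthetic DNA and ARFIMA
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
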