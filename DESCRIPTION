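Package: dreamHF
Title: Process-Mining and Decay-Replay Prediction of Unplanned 30-Day
    Readmission for ICU Heart-Failure Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts MIMIC-III-shaped electronic health records of heart
    failure (HF) intensive-care patients into timestamped clinical event
    logs, discovers a Petri-net careflow model, replays each patient's
    history with per-place linear decay functions (Decay Replay Mining) to
    obtain Timed State Samples at the index discharge, and feeds these
    together with demographics and Charlson/Elixhauser severity scores to a
    three-branch neural network that predicts unplanned 30-day readmission.
    Includes a synthetic EHR generator with a configurable latent
    readmission mechanism, classical machine-learning baselines in both
    tabular and timed-state input modes, DeLong confidence intervals for
    the AUROC, grouped Monte-Carlo Shapley attribution, and variable/layer
    ablation drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pROC,
    e1071,
    class,
    rpart,
    ranger,
    xgboost,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
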