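Package: slimpae
Title: Short Linear Motif Discovery from AlphaFold Binary-Complex Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening candidate short linear motifs (SLiMs) with
    AlphaFold binary-complex predictions. Parses ColabFold (AlphaFold2) score
    files and AlphaFold3 server bundles into a common prediction record;
    computes interface-confidence metrics (Model Confidence, MiniPAE,
    per-residue minimum inter-chain PAE, AlphaSLiM); localizes candidate
    motifs from per-residue profiles; calibrates a screen-size-dependent
    MiniPAE threshold by subsampling non-binder pools and fitting a power
    law; and evaluates screening performance with ROC and precision-recall
    analysis under class imbalance, including shuffled-negative benchmark
    construction. A synthetic-fixture generator emulates AlphaFold outputs
    with planted interface signals so the whole pipeline is testable without
    any structure-prediction run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    bio3d,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
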