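Package: contextpriors
Title: Contextual Expectation Models and Late-Fusion Augmentation of Object Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring, modelling and exploiting human contextual
    expectations about objects in scenes that do not contain them. Implements
    linear expectation models for object likelihood, location, scale and aspect
    ratio built from three per-scene feature channels (target-detector
    summaries, binary nontarget-object labels, and coarse scene features),
    channel-wise principal-component complexity equalization, cross-validated
    model comparison over resampled scene splits, split-half noise ceilings
    with the Spearman-Brown correction, late fusion of predicted priors with
    detector confidence scores via cross-validated linear discriminant
    analysis, ROC analysis, and co-occurrence (association-index) transfer
    analysis. Includes a synthetic-data module that generates behavioural
    rating tables and evaluation sets with known ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
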