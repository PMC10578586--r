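Package: colonyevo
Title: Colony Surface Competition, Regulon Activity, and Outline Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study bacterial surface competition under edge-transfer
    serial passaging. Provides a radial reaction-diffusion simulator of colony
    growth, sporulation and genotype competition; regulator-activity inference
    from colony transcriptomes with coactivation and activity-module detection;
    a differential-expression, enrichment, PCA and self-organizing-map analysis
    of expression profiles with operon-coherence statistics; a colony-outline
    image pipeline with sigmoid inflection-point boundary refinement; and a
    fully seeded synthetic-data generator (regulon-structured counts, cell-type
    composition tables, shaded colony images) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    cluster,
    minpack.lm,
    EBImage,
    png,
    tiff,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
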