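Package: geocurate
Title: Role-Based Annotation and Quality Control of Gene-Expression Series Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curation pipeline for gene-expression series metadata in the
    style of the Gene Expression Omnibus (GEO). A set of cooperating
    annotator roles (original annotator, result checker, prompt optimizer,
    optimal annotator, quality controller) turns free-text series and
    sample descriptions into structured control-versus-perturbation
    annotations. A deterministic rule engine enforces three quality
    criteria (characteristic alignment with sex and age ignored, grouping
    uniformity, correct perturbation assignment); consistency between two
    quality-control channels, annotation pass rate and dataset pass rate
    summarise a run. A prompt-optimization loop trains the annotator
    against a gold standard. Downstream, quality-passed annotations yield
    differential-expression signatures whose rank correlation against a
    signature library, with permutation p-values and Benjamini-Hochberg
    q-values, ranks drug-repurposing candidates. A deterministic mock
    backend and a synthetic corpus generator with labelled error injection
    make the whole pipeline runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
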