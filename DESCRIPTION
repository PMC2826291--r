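Package: spatzone
Title: Spatiotemporal Zoning of Outbreak News Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data model, validator and tooling for spatiotemporal zoning of
    disease-outbreak news reports. Event-predicates (clause-level events) are
    annotated with one of four event classes, day-granularity temporal
    attributes anchored to a reference date, and surface-form location
    attributes; consecutive attribute-compatible predicates are merged into
    zones. The package provides the annotation XML dialect reader/writer,
    ISO 8601 temporal-expression normalization, the zone-boundary generation
    algorithm, an inter-annotator agreement suite (Cohen's kappa, percentage
    agreement under exact and gazetteer-based approximate spatial
    comparators, per-class stratification), and a synthetic corpus and
    annotator-noise simulator for scheme-reliability experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
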