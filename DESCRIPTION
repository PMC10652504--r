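Package: acmgrules
Title: Deterministic ACMG/AMP Sequence-Variant Classification Engine
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable rules engine for constitutional
    sequence-variant classification under laboratory-modulated ACMG/AMP
    criteria. Evaluates population-frequency, molecular, case-level,
    in-silico and functional criteria with per-criterion strength
    modulation, resolves mutually exclusive evidence, applies the
    enumerated combining rules for the five-tier classification, and
    computes a Bayesian posterior probability of pathogenicity from
    exponentially scaled odds. Evidence arrives pre-annotated as JSON,
    TSV or minimally annotated VCF; every decision is recorded in a
    per-variant audit trail.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
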