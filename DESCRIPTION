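Package: collabnet
Title: Development of Interprofessional Collaboration Networks from
    Two-Round Ego-Nomination Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to measure the development of interprofessional
    collaboration networks in community health care districts from
    two-round ego-nomination surveys administered before and after an
    intervention.  Covers roster construction under a snowball plus
    fixed-list network boundary, classification of professionals into
    rings (program participants, consented responders, nominated
    non-responders with missing outgoing ties), assembly of directed
    valued collaboration networks, a metric suite (out-degree, density,
    dyadic reciprocity, per-ring E-I index, a discipline-diversity index,
    and tie value), paired pre/post comparison with t tests, a synthetic
    two-timepoint cohort generator with a spill-over effect, sociogram
    rendering, and readers/writers for standard network file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
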