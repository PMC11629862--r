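Package: replimet
Title: Replication-Driven Gene Dosage, Metabolite Homeostasis and the
    Evolution of Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links bacterial chromosome replication to metabolic
    homeostasis and gene order. Implements locus copy-number arithmetic
    under the Helmstetter-Cooper model (average population copies and
    per-cell fork counts), metabolic control analysis response formulas
    (flux amplification, metabolite response, replication-coupled flux
    response), a linlog metabolic model engine with an analytic steady
    state and a packaged 34-reaction central-carbon fixture, optimization
    of gene positions and promoter strengths under a coefficient-of-
    variation homeostasis objective, a population simulation of gene-order
    evolution by inversions and translocations with fitness-proportional
    selection, and genomic statistics (proximity score of functional
    modules, peak-to-trough coverage ratio) together with synthetic-data
    generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
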