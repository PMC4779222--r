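Package: gutdiverge
Title: Cross-Species Comparison of Nematode Intestinal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls tissue-enriched genes from paired tissue/whole-animal
    RNA-seq libraries in two nematode species and quantifies how conserved
    the resulting intestinal transcriptomes are at three levels: single
    one-to-one orthologous genes, protein-domain gene families, and
    functional gene sets (GO terms, cross-study comparisons, and
    pathogen-response overlaps). The core statistic is a numerically stable
    one-sided hypergeometric (Fisher) overlap test computed in log space.
    Ships a synthetic two-species RNA-seq count generator with planted
    ground truth (orthologous cores, power-law gene families, log-normal
    expression, Poisson counts, tunable cross-species conservation and
    pathogen-response coupling) so that every pipeline stage is testable
    without external downloads, plus an end-to-end pipeline that produces
    the figure- and table-shaped reports of a two-species comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
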