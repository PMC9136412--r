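Package: conglutinr
Title: Conglutin Isoform Discovery, Marker-Peptide Selection and Relative
    Quantitation for Narrow-Leafed Lupin
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-guided discovery and structural classification of
    conglutin seed-storage-protein isoforms in narrow-leafed lupin protein
    databases, peptide-level conservation mapping across accessions,
    rule-based selection of marker peptides for multiple reaction monitoring
    (MRM) assays, and batch-corrected relative quantitation with family-level
    aggregation and multivariate summaries. Includes a synthetic-data
    generator that emulates every input of the pipeline with known ground
    truth, so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
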