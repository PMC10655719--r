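Package: tmtpolish
Title: Differential Abundance for Isobaric-Label Proteomics and
    Phosphoproteomics with Splicing-Event Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a complete differential-abundance workflow for
    single-plex tandem-mass-tag (TMT) proteomics and phosphoproteomics:
    collapse of peptide-spectrum matches (PSMs) to peptide ions by maximum
    reporter-ion intensity, global median normalization of log2 intensities
    under an equal-loading assumption, Tukey median-polish summarization of
    peptides to proteins, feature-wise fixed-effects linear models with
    pooled-variance contrasts against a designated reference condition,
    Benjamini-Hochberg false-discovery-rate control, and normalization of
    phosphopeptide fold changes to their parent protein's fold change so
    that site-level regulation is separated from abundance change.  Also
    provides a counter for significant local splice variations (LSVs) from
    delta-PSI posterior tables, and a synthetic-data generator with known
    ground truth so every stage can be validated without raw
    mass-spectrometry or RNA-seq data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
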