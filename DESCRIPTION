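Package: dielcross
Title: Crosstalk Between Drought Response and Diurnal Rhythm in
    Transcriptome Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes that are both stress-responsive and
    diurnally rhythmic from gene-by-sample expression matrices, following
    the meta-expression workflow used for rice leaf transcriptomes:
    log2 normalization, per-replicate stress-versus-MOCK fold changes,
    K-means classification of drought up-/down-regulated genes, clustering
    of field-grown diurnal time courses with cosinor rhythmicity scoring
    and peak phase-window assignment (predawn, midday, lateday, midnight),
    crosstalk summaries, hypergeometric term enrichment with a fold-change
    filter, confidence-weighted pathway interaction networks scored by
    Pearson correlation with transcription-factor regulon overlays, and
    comparative-Ct (2^-ddCt) relative quantification with Welch tests.
    A synthetic-data module generates stress series and diurnal courses
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
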