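Package: fusiontriage
Title: Filtering, Prioritization and Annotation of Candidate Fusion Transcripts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Triage of fusion-transcript candidates reported by RNA-seq fusion
    callers in acute leukemia cohorts. Reads ChimeraScan- and deFuse-style
    candidate tables, applies a transparent filter cascade (split-read support,
    partner annotation, healthy-panel contamination, structural reliability,
    promiscuous partners, read-through artifacts, cohort recurrence), checks
    concordance of surviving fusions against ISCN karyotypes, and assigns a
    three-tier priority: cytogenetically concordant events (tier 1), high
    driver-score cryptic events (tier 2), and out-of-frame fusions rescued
    because a tumor suppressor gene is involved (tier 3). Each fusion is
    annotated with reading frame at the chimeric junction, partner orientation,
    alternative acceptor-exon splicing isoforms, fusion-protein extent,
    junction microhomology, and, for intrachromosomal flanking-gene fusions,
    the implied interstitial copy-number loss. Includes a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
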