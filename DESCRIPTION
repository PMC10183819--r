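Package: promarch
Title: Promoter Architecture Analysis of Focused and Dispersed Transcription Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to distinguish developmental (focused-initiation) from
    housekeeping (dispersed-initiation) core promoters from 5'-end tag data.
    Implements CAGE-based correction of annotated transcription start sites,
    positional PWM scoring and classification of core promoter motifs
    (TATA-box, INR, DPE, TCT, DRE, Ohler1/6/7), initiation-shape statistics
    (dominant TSS, dominant fraction, activated-TSS count, initiation width),
    +1 nucleosome calling from MNase fragment centers with CAGE x MNase
    cross-correlation, and spike-in-normalized differential analysis of
    nascent-transcription (PRO-seq) counts under factor depletion, including
    an exact conditional test, motif enrichment, and ChIP signal z-scores.
    A deterministic seeded simulator generates genomes, promoters, CAGE,
    MNase and PRO-seq style data with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
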