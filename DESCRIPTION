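Package: protomotif
Title: Protein-Coding Signal Detection from Accumulated Low-Score
    Translated Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects putative protein-coding regions in genomic sequence by
    accumulating low bit-score translated-alignment hits ("protomotifs")
    into per-strand depth profiles and calling intervals whose peak
    protomotif accumulation exceeds a peak-height threshold.  Includes
    readers and writers for FASTA, GFF3, BLAST tabular, BED6 and bedGraph;
    an evaluator that scores called coding-signals against a reference
    annotation with a reciprocal 20 percent overlap rule (precision,
    recall, threshold sweeps, peak-height binning, reading-frame
    distributions); negative controls (sequence reversal and
    composition-preserving shuffles); and a self-contained synthetic
    fixture generator (genome with planted open reading frames, truth
    annotation, simulated hit reports).  An optional wrapper drives a
    local NCBI BLAST+ translated search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    withr,
    optparse
Config/testthat/edition: 3
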