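Package: retdup
Title: Simulation and Detection of Transposon-Induced Tandem Direct Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-level tools for studying tandem direct duplications and
    reciprocal deletions generated by reversed-ends transposition (RET) of
    hAT-family DNA transposons such as maize Ac/Ds. Provides an executable
    model of standard cut-and-paste transposition, excision with footprints,
    and reversed-ends transposition on annotated chromatids; a genome scanner
    that locates hAT-family element copies, compares their flanking sequences,
    and classifies candidate tandem duplications by their target-site
    duplication signature (RET-consistent versus NAHR-like); a synthetic
    genome generator that plants RET duplications, NAHR decoys, excised
    junctions and ordinary insertions with a machine-readable truth manifest;
    and in-silico molecular diagnostics (junction PCR, excision PCR, virtual
    restriction digest with probe hybridisation, and paralog copy ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
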