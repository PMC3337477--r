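Package: readthrough
Title: Detection of 3' Read-Through Transcripts, pri-miRNA Remnants, and
    Differentially Methylated Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Strand-specific quantification of fixed-length genomic windows
    downstream of annotated gene 3' ends, with a four-parameter filter
    (fold change, mutant RPKM, t-test P-value, non-pri-miRNA) to call
    candidate 3' transcript extensions that accumulate when 5'-3'
    exoribonucleolytic surveillance is impaired. Also quantifies pri-miRNA
    3'-remnant windows and miRNA-target cleavage-fragment windows, calls
    differentially methylated regions from per-cytosine bisulfite calls
    (100-bp window scan, Kruskal-Wallis test, Fisher combination of joined
    windows, Benjamini-Hochberg correction, methylation-density fold
    filter), and integrates the resulting interval sets with strand-aware
    overlap analysis. Includes a seeded synthetic-data generator that
    plants extension, remnant, and DMR signals so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
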