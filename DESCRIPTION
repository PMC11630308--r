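Package: denovoscan
Title: Identification and Characterization of De Novo Genes from Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for calling de novo genes in a focal genome
    by comparison against annotated in-group and out-group relative genomes.
    Candidate genes without protein-level homologs in any relative are mapped
    at the DNA level onto relative genomes; candidates whose loci are
    noncoding in at least one in-group and one out-group genome are called
    putative de novo genes, screened against unannotated open reading frames,
    and classified by origin (entirely noncoding, or chimeric with fragments
    of pre-existing genes or transposable elements). Downstream modules
    characterize the calls: structural and codon-usage features (GC by codon
    position, frequency of optimal codons), an intrinsic-disorder proxy,
    expression level and breadth from an FPKM matrix, promoter cis-regulatory
    binding-site scanning with a confidence-interval exceedance test, GO
    enrichment of flanking genes, weighted co-expression module detection,
    and QTL interval overlap. A seeded synthetic-genome generator plants
    known gene classes with a truth table so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
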