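Package: mapsr
Title: Tunable mRNA Transcript Assembly for Proteogenomic Microprotein Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-guided assembly of spliced RNA-Seq alignments into a
    diverse, stringency-tunable set of transcripts intended for downstream
    shotgun-proteomics database searching (the MAPS strategy). Reads are
    tallied into junctions and candidate exons, chained greedily by read
    support and junction distance, translated in three frames with
    consensus (SNP-aware) sequence correction and open-reading-frame
    extension to the nearest in-frame stop codon, and the resulting
    microprotein candidates are annotated by start-codon class and small-ORF
    status. Includes an exon-overlap assembler evaluation against a
    reference annotation and a spliced-read simulator that plants SNPs and
    small ORFs for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
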