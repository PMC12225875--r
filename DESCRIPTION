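Package: toxinloss
Title: Multi-Evidence Calling of Toxin Gene Loss in Paralogous Venom Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls presence, absence and inactivation mechanism (whole-gene
    deletion, chimeric gene fusion, frameshift disruption) of individual toxin
    genes within highly similar gene families, per specimen, by integrating
    three evidence layers: exclusive-unique peptide counts and protease-domain
    coverage from venom proteomics; full-length transcript support from
    short-read coverage gaps (with mappability masking), exon tiling of
    assembled transcript fragments and clustered long-read isoforms; and
    genomic state from targeted-capture coverage ratios and exon-level
    annotation of assembled contigs. Tests geographic association of gene loss
    with a continuity-corrected chi-squared statistic. Includes a synthetic
    data generator that emulates a rattlesnake venom metalloproteinase (SVMP)
    gene complex, with near-identical paralog segments, gene deletions,
    fusions and frameshifted alleles, for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
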