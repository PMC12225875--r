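# Shared fixtures. The default simulated study is expensive enough to build
# once per test run and reuse read-only.

.fixtures <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- simulate_study(simulation_config())
  .fixtures$bundle
}

# specimen ids by genotype class from a bundle
specimens_of_class <- function(bundle, cls) {
  ids <- vapply(bundle$genotypes, `[[`, character(1), "specimen_id")
  ids[vapply(bundle$genotypes, `[[`, character(1), "genotype_class") == cls]
}

# a BED12-style one-row data.frame
bed_row <- function(name, blocks, chrom = "chr") {
  df <- data.frame(chrom = chrom, start = blocks$start[1],
                   end = blocks$end[nrow(blocks)], name = name,
                   stringsAsFactors = FALSE)
  df$blocks <- list(blocks)
  df
}

iv <- function(start, end) data.frame(start = as.integer(start),
                                      end = as.integer(end))

# a toy single-exon gene model whose whole protein is one domain
toy_gene <- function(protein, gene_id = "G1",
                     domain = "metalloproteinase") {
  nt <- aa_to_nt(protein)
  structure(list(
    gene_id = gene_id, klass = "P1",
    locus_interval = c(0L, nchar(nt)),
    exons = data.frame(exon_index = 1L, start = 0L, end = nchar(nt),
                       domain_label = domain, stringsAsFactors = FALSE),
    transcript_seq = nt, protein_seq = protein, abundance_tpm = 1000
  ), class = "GeneModel")
}
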