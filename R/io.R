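# File-format boundary. Internally everything is 0-based half-open on the
# forward strand; GFF3 (1-based closed) and BED/bedGraph conventions are
# converted here and only here. All formats are plain text.

#' @noRd
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# family reference ----------------------------------------------------------

write_family <- function(family, dir) {
  ref_path <- file.path(dir, "reference.fasta")
  write_fasta(c(family_ref = family$reference_seq), ref_path)

  rows <- list()
  for (gid in names(family$genes)) {
    g <- family$genes[[gid]]
    rows[[length(rows) + 1L]] <- data.frame(
      start = g$locus_interval[1] + 1L, end = g$locus_interval[2],
      type = "gene", ID = gid, Parent = NA_character_,
      klass = g$klass, exon_index = NA_integer_,
      domain_label = NA_character_,
      abundance_tpm = g$abundance_tpm,
      role = if (identical(gid, family$control_gene_id)) "control"
             else if (identical(gid, family$target_gene_id)) "target"
             else NA_character_,
      partner_gene_id = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      start = g$exons$start + 1L, end = g$exons$end,
      type = "exon", ID = paste0(gid, ".exon", g$exons$exon_index),
      Parent = gid, klass = NA_character_,
      exon_index = g$exons$exon_index, domain_label = g$exons$domain_label,
      abundance_tpm = NA_real_, role = NA_character_,
      partner_gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  hr <- family$hard_regions
  if (nrow(hr) > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      start = hr$start + 1L, end = hr$end, type = "biological_region",
      ID = paste0("hard_region_", seq_len(nrow(hr))),
      Parent = hr$gene_id, klass = NA_character_,
      exon_index = hr$exon_index, domain_label = NA_character_,
      abundance_tpm = NA_real_, role = "hard_region",
      partner_gene_id = hr$partner_gene_id, stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges("family_ref",
                               IRanges::IRanges(tab$start, tab$end),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "toxinloss", type = tab$type, ID = tab$ID, Parent = tab$Parent,
    klass = tab$klass, exon_index = tab$exon_index,
    domain_label = tab$domain_label, abundance_tpm = tab$abundance_tpm,
    role = tab$role, partner_gene_id = tab$partner_gene_id)
  gff_path <- file.path(dir, "genes.gff3")
  rtracklayer::export(gr, gff_path, format = "gff3")
  c(reference = ref_path, gff = gff_path)
}

#' Read a family reference from FASTA + GFF3
#'
#' Reconstructs the `FamilyReference` structure from the reference sequence
#' and gene models written by [simulate_study()] (or any GFF3 following the
#' same attribute conventions: exon features carry `exon_index` and
#' `domain_label`; gene features carry `klass` and optionally
#' `role=target|control`; hard regions are `biological_region` features).
#'
#' @param reference_fasta,gff3 File paths.
#' @return A `FamilyReference`.
#' @export
read_family <- function(reference_fasta, gff3) {
  ref <- read_fasta(reference_fasta)[[1]]
  gr <- rtracklayer::import(gff3, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  first_chr <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v)[1] else NA_character_, character(1))
  parent <- if (is(mc$Parent, "List")) first_chr(mc$Parent) else
    as.character(mc$Parent)
  is_gene <- mc$type == "gene"
  genes <- list()
  target_id <- NA_character_; control_id <- NA_character_
  for (i in which(is_gene)) {
    gid <- as.character(mc$ID[i])
    exi <- which(mc$type == "exon" & parent == gid)
    exi <- exi[order(as.integer(mc$exon_index[exi]))]
    ex <- data.frame(exon_index = as.integer(mc$exon_index[exi]),
                     start = BiocGenerics::start(gr)[exi] - 1L,
                     end = BiocGenerics::end(gr)[exi],
                     domain_label = as.character(mc$domain_label[exi]),
                     stringsAsFactors = FALSE)
    tx <- paste(substring(ref, ex$start + 1L, ex$end), collapse = "")
    role <- as.character(mc$role[i])
    if (!is.na(role) && role == "target") target_id <- gid
    if (!is.na(role) && role == "control") control_id <- gid
    genes[[gid]] <- structure(list(
      gene_id = gid, klass = as.character(mc$klass[i]),
      locus_interval = c(BiocGenerics::start(gr)[i] - 1L,
                         BiocGenerics::end(gr)[i]),
      exons = ex, transcript_seq = tx, protein_seq = tl_translate(tx),
      abundance_tpm = as.numeric(mc$abundance_tpm[i])
    ), class = "GeneModel")
  }
  hri <- which(mc$type == "biological_region")
  hard <- data.frame(start = BiocGenerics::start(gr)[hri] - 1L,
                     end = BiocGenerics::end(gr)[hri],
                     gene_id = parent[hri],
                     exon_index = as.integer(mc$exon_index[hri]),
                     partner_gene_id = as.character(mc$partner_gene_id[hri]),
                     stringsAsFactors = FALSE)
  if (is.na(target_id))
    target_id <- names(genes)[vapply(genes, function(g) g$klass == "P1",
                                     logical(1))][1]
  structure(list(reference_seq = ref, genes = genes, hard_regions = hard,
                 control_gene_id = control_id, target_gene_id = target_id,
                 hard_partner_id = if (nrow(hard)) hard$partner_gene_id[
                   hard$gene_id == target_id][1] else NA_character_,
                 config = NULL),
            class = "FamilyReference")
}

# bedGraph -------------------------------------------------------------------

write_bedgraph <- function(depth_by_chrom, path) {
  grs <- lapply(names(depth_by_chrom), function(chrom) {
    runs <- depth_to_runs(depth_by_chrom[[chrom]])
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(runs$start + 1L, runs$end),
                           score = runs$depth)
  })
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# returns named list of per-position integer depth vectors; lengths taken
# from `chrom_lengths` (named integer vector)
read_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(chrom_lengths), function(chrom) {
    sel <- gr[GenomicRanges::seqnames(gr) == chrom]
    runs <- data.frame(start = BiocGenerics::start(sel) - 1L,
                       end = BiocGenerics::end(sel),
                       depth = S4Vectors::mcols(sel)$score)
    runs_to_depth(runs, chrom_lengths[[chrom]])
  })
  setNames(out, names(chrom_lengths))
}

# BED12 ----------------------------------------------------------------------

# internal representation: data.frame(chrom, start, end, name, ...) with a
# `blocks` list-column of absolute 0-based half-open intervals
write_bed12 <- function(bed, path) {
  if (nrow(bed) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(bed$chrom,
                               IRanges::IRanges(bed$start + 1L, bed$end),
                               strand = "+")
  blocks <- IRanges::IRangesList(lapply(seq_len(nrow(bed)), function(i) {
    b <- bed$blocks[[i]]
    IRanges::IRanges(b$start - bed$start[i] + 1L, b$end - bed$start[i])
  }))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = bed$name, score = 0L,
    thick = IRanges::IRanges(bed$start + 1L, bed$end), blocks = blocks)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

read_bed12 <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      blocks = I(list())))
  gr <- rtracklayer::import(path, format = "bed")
  starts <- BiocGenerics::start(gr) - 1L
  blocks_rel <- S4Vectors::mcols(gr)$blocks
  blocks <- lapply(seq_along(gr), function(i) {
    if (is.null(blocks_rel) || length(blocks_rel[[i]]) == 0L)
      interval_df(starts[i], BiocGenerics::end(gr)[i])
    else
      interval_df(starts[i] + BiocGenerics::start(blocks_rel[[i]]) - 1L,
                  starts[i] + BiocGenerics::end(blocks_rel[[i]]))
  })
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = starts, end = BiocGenerics::end(gr),
                    name = S4Vectors::mcols(gr)$name,
                    stringsAsFactors = FALSE)
  out$blocks <- blocks
  out
}

# study bundle ---------------------------------------------------------------

#' Write a simulated study to disk
#'
#' @param bundle Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_family(bundle$family, dir)

  p <- file.path(dir, "peptides.tsv")
  write.table(bundle$peptides, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["peptides"] <- p

  p <- file.path(dir, "specimens.tsv")
  write.table(bundle$specimens, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["specimens"] <- p

  for (sp in names(bundle$transcript$coverage)) {
    p <- file.path(dir, sprintf("transcript_cov_%s.bedGraph", sp))
    write_bedgraph(bundle$transcript$coverage[[sp]], p)
    paths[paste0("transcript_cov_", sp)] <- p
  }
  for (sp in bundle$specimens$specimen_id) {
    fr <- bundle$transcript$fragments
    fr <- fr[fr$specimen_id == sp, , drop = FALSE]
    p <- file.path(dir, sprintf("fragments_%s.bed", sp))
    write_bed12(fr, p); paths[paste0("fragments_", sp)] <- p
    iso <- bundle$transcript$isoforms
    iso <- iso[iso$specimen_id == sp, , drop = FALSE]
    p <- file.path(dir, sprintf("isoforms_%s.bed", sp))
    write_bed12(iso, p); paths[paste0("isoforms_", sp)] <- p
    p <- file.path(dir, sprintf("locus_cov_%s.bedGraph", sp))
    write_bedgraph(list(family_ref = bundle$capture$locus_coverage[[sp]]), p)
    paths[paste0("locus_cov_", sp)] <- p
    p <- file.path(dir, sprintf("contigs_%s.fasta", sp))
    ctg <- bundle$capture$contigs[[sp]]
    if (length(ctg)) write_fasta(ctg, p) else writeLines(character(0), p)
    paths[paste0("contigs_", sp)] <- p
  }

  p <- file.path(dir, "truth.json")
  truth_list <- list(
    statuses = bundle$truth,
    genotype_classes = data.frame(
      specimen_id = vapply(bundle$genotypes, `[[`, character(1),
                           "specimen_id"),
      region = vapply(bundle$genotypes, `[[`, character(1), "region"),
      genotype_class = vapply(bundle$genotypes, `[[`, character(1),
                              "genotype_class")))
  jsonlite::write_json(truth_list, p, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  paths["truth"] <- p
  invisible(paths)
}

#' Read a simulated study back from disk
#'
#' @param dir Directory written by [write_study()].
#' @return A bundle with the same layout as [simulate_study()] (without
#'   genotypes; `truth` is read from `truth.json` when present).
#' @export
read_study <- function(dir) {
  family <- read_family(file.path(dir, "reference.fasta"),
                        file.path(dir, "genes.gff3"))
  specimens <- read.delim(file.path(dir, "specimens.tsv"),
                          stringsAsFactors = FALSE)
  peptides <- read.delim(file.path(dir, "peptides.tsv"),
                         stringsAsFactors = FALSE)
  tx_lengths <- vapply(family$genes, transcript_length, integer(1))
  ref_len <- c(family_ref = nchar(family$reference_seq))
  coverage <- list(); locus_coverage <- list(); contigs <- list()
  frags <- list(); isos <- list()
  for (sp in specimens$specimen_id) {
    coverage[[sp]] <- read_bedgraph(
      file.path(dir, sprintf("transcript_cov_%s.bedGraph", sp)), tx_lengths)
    locus_coverage[[sp]] <- read_bedgraph(
      file.path(dir, sprintf("locus_cov_%s.bedGraph", sp)), ref_len)[[1]]
    fp <- file.path(dir, sprintf("contigs_%s.fasta", sp))
    contigs[[sp]] <- if (file.size(fp) > 0L) read_fasta(fp) else character(0)
    fr <- read_bed12(file.path(dir, sprintf("fragments_%s.bed", sp)))
    if (nrow(fr)) { fr$specimen_id <- sp; frags[[sp]] <- fr }
    iso <- read_bed12(file.path(dir, sprintf("isoforms_%s.bed", sp)))
    if (nrow(iso)) { iso$specimen_id <- sp; isos[[sp]] <- iso }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), blocks = I(list()),
               specimen_id = character())
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp, simplifyVector = TRUE)
    truth <- tj$statuses
  }
  list(family = family, specimens = specimens, peptides = peptides,
       transcript = list(coverage = coverage, fragments = bind(frags),
                         isoforms = bind(isos)),
       capture = list(locus_coverage = locus_coverage, contigs = contigs),
       truth = truth)
}
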