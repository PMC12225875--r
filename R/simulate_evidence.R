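# Per-specimen evidence simulation: peptide tables, transcript coverage /
# fragments / isoforms, targeted-capture coverage and contigs. Each layer is
# generated from the genotypes alone, so the downstream pipeline can be
# scored against ground truth.

# transcript-space exon intervals (0-based half-open)
tx_exon_intervals <- function(gene) {
  exlen <- gene$exons$end - gene$exons$start
  ends <- cumsum(exlen)
  interval_df(ends - exlen, ends)
}

transcript_length <- function(gene) sum(gene$exons$end - gene$exons$start)

# transcript-space hard-region intervals for a gene (empty if none)
hard_tx_intervals <- function(family, gene_id) {
  hr <- family$hard_regions
  hr <- hr[hr$gene_id == gene_id, , drop = FALSE]
  if (nrow(hr) == 0L) return(interval_df())
  txe <- tx_exon_intervals(family$genes[[gene_id]])
  interval_df(txe$start[hr$exon_index], txe$end[hr$exon_index])
}

# number of protein-producing alleles (intact and divergent alleles fold into
# detectable protein; frameshift and fusion products are truncated/chimeric
# and are modeled as undetectable in venom)
protein_dosage <- function(alleles) {
  sum(vapply(alleles, `[[`, character(1), "type") %in%
        c("intact", "divergent"))
}

# number of fully transcribing alleles (frameshift alleles still transcribe)
rna_full_dosage <- function(alleles) {
  sum(vapply(alleles, `[[`, character(1), "type") %in%
        c("intact", "divergent", "frameshift"))
}

fusion_alleles <- function(alleles) {
  Filter(function(a) a$type == "fusion", alleles)
}

#' Simulate per-specimen peptide tables
#'
#' Peptide counts are Poisson with expectation proportional to gene abundance
#' times protein-producing allele dosage, split evenly across the gene's
#' usable tryptic peptides. Instrument carry-over adds a fixed fraction of
#' every other specimen's expectation to each specimen, so homozygously
#' deleted genes contribute only contamination-level counts. Identical
#' peptide sequences arising from several paralogs accumulate counts from
#' every expressing copy.
#'
#' @param family A `FamilyReference`.
#' @param genotypes Output of [assign_genotypes()].
#' @param config A [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return data.frame with `specimen_id`, `peptide_seq`, `count` (rows with
#'   positive counts only), sorted for byte-stable output.
#' @export
simulate_peptide_table <- function(family, genotypes, config = family$config,
                                   seed = config$seed + 2L) {
  set.seed(seed)
  spec_ids <- vapply(genotypes, `[[`, character(1), "specimen_id")
  rows <- list()
  for (gid in names(family$genes)) {
    gene <- family$genes[[gid]]
    base_total <- config$peptide_depth * gene$abundance_tpm / 1000

    emit_protein <- function(protein_seq, dosage_by_spec) {
      dg <- tryptic_digest(protein_seq, config$min_peptide_length)
      dg <- dg[dg$usable, , drop = FALSE]
      if (nrow(dg) == 0L || all(dosage_by_spec == 0)) return(NULL)
      lam_per_pep <- base_total * dosage_by_spec / 2 / nrow(dg)
      # contamination: each specimen receives a fixed fraction of the summed
      # expectation of all other specimens
      tot <- sum(lam_per_pep)
      lam <- lam_per_pep + config$contamination_rate * (tot - lam_per_pep)
      out <- list()
      for (s in seq_along(spec_ids)) {
        if (lam[s] <= 0) next
        cnt <- rpois(nrow(dg), lam[s])
        keep <- cnt > 0L
        if (any(keep))
          out[[length(out) + 1L]] <- data.frame(
            specimen_id = spec_ids[s], peptide_seq = dg$peptide[keep],
            count = cnt[keep], stringsAsFactors = FALSE)
      }
      if (length(out)) do.call(rbind, out) else NULL
    }

    # reference protein: dosage = intact alleles per specimen
    d_ref <- vapply(genotypes, function(g)
      sum(vapply(g$alleles[[gid]], `[[`, character(1), "type") == "intact"),
      numeric(1))
    rows[[length(rows) + 1L]] <- emit_protein(gene$protein_seq, d_ref)

    # divergent alleles emit the peptides of their own mutated protein
    for (s in seq_along(genotypes)) {
      for (a in genotypes[[s]]$alleles[[gid]]) {
        if (a$type != "divergent") next
        hap <- build_haplotype(family, gid, a)
        tx <- paste(substring(hap$seq, hap$exons$start + 1L, hap$exons$end),
                    collapse = "")
        d <- numeric(length(spec_ids)); d[s] <- 1
        rows[[length(rows) + 1L]] <- emit_protein(tl_translate(tx), d)
      }
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(specimen_id = character(), peptide_seq = character(),
                      count = integer()))
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(count ~ specimen_id + peptide_seq, tab, sum)
  agg <- agg[order(agg$specimen_id, agg$peptide_seq), ]
  rownames(agg) <- NULL
  agg
}

#' Simulate transcript-level evidence
#'
#' Produces, per specimen: per-gene transcript coverage (Poisson around
#' abundance x transcribing-allele dosage, with hard-region positions
#' depressed to `hard_region_factor` of the combined expectation of both
#' near-identical copies), assembled-fragment alignments tiling all adjacent
#' exon pairs for fully transcribing genes, and long-read isoforms (three
#' jittered copies within the clustering tolerances). Fusion alleles
#' transcribe only the target-derived exons downstream of the breakpoint;
#' homozygously deleted genes yield neither fragments nor isoforms.
#'
#' @inheritParams simulate_peptide_table
#' @param seed RNG seed (defaults to `config$seed + 3`).
#' @return List with `coverage` (`coverage[[specimen]][[gene]]` integer depth
#'   vectors over the transcript), `fragments` and `isoforms` (BED12-style
#'   data.frames with a `blocks` list-column of absolute 0-based half-open
#'   genomic intervals).
#' @export
simulate_transcript_evidence <- function(family, genotypes,
                                         config = family$config,
                                         seed = config$seed + 3L) {
  set.seed(seed)
  coverage <- list(); frag_rows <- list(); iso_rows <- list()
  for (g in genotypes) {
    sp <- g$specimen_id
    coverage[[sp]] <- list()
    for (gid in names(family$genes)) {
      gene <- family$genes[[gid]]
      txlen <- transcript_length(gene)
      txe <- tx_exon_intervals(gene)
      alleles <- g$alleles[[gid]]
      base <- config$transcript_depth * gene$abundance_tpm / 1000 / 2
      dose <- rep(rna_full_dosage(alleles), txlen)
      for (a in fusion_alleles(alleles)) {
        b <- a$breakpoint_exon
        if (b < nrow(txe)) {
          idx <- (txe$start[b + 1L] + 1L):txlen
          dose[idx] <- dose[idx] + 1
        }
      }
      expect <- base * dose
      hard <- hard_tx_intervals(family, gid)
      if (nrow(hard) > 0L) {
        pid <- family$hard_regions$partner_gene_id[
          family$hard_regions$gene_id == gid][1]
        pgene <- family$genes[[pid]]
        p_base <- config$transcript_depth * pgene$abundance_tpm / 1000 / 2
        p_dose <- rna_full_dosage(g$alleles[[pid]])
        hm <- intervals_to_mask(hard, txlen)
        expect[hm] <- config$hard_region_factor *
          (expect[hm] + p_base * p_dose)
      }
      coverage[[sp]][[gid]] <- rpois(txlen, expect)

      nex <- nrow(txe)
      full <- rna_full_dosage(alleles) > 0
      mk_row <- function(name, block_idx, trim5 = 0L, trim3 = 0L) {
        blocks <- interval_df(gene$exons$start[block_idx],
                              gene$exons$end[block_idx])
        blocks$start[1] <- blocks$start[1] + trim5
        blocks$end[nrow(blocks)] <- blocks$end[nrow(blocks)] - trim3
        df <- data.frame(chrom = "family_ref", start = blocks$start[1],
                         end = blocks$end[nrow(blocks)], name = name,
                         specimen_id = sp, gene_id = gid,
                         stringsAsFactors = FALSE)
        df$blocks <- list(blocks)
        df
      }
      if (full && nex >= 1L) {
        if (nex >= 3L) {
          for (i in seq_len(nex - 2L))
            frag_rows[[length(frag_rows) + 1L]] <-
              mk_row(sprintf("%s|%s|frag%02d", sp, gid, i), i:(i + 2L))
        } else {
          frag_rows[[length(frag_rows) + 1L]] <-
            mk_row(sprintf("%s|%s|frag01", sp, gid), seq_len(nex))
        }
        jit <- list(c(0L, 0L), c(40L, 10L), c(80L, 20L))
        for (k in seq_along(jit))
          iso_rows[[length(iso_rows) + 1L]] <-
            mk_row(sprintf("%s|%s|iso%d", sp, gid, k), seq_len(nex),
                   trim5 = jit[[k]][1], trim3 = jit[[k]][2])
      } else if (length(fusion_alleles(alleles)) > 0L) {
        b <- fusion_alleles(alleles)[[1]]$breakpoint_exon
        if (b < nex) {
          retained <- (b + 1L):nex
          frag_rows[[length(frag_rows) + 1L]] <-
            mk_row(sprintf("%s|%s|frag01", sp, gid), retained)
          iso_rows[[length(iso_rows) + 1L]] <-
            mk_row(sprintf("%s|%s|iso1", sp, gid), retained)
        }
      }
    }
  }
  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), specimen_id = character(),
               gene_id = character(), blocks = I(list()))
  list(coverage = coverage, fragments = bind(frag_rows),
       isoforms = bind(iso_rows))
}

# per-position capture dosage for one specimen over a gene's locus
allele_locus_dosage <- function(family, gene_id, allele, locus_len) {
  gene <- family$genes[[gene_id]]
  switch(allele$type,
    deleted = numeric(locus_len),
    fusion = {
      # the donor-derived 5' part of the chimera maps to the donor locus;
      # only the retained target-derived tail maps back here
      cut <- gene$exons$end[allele$breakpoint_exon] - gene$locus_interval[1]
      c(numeric(cut), rep(1, locus_len - cut))
    },
    rep(1, locus_len))
}

#' Simulate targeted-capture evidence
#'
#' Capture depth is Poisson per bait window (`bait_spacing` nt), with
#' expectation `capture_depth` x dosage / 2; dosage is 2 everywhere except
#' within gene loci carrying loss alleles. Contigs are the specimen's
#' distinct haplotype sequences over each locus, carrying fusion, frameshift
#' and divergence edits verbatim; deleted haplotypes yield no contig.
#'
#' @inheritParams simulate_peptide_table
#' @param seed RNG seed (defaults to `config$seed + 4`).
#' @return List with `locus_coverage` (per-specimen integer depth vector over
#'   the reference) and `contigs` (per-specimen named character vectors;
#'   names are `specimen|gene|hapN`).
#' @export
simulate_capture_evidence <- function(family, genotypes,
                                      config = family$config,
                                      seed = config$seed + 4L) {
  set.seed(seed)
  ref_len <- nchar(family$reference_seq)
  win <- config$bait_spacing
  n_win <- ceiling(ref_len / win)
  win_start <- (seq_len(n_win) - 1L) * win
  win_end <- pmin(win_start + win, ref_len)
  mid <- (win_start + win_end) %/% 2L

  locus_coverage <- list(); contigs <- list()
  for (g in genotypes) {
    sp <- g$specimen_id
    dose <- rep(2, n_win)
    for (gid in names(family$genes)) {
      gene <- family$genes[[gid]]
      loc <- gene$locus_interval
      in_locus <- which(mid >= loc[1] & mid < loc[2])
      if (!length(in_locus)) next
      ad <- numeric(length(in_locus))
      for (a in g$alleles[[gid]]) {
        d <- allele_locus_dosage(family, gid, a, loc[2] - loc[1])
        ad <- ad + d[mid[in_locus] - loc[1] + 1L]
      }
      dose[in_locus] <- ad
    }
    wd <- rpois(n_win, config$capture_depth * dose / 2)
    depth <- rep(wd, times = win_end - win_start)
    locus_coverage[[sp]] <- depth

    ctg <- character(0)
    for (gid in names(family$genes)) {
      haps <- lapply(g$alleles[[gid]], function(a)
        build_haplotype(family, gid, a))
      haps <- Filter(Negate(is.null), haps)
      seqs <- unique(vapply(haps, `[[`, character(1), "seq"))
      if (length(seqs))
        ctg[paste0(sp, "|", gid, "|hap", seq_along(seqs))] <- seqs
    }
    contigs[[sp]] <- ctg
  }
  list(locus_coverage = locus_coverage, contigs = contigs)
}

#' Simulate a complete study
#'
#' Builds the family, assigns genotypes and generates all three evidence
#' layers plus ground truth. If `outdir` is given, every layer is written to
#' disk in its standard plain-text format (FASTA, GFF3, TSV, bedGraph,
#' BED12, JSON) and the same files reparse into the returned structures.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory.
#' @return List with `family`, `genotypes`, `specimens`, `peptides`,
#'   `transcript` (coverage/fragments/isoforms), `capture`
#'   (locus_coverage/contigs), `truth`, and `paths` when written.
#' @export
simulate_study <- function(config = simulation_config(), outdir = NULL) {
  if (config$n_specimens_west + config$n_specimens_east == 0L)
    stop("input error: empty specimen table")
  family <- build_gene_family(config)
  genotypes <- assign_genotypes(family, config)
  peptides <- simulate_peptide_table(family, genotypes, config)
  transcript <- simulate_transcript_evidence(family, genotypes, config)
  capture <- simulate_capture_evidence(family, genotypes, config)
  truth <- truth_gene_status(family, genotypes)
  specimens <- unique(truth[, c("specimen_id", "region")])
  rownames(specimens) <- NULL
  bundle <- list(family = family, genotypes = genotypes,
                 specimens = specimens, peptides = peptides,
                 transcript = transcript, capture = capture, truth = truth)
  if (!is.null(outdir)) bundle$paths <- write_study(bundle, outdir)
  bundle
}
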