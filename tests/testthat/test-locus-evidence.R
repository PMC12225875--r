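test_that("locus coverage summaries and copy states follow the ratio bands", {
  s <- summarize_locus_coverage(rep(0L, 100), rep(40L, 100))
  expect_equal(s$ratio, 0)
  expect_equal(call_copy_state(s), "HOM_DELETION")
  s <- summarize_locus_coverage(rep(40L, 100), rep(40L, 100))
  expect_equal(s$ratio, 1)
  expect_equal(call_copy_state(s), "INTACT")
  s <- summarize_locus_coverage(rep(20L, 100), rep(40L, 100))
  expect_equal(call_copy_state(s), "HET_DELETION")
  s <- summarize_locus_coverage(rep(30L, 100), rep(40L, 100))
  expect_equal(call_copy_state(s), "AMBIGUOUS_RATIO")
  s <- summarize_locus_coverage(rep(10L, 100), rep(0L, 100))
  expect_true(s$no_data)
  expect_equal(call_copy_state(s), "NO_DATA")
})

test_that("an unmutated haplotype annotates as a complete in-frame chain", {
  b <- default_bundle()
  fam <- b$family
  lib <- exon_library(fam)
  sp <- specimens_of_class(b, "intact")[1]
  target <- fam$target_gene_id
  ctg <- b$capture$contigs[[sp]][[paste0(sp, "|", target, "|hap1")]]
  calls <- annotate_contig_exons(ctg, lib)
  n_ex <- nrow(fam$genes[[target]]$exons)
  # collinear, complete, in frame; the resident gene wins or ties every call
  expect_equal(nrow(calls), n_ex)
  expect_equal(sort(calls$exon_index), seq_len(n_ex))
  expect_true(all(diff(calls$start) > 0))
  expect_true(all(calls$frame_status == "in_frame"))
  expect_true(all(calls$aa_identity == 1.0))
  resident <- calls$best_gene_id == target |
    grepl(target, calls$tied_gene_ids)
  expect_true(all(resident))
  # hard-region exon copies surface as explicit ambiguity, not misassignment
  expect_true(all(calls$ambiguous[calls$exon_index %in% c(3, 4)]))
  expect_false(any(calls$ambiguous[!calls$exon_index %in% c(3, 4)]))
})

test_that("an embedded divergent exon is recovered at oracle identity", {
  fam <- build_gene_family(simulation_config(n_genes = 2L, seed = 31L))
  lib <- exon_library(fam)
  row <- which(lib$gene_id == fam$target_gene_id & lib$exon_index == 7L)
  exon_nt <- lib$nt[row]; exon_aa <- lib$aa[row]
  # substitute 6 interior amino acids, choosing codons within 2 nt of the
  # original so the segment stays findable
  set.seed(32)
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(exon_nt, seq(1, nchar(exon_nt), 3),
                      seq(3, nchar(exon_nt), 3))
  idx <- sample(5:35, 6)
  for (i in idx) {
    old <- codons[i]
    cands <- names(gc)[gc != gc[[old]] & gc != "*"]
    dist <- vapply(cands, function(cd)
      sum(strsplit(cd, "")[[1]] != strsplit(old, "")[[1]]), integer(1))
    codons[i] <- cands[dist <= 2][1]
  }
  mutated <- paste(codons, collapse = "")
  set.seed(33)
  contig <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                  collapse = "")
  contig <- paste0(substr(contig, 1, 200), mutated,
                   substr(contig, 201, 700))
  calls <- annotate_contig_exons(contig, lib)
  hit <- calls[calls$exon_index == 7L & calls$best_gene_id ==
                 fam$target_gene_id, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 200L)
  oracle <- nw_identity(toxinloss:::tl_translate(mutated), exon_aa)
  expect_lt(abs(hit$aa_identity - oracle), 0.02)
})

test_that("fusion detection needs a donor run of two next to target exons", {
  b <- default_bundle()
  fam <- b$family
  target <- fam$target_gene_id
  sp <- specimens_of_class(b, "hom_fusion")[1]
  ctg <- b$capture$contigs[[sp]][[paste0(sp, "|", target, "|hap1")]]
  calls <- annotate_contig_exons(ctg, exon_library(fam))
  fus <- detect_fusion(calls, target)
  expect_equal(fus$donor_gene_id, fam$hard_partner_id)
  expect_equal(unname(fus$breakpoint["before_target_exon"]), 11L)
  expect_true(all(fus$donor_exons <= 10L))

  # constructed call chains: donor run interrupted by an ambiguous exon, the
  # published chimera pattern
  mk_calls <- function(genes, exons, ident = 1, amb = FALSE) {
    n <- length(genes)
    data.frame(start = (0:(n - 1)) * 200L, end = (0:(n - 1)) * 200L + 120L,
               best_gene_id = genes, exon_index = exons,
               aa_identity = rep(ident, n),
               ambiguous = rep(amb, length.out = n),
               tied_gene_ids = genes, frame_status = "in_frame",
               stringsAsFactors = FALSE)
  }
  chimera <- mk_calls(c("MAD5", "MAD5", "MAD5", "MAD5", "AMB", "TGT", "TGT"),
                      c(7L, 8L, 9L, 10L, 11L, 12L, 14L))
  chimera$ambiguous <- c(rep(FALSE, 4), TRUE, FALSE, FALSE)
  fus <- detect_fusion(chimera, "TGT")
  expect_equal(fus$donor_gene_id, "MAD5")
  expect_equal(unname(fus$breakpoint["after_donor_exon"]), 10L)

  expect_null(detect_fusion(mk_calls(rep("TGT", 5), 1:5), "TGT"))
  # a single stray non-target call is not a fusion
  stray <- mk_calls(c("TGT", "MAD5", "TGT", "TGT"), c(1L, 2L, 3L, 4L),
                    ident = 0.91)
  expect_null(detect_fusion(stray, "TGT"))
  # a low-identity run is not a fusion either
  weak <- mk_calls(c("MAD5", "MAD5", "TGT", "TGT"), c(1L, 2L, 3L, 4L),
                   ident = 0.7)
  expect_null(detect_fusion(weak, "TGT"))
})

test_that("frameshift disruption is recovered with a premature stop", {
  b <- default_bundle()
  fam <- b$family
  target <- fam$target_gene_id
  gene <- fam$genes[[target]]
  sp <- specimens_of_class(b, "het_frameshift")[1]
  ctgs <- b$capture$contigs[[sp]]
  ctgs <- ctgs[grepl(paste0("[|]", target, "[|]"), names(ctgs))]
  expect_length(ctgs, 2L)   # intact and frameshifted haplotypes
  lib <- exon_library(fam)
  reports <- lapply(ctgs, function(x)
    detect_disruption(annotate_contig_exons(x, lib), gene))
  hit <- Filter(Negate(is.null), reports)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$type, "FRAMESHIFT")
  expect_equal(hit[[1]]$first_affected_exon, 10L)
  expect_equal(hit[[1]]$frame_status, "premature_stop")

  # independent codon-table oracle: the edited spliced CDS stops before the
  # final metalloproteinase exon
  fs_ctg <- ctgs[[which(!vapply(reports, is.null, logical(1)))]]
  gt <- b$genotypes[[which(vapply(b$genotypes, `[[`, character(1),
                                  "specimen_id") == sp)]]
  allele <- Filter(function(a) a$type == "frameshift",
                   gt$alleles[[target]])[[1]]
  hap <- build_haplotype(fam, target, allele)
  expect_identical(hap$seq, fs_ctg)
  cds <- paste(substring(hap$seq, hap$exons$start + 1L, hap$exons$end),
               collapse = "")
  aa_oracle <- seqinr::translate(strsplit(tolower(cds), "")[[1]])
  stop_at <- which(aa_oracle == "*")[1]
  last_dom <- max(gene$exons$exon_index[gene$exons$domain_label ==
                                          "metalloproteinase"])
  exlen <- gene$exons$end[1] - gene$exons$start[1]
  expect_false(is.na(stop_at))
  expect_lt(stop_at, (last_dom - 1L) * exlen / 3)

  # an intact contig yields no disruption
  intact_ctg <- ctgs[[which(vapply(reports, is.null, logical(1)))]]
  expect_null(detect_disruption(annotate_contig_exons(intact_ctg, lib),
                                gene))
})

test_that("a substituted allele without frame damage is called divergent", {
  cfg <- simulation_config(
    n_specimens_west = 0L, n_specimens_east = 1L,
    genotypes = list(mode = "counts", west = list(),
                     east = list(hom_divergent = 1L),
                     fusion_breakpoint_exon = 10L,
                     frameshift_exon = 10L, frameshift_indel = 1L),
    seed = 77L)
  fam <- build_gene_family(cfg)
  gt <- assign_genotypes(fam, cfg)
  # raise the substitution load so several exons fall below same-gene
  # identity
  gt[[1]]$alleles[[fam$target_gene_id]] <- lapply(
    gt[[1]]$alleles[[fam$target_gene_id]], function(a) {
      a$substitution_rate <- 0.05
      a$edits <- toxinloss:::draw_divergent_edits(fam, fam$target_gene_id,
                                                  0.05)
      a
    })
  cap <- simulate_capture_evidence(fam, gt, cfg)
  ctg <- cap$contigs[[1]][grepl(paste0("[|]", fam$target_gene_id, "[|]"),
                                names(cap$contigs[[1]]))][[1]]
  calls <- annotate_contig_exons(ctg, exon_library(fam))
  rep <- detect_disruption(calls, fam$genes[[fam$target_gene_id]])
  expect_equal(rep$type, "DIVERGENT_ALLELE")
})

test_that("locus states over the simulated study match the genotypes", {
  b <- default_bundle()
  lc <- call_locus_states(b$family, b$capture$locus_coverage,
                          b$capture$contigs)
  target <- b$family$target_gene_id
  pick <- function(sp) lc$calls$locus_state[lc$calls$specimen_id == sp &
                                              lc$calls$gene_id == target]
  for (sp in specimens_of_class(b, "hom_deletion"))
    expect_equal(pick(sp), "HOM_DELETION")
  for (sp in specimens_of_class(b, "het_deletion"))
    expect_equal(pick(sp), "HET_DELETION")
  for (sp in specimens_of_class(b, "hom_fusion"))
    expect_equal(pick(sp), "FUSION")
  for (sp in specimens_of_class(b, "het_frameshift"))
    expect_equal(pick(sp), "FRAMESHIFT")
  for (sp in specimens_of_class(b, "intact"))
    expect_equal(pick(sp), "INTACT")
  # non-target genes are intact everywhere; no spurious fusion or frameshift
  other <- lc$calls[lc$calls$gene_id != target, ]
  expect_true(all(other$locus_state == "INTACT"))
})
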