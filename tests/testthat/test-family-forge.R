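test_that("family size, classes and hard regions follow the configuration", {
  fam1 <- build_gene_family(simulation_config(n_genes = 1L, seed = 3L))
  expect_length(fam1$genes, 1L)
  expect_equal(fam1$genes[[1]]$klass, "P1")
  expect_equal(nrow(fam1$hard_regions), 0L)
  expect_true(is.na(fam1$control_gene_id))

  fam30 <- build_gene_family(simulation_config(n_genes = 30L, seed = 3L))
  expect_length(fam30$genes, 30L)
  klasses <- vapply(fam30$genes, `[[`, character(1), "klass")
  expect_equal(sum(klasses == "P1"), 1L)
  expect_equal(fam30$genes[[fam30$control_gene_id]]$klass, "P3")
  expect_gt(nrow(fam30$hard_regions), 0L)
  # hard-region copies are identical sequences on the reference
  hr <- fam30$hard_regions
  seqs <- substring(fam30$reference_seq, hr$start + 1L, hr$end)
  expect_equal(seqs[hr$exon_index == 3][1], seqs[hr$exon_index == 3][2])
})

test_that("gene model invariants hold: disjoint sorted exons that translate", {
  fam <- default_bundle()$family
  for (g in fam$genes) {
    ex <- g$exons
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end[-nrow(ex)] <= ex$start[-1]))
    expect_true(all(ex$start >= g$locus_interval[1]))
    expect_true(all(ex$end <= g$locus_interval[2]))
    tx <- paste(substring(fam$reference_seq, ex$start + 1L, ex$end),
                collapse = "")
    expect_identical(tx, g$transcript_seq)
    expect_false(grepl("*", g$protein_seq, fixed = TRUE))
    if (g$klass == "P1")
      expect_false(any(ex$domain_label %in% c("disintegrin",
                                              "cysteine_rich")))
  }
})

test_that("pairwise identities sit in the band and agree with an independent aligner", {
  cfg <- simulation_config(n_genes = 4L, exon_length = 30L, seed = 11L)
  fam <- build_gene_family(cfg)
  ids <- pairwise_protein_identity(fam)
  hard_pair <- !is.na(fam$hard_partner_id) &
    ((ids$gene1 == fam$target_gene_id & ids$gene2 == fam$hard_partner_id) |
       (ids$gene2 == fam$target_gene_id & ids$gene1 == fam$hard_partner_id))
  expect_true(all(ids$identity[!hard_pair] >= cfg$identity_band[1]))
  expect_true(all(ids$identity[!hard_pair] <= cfg$identity_band[2]))
  for (i in seq_len(nrow(ids))) {
    oracle <- nw_identity(fam$genes[[ids$gene1[i]]]$protein_seq,
                          fam$genes[[ids$gene2[i]]]$protein_seq)
    expect_lt(abs(ids$identity[i] - oracle), 0.03)
  }
  expect_error(build_gene_family(simulation_config(identity_band = c(0.01,
                                                                     0.05))),
               "configuration error")
})

test_that("genotype presets are exact, deterministic and spare the control gene", {
  fam <- default_bundle()$family
  cfg <- simulation_config()
  g1 <- assign_genotypes(fam, cfg, seed = 42L)
  g2 <- assign_genotypes(fam, cfg, seed = 42L)
  expect_identical(g1, g2)
  cls <- table(vapply(g1, `[[`, character(1), "genotype_class"))
  expect_equal(unname(cls["hom_deletion"]), 2L)
  expect_equal(unname(cls["het_deletion"]), 1L)
  expect_equal(unname(cls["hom_fusion"]), 1L)
  expect_equal(unname(cls["het_frameshift"]), 1L)
  # mutation classes live in the configured cohorts
  for (g in g1) {
    if (g$genotype_class %in% c("hom_deletion", "het_deletion", "hom_fusion"))
      expect_equal(g$region, "west")
    if (g$genotype_class == "het_frameshift") expect_equal(g$region, "east")
    # control gene intact in every specimen
    types <- vapply(g$alleles[[fam$control_gene_id]], `[[`, character(1),
                    "type")
    expect_true(all(types == "intact"))
  }
  allint <- assign_genotypes(fam, simulation_config(
    genotypes = genotype_preset("all_intact")), seed = 1L)
  expect_true(all(vapply(allint, function(g)
    all(vapply(unlist(g$alleles, recursive = FALSE), `[[`, character(1),
               "type") == "intact"), logical(1))))

  bad_cfg <- simulation_config()
  bad_cfg$genotypes$target_gene <- fam$control_gene_id
  expect_error(assign_genotypes(fam, bad_cfg), "control gene")
})

test_that("frequency-mode allele frequencies match the binomial expectation", {
  fam <- build_gene_family(simulation_config(seed = 5L))
  p <- 0.4
  cfg <- simulation_config(genotypes = genotype_frequencies(
    west_loss_freq = p, east_loss_freq = 0.1))
  n_seeds <- 1000L
  loss_alleles <- 0L
  for (s in seq_len(n_seeds)) {
    gt <- assign_genotypes(fam, cfg, seed = s)
    west <- Filter(function(g) g$region == "west", gt)
    loss_alleles <- loss_alleles + sum(vapply(west, function(g) {
      switch(g$genotype_class, intact = 0L,
             het_deletion = , het_fusion = , het_frameshift = ,
             het_divergent = 1L, 2L)
    }, integer(1)))
  }
  n_draws <- n_seeds * 4L * 2L
  expect_gte(loss_alleles, qbinom(0.005, n_draws, p))
  expect_lte(loss_alleles, qbinom(0.995, n_draws, p))
})

test_that("peptide totals scale with abundance within the Poisson band", {
  cfg <- simulation_config(n_genes = 2L, n_specimens_west = 1L,
                           n_specimens_east = 0L,
                           abundance_tpm = c(4000, 1000),
                           contamination_rate = 0,
                           genotypes = genotype_preset("all_intact"),
                           seed = 9L)
  fam <- build_gene_family(cfg)
  gt <- assign_genotypes(fam, cfg)
  pep <- simulate_peptide_table(fam, gt, cfg)
  theo <- toxinloss:::theoretical_eups(fam)
  tot <- vapply(names(fam$genes), function(gid)
    sum(pep$count[pep$peptide_seq %in% theo[[gid]]$peptide]), numeric(1))
  # expected EUP totals: gene expectation spread uniformly over all usable
  # tryptic peptides, of which only the exclusive-unique subset is counted
  lam <- vapply(names(fam$genes), function(gid) {
    dg <- tryptic_digest(fam$genes[[gid]]$protein_seq,
                         cfg$min_peptide_length)
    cfg$peptide_depth * fam$genes[[gid]]$abundance_tpm / 1000 *
      nrow(theo[[gid]]) / sum(dg$usable)
  }, numeric(1))
  for (gid in names(fam$genes)) {
    expect_gte(tot[[gid]], qpois(0.005, lam[[gid]]))
    expect_lte(tot[[gid]], qpois(0.995, lam[[gid]]))
  }
})

test_that("evidence is monotone in allele dosage", {
  b <- default_bundle()
  fam <- b$family
  target <- fam$target_gene_id
  theo <- toxinloss:::theoretical_eups(fam)[[target]]
  hom <- specimens_of_class(b, "hom_deletion")[1]
  het <- specimens_of_class(b, "het_deletion")[1]
  full <- specimens_of_class(b, "intact")[1]
  eup_total <- function(sp) sum(b$peptides$count[
    b$peptides$specimen_id == sp & b$peptides$peptide_seq %in% theo$peptide])
  expect_lte(eup_total(hom), eup_total(het))
  expect_lt(eup_total(het), eup_total(full))
  tx_total <- function(sp) sum(b$transcript$coverage[[sp]][[target]])
  expect_lt(tx_total(hom), tx_total(het))
  expect_lt(tx_total(het), tx_total(full))
  loc <- fam$genes[[target]]$locus_interval
  cap_mean <- function(sp)
    mean(b$capture$locus_coverage[[sp]][(loc[1] + 1L):loc[2]])
  expect_lt(cap_mean(hom), cap_mean(het))
  expect_lt(cap_mean(het), cap_mean(full))
})

test_that("heterozygous-deletion capture ratio centers on one half", {
  cfg <- simulation_config(
    n_specimens_west = 1L, n_specimens_east = 0L,
    genotypes = list(mode = "counts", west = list(het_deletion = 1L),
                     east = list(), fusion_breakpoint_exon = 10L,
                     frameshift_exon = 10L, frameshift_indel = 1L))
  fam <- build_gene_family(cfg)
  gt <- assign_genotypes(fam, cfg)
  loc_t <- fam$genes[[fam$target_gene_id]]$locus_interval
  loc_c <- fam$genes[[fam$control_gene_id]]$locus_interval
  ratios <- vapply(seq_len(100L), function(s) {
    cap <- simulate_capture_evidence(fam, gt, cfg, seed = 1000L + s)
    d <- cap$locus_coverage[[1]]
    mean(d[(loc_t[1] + 1L):loc_t[2]]) / mean(d[(loc_c[1] + 1L):loc_c[2]])
  }, numeric(1))
  expect_gte(mean(ratios), 0.45)
  expect_lte(mean(ratios), 0.55)
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 17L)
  d1 <- file.path(tempdir(), "det_a"); d2 <- file.path(tempdir(), "det_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("every emitted file reparses into the generating structures", {
  cfg <- simulation_config(seed = 23L)
  d <- file.path(tempdir(), "roundtrip")
  unlink(d, recursive = TRUE)
  b <- simulate_study(cfg, outdir = d)
  rb <- read_study(d)
  expect_identical(rb$family$reference_seq, b$family$reference_seq)
  expect_identical(names(rb$family$genes), names(b$family$genes))
  for (gid in names(b$family$genes)) {
    expect_equal(rb$family$genes[[gid]]$exons, b$family$genes[[gid]]$exons)
    expect_identical(rb$family$genes[[gid]]$protein_seq,
                     b$family$genes[[gid]]$protein_seq)
  }
  expect_equal(rb$family$hard_regions$start, b$family$hard_regions$start)
  expect_identical(rb$family$target_gene_id, b$family$target_gene_id)
  expect_identical(rb$family$control_gene_id, b$family$control_gene_id)
  ord <- function(df) {
    df <- df[order(df$specimen_id, df$peptide_seq), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(rb$peptides), ord(b$peptides))
  for (sp in b$specimens$specimen_id) {
    expect_identical(rb$capture$contigs[[sp]], b$capture$contigs[[sp]])
    expect_identical(unname(rb$capture$locus_coverage[[sp]]),
                     unname(b$capture$locus_coverage[[sp]]))
    for (gid in names(b$family$genes))
      expect_identical(rb$transcript$coverage[[sp]][[gid]],
                       b$transcript$coverage[[sp]][[gid]])
  }
  expect_setequal(rb$transcript$fragments$name, b$transcript$fragments$name)
  i1 <- which(b$transcript$fragments$name == "E1|MPO1|frag01")
  i2 <- which(rb$transcript$fragments$name == "E1|MPO1|frag01")
  expect_equal(rb$transcript$fragments$blocks[[i2]],
               b$transcript$fragments$blocks[[i1]],
               ignore_attr = TRUE)
})
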