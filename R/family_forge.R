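# Synthetic paralogous toxin gene family ("family forge").
#
# The generator emulates the architecture of a snake venom metalloproteinase
# (SVMP) gene complex: one reference contig carrying a tandem array of highly
# similar paralogs of three structural classes (P1 = metalloproteinase domain
# only; P2 = + disintegrin; P3 = + disintegrin and cysteine-rich), including
# a "hard region" where one exon pair is carried verbatim by two paralogs so
# that unambiguous short-read mapping fails there.
#
# Exons are fixed-length and codon-aligned (default 120 nt = 40 codons), so
# every exon starts in frame 0 of its gene's ORF; this keeps frame bookkeeping
# exact for the frameshift / fusion machinery without loss of generality for
# the downstream analysis, which never relies on exon length.

N_EXONS_BY_CLASS <- c(P1 = 12L, P2 = 14L, P3 = 16L)

exon_domain_labels <- function(klass, n_exons) {
  lab <- character(n_exons)
  lab[1L] <- "signal"
  lab[2:4] <- "pro"
  lab[5:12] <- "metalloproteinase"
  if (klass %in% c("P2", "P3")) lab[13:14] <- "disintegrin"
  if (klass == "P3") lab[15:16] <- "cysteine_rich"
  lab
}

#' Build a synthetic paralogous gene family
#'
#' Generates a family of toxin-gene paralogs descended from one simulated
#' ancestral coding sequence, laid out on a single forward-strand reference
#' contig with introns and intergenic spacers. Exactly one gene is class P1
#' (the focal gene); one P3 gene placed immediately downstream of it is the
#' designated capture control and is never mutated by genotype assignment.
#' When the family has at least two genes, the focal gene's exons 3 and 4 are
#' copied verbatim into a partner paralog, creating the near-identical "hard
#' region" that defeats unambiguous read mapping.
#'
#' @param config A [simulation_config()].
#' @return An object of class `FamilyReference`: a list with `reference_seq`
#'   (character), `genes` (named list of `GeneModel`), `hard_regions`
#'   (data.frame of 0-based half-open reference intervals with the gene/exon
#'   each copy sits in), `control_gene_id`, `target_gene_id`,
#'   `hard_partner_id` and `config`.
#' @export
build_gene_family <- function(config = simulation_config()) {
  stopifnot(inherits(config, "toxinloss_config"))
  set.seed(config$seed)
  n <- config$n_genes
  exlen <- config$exon_length
  codons_per_exon <- exlen %/% 3L
  max_exons <- max(N_EXONS_BY_CLASS)

  # feasibility of the identity band: background identity for unrelated
  # proteins is ~1/20; a band below that cannot be hit by divergence alone
  if (config$identity_band[1] > 0.999 || config$identity_band[2] < 0.10)
    stop("configuration error: identity band infeasible for this alphabet")

  # ancestral CDS (all sense codons, Met start)
  anc_aa <- c("M", sample(AA_ALPHABET20, max_exons * codons_per_exon - 1L,
                          replace = TRUE))
  anc_codons <- vapply(anc_aa, codon_for_aa, character(1))

  # class layout: one P1, one control P3, remainder alternating P2/P3
  klasses <- "P1"
  if (n >= 2L) klasses <- c(klasses, "P3")
  if (n >= 3L) klasses <- c(klasses, rep(c("P2", "P3"), length.out = n - 2L))
  ids <- character(n)
  ids[1L] <- "MPO1"
  ids[klasses == "P3"] <- paste0("MDC", seq_len(sum(klasses == "P3")))
  ids[klasses == "P2"] <- paste0("MAD", seq_len(sum(klasses == "P2")))

  # per-gene divergence from the ancestor targeting the identity band
  m0 <- 1 - sqrt(config$identity_mean)
  m_g <- pmin(0.6, pmax(0.005, m0 + rnorm(n, 0, config$identity_sd)))

  gene_codons <- vector("list", n)
  for (g in seq_len(n)) {
    nex <- N_EXONS_BY_CLASS[[klasses[g]]]
    cod <- anc_codons[seq_len(nex * codons_per_exon)]
    hit <- which(runif(length(cod)) < m_g[g])
    hit <- hit[hit > 1L]                       # preserve the start codon
    for (i in hit) {
      old_aa <- GENETIC_CODE_SENSE[[cod[i]]]
      new_aa <- sample(setdiff(AA_ALPHABET20, old_aa), 1L)
      cod[i] <- codon_for_aa(new_aa)
    }
    gene_codons[[g]] <- cod
  }

  # hard region: copy focal exons 3-4 into a partner paralog, verbatim
  hard_partner <- NA_character_
  hard_regions <- data.frame(start = integer(), end = integer(),
                             gene_id = character(), exon_index = integer(),
                             partner_gene_id = character())
  partner_idx <- NA_integer_
  if (n >= 3L) partner_idx <- which(klasses == "P2")[1L]
  if (is.na(partner_idx) && n >= 2L) partner_idx <- 2L
  if (!is.na(partner_idx)) {
    hard_partner <- ids[partner_idx]
    hard_cod_idx <- (2L * codons_per_exon + 1L):(4L * codons_per_exon)
    gene_codons[[partner_idx]][hard_cod_idx] <- gene_codons[[1L]][hard_cod_idx]
  }

  # reference layout: half the non-focal genes, focal gene, control, the rest
  other <- setdiff(seq_len(n), c(1L, if (n >= 2L) 2L))
  first_half <- other[seq_len(length(other) %/% 2L)]
  order_idx <- c(first_half, 1L, if (n >= 2L) 2L, setdiff(other, first_half))

  genes <- list()
  ref_parts <- character(0)
  pos <- 0L
  for (g in order_idx) {
    spacer <- random_dna(config$spacer_length)
    ref_parts <- c(ref_parts, spacer)
    pos <- pos + config$spacer_length
    nex <- N_EXONS_BY_CLASS[[klasses[g]]]
    exon_nt <- vapply(seq_len(nex), function(e) {
      paste(gene_codons[[g]][((e - 1L) * codons_per_exon + 1L):
                               (e * codons_per_exon)], collapse = "")
    }, character(1))
    locus_start <- pos
    ex_start <- integer(nex); ex_end <- integer(nex)
    for (e in seq_len(nex)) {
      if (e > 1L) {
        ref_parts <- c(ref_parts, random_dna(config$intron_length))
        pos <- pos + config$intron_length
      }
      ex_start[e] <- pos
      ref_parts <- c(ref_parts, exon_nt[e])
      pos <- pos + exlen
      ex_end[e] <- pos
    }
    tx <- paste(exon_nt, collapse = "")
    genes[[ids[g]]] <- structure(list(
      gene_id = ids[g], klass = klasses[g],
      locus_interval = c(locus_start, pos),
      exons = data.frame(exon_index = seq_len(nex), start = ex_start,
                         end = ex_end,
                         domain_label = exon_domain_labels(klasses[g], nex),
                         stringsAsFactors = FALSE),
      transcript_seq = tx,
      protein_seq = tl_translate(tx),
      abundance_tpm = config$abundance_tpm[g]
    ), class = "GeneModel")
  }
  ref_parts <- c(ref_parts, random_dna(config$spacer_length))
  reference_seq <- paste(ref_parts, collapse = "")

  if (!is.na(hard_partner)) {
    for (gid in c(ids[1L], hard_partner)) {
      ex <- genes[[gid]]$exons
      hard_regions <- rbind(hard_regions, data.frame(
        start = ex$start[3:4], end = ex$end[3:4], gene_id = gid,
        exon_index = 3:4, partner_gene_id = setdiff(c(ids[1L], hard_partner),
                                                    gid)))
    }
  }

  fam <- structure(list(
    reference_seq = reference_seq,
    genes = genes,
    hard_regions = hard_regions,
    control_gene_id = if (n >= 2L) ids[2L] else NA_character_,
    target_gene_id = ids[1L],
    hard_partner_id = hard_partner,
    config = config
  ), class = "FamilyReference")

  ids_pi <- pairwise_protein_identity(fam)
  bad <- ids_pi$identity < config$identity_band[1] |
    ids_pi$identity > config$identity_band[2]
  # the hard-region pair legitimately exceeds the band: shared exons
  is_hard_pair <- (ids_pi$gene1 == fam$target_gene_id &
                     ids_pi$gene2 == hard_partner) |
    (ids_pi$gene2 == fam$target_gene_id & ids_pi$gene1 == hard_partner)
  if (any(bad & !is_hard_pair))
    stop("configuration error: realized pairwise identities fall outside ",
         "the configured identity band")
  fam
}

#' Pairwise protein identities within a family
#'
#' Identity is computed positionally over the shared N-terminal region (the
#' paralogs are colinear by construction): matches divided by the number of
#' compared residue pairs, ignoring the unalignable class-specific C-terminal
#' domains.
#'
#' @param family A `FamilyReference`.
#' @return data.frame with `gene1`, `gene2`, `identity`.
#' @export
pairwise_protein_identity <- function(family) {
  ids <- names(family$genes)
  out <- data.frame(gene1 = character(), gene2 = character(),
                    identity = numeric())
  if (length(ids) < 2L) return(out)
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    p1 <- strsplit(family$genes[[ids[i]]]$protein_seq, "")[[1]]
    p2 <- strsplit(family$genes[[ids[j]]]$protein_seq, "")[[1]]
    k <- min(length(p1), length(p2))
    out <- rbind(out, data.frame(gene1 = ids[i], gene2 = ids[j],
                                 identity = mean(p1[seq_len(k)] ==
                                                   p2[seq_len(k)])))
  }
  out
}

# ---------------------------------------------------------------------------
# genotype assignment

new_allele <- function(type, ...) c(list(type = type), list(...))

allele_pair_for_class <- function(cls, gt) {
  fus <- function() new_allele("fusion",
                               breakpoint_exon = gt$fusion_breakpoint_exon)
  fs <- function() new_allele("frameshift", exon_index = gt$frameshift_exon,
                              indel_length = gt$frameshift_indel)
  dv <- function() new_allele("divergent", substitution_rate = 0.02)
  switch(cls,
    intact          = list(new_allele("intact"), new_allele("intact")),
    hom_deletion    = list(new_allele("deleted"), new_allele("deleted")),
    het_deletion    = list(new_allele("intact"), new_allele("deleted")),
    hom_fusion      = list(fus(), fus()),
    het_fusion      = list(new_allele("intact"), fus()),
    hom_frameshift  = list(fs(), fs()),
    het_frameshift  = list(new_allele("intact"), fs()),
    hom_divergent   = list(dv(), dv()),
    het_divergent   = list(new_allele("intact"), dv()),
    stop("unknown genotype class: ", cls))
}

#' Assign per-specimen genotypes
#'
#' Assigns an allele pair for every gene and specimen. Only the focal (P1)
#' gene receives loss alleles; the control gene and all other paralogs stay
#' intact. See [genotype_preset()] for the two assignment modes.
#'
#' @param family A `FamilyReference`.
#' @param config A [simulation_config()] (its `genotypes` entry is used).
#' @param seed Integer seed for placement/drawing; defaults to
#'   `config$seed + 1`.
#' @return List of `GenotypeSpec` objects: `specimen_id`, `region`, and
#'   `alleles` (named per-gene list of two-allele lists). Divergent and
#'   frameshift alleles carry their realized edits so that downstream
#'   simulation is reproducible from the genotype alone.
#' @export
assign_genotypes <- function(family, config = family$config,
                             seed = config$seed + 1L) {
  gt <- config$genotypes
  target <- gt$target_gene %||% family$target_gene_id
  if (!is.na(family$control_gene_id) && identical(target,
                                                  family$control_gene_id))
    stop("configuration error: loss alleles requested for the control gene")
  if (!target %in% names(family$genes))
    stop("configuration error: unknown target gene ", target)
  set.seed(seed)

  spec_ids <- c(if (config$n_specimens_west > 0)
                  paste0("W", seq_len(config$n_specimens_west)),
                if (config$n_specimens_east > 0)
                  paste0("E", seq_len(config$n_specimens_east)))
  regions <- c(rep("west", config$n_specimens_west),
               rep("east", config$n_specimens_east))

  draw_classes <- function(counts, n_cohort) {
    cls <- rep(names(counts), times = unlist(counts))
    if (length(cls) > n_cohort)
      stop("configuration error: more mutation classes than specimens")
    cls <- c(cls, rep("intact", n_cohort - length(cls)))
    sample(cls)
  }

  if (gt$mode == "counts") {
    classes <- c(draw_classes(gt$west, config$n_specimens_west),
                 draw_classes(gt$east, config$n_specimens_east))
  } else {
    freq <- ifelse(regions == "west", gt$west_loss_freq, gt$east_loss_freq)
    classes <- vapply(seq_along(spec_ids), function(i) {
      loss <- runif(2) < freq[i]
      types <- ifelse(loss, sample(names(gt$loss_type_probs), 2,
                                   replace = TRUE,
                                   prob = gt$loss_type_probs), "intact")
      key <- sort(types)
      if (all(key == "intact")) return("intact")
      if (all(key != "intact")) {
        # homozygous for the first-sorted loss type (simplification)
        return(paste0("hom_", type_word(key[1])))
      }
      paste0("het_", type_word(key[key != "intact"][1]))
    }, character(1))
  }

  partner_id <- family$hard_partner_id
  lapply(seq_along(spec_ids), function(i) {
    alleles <- lapply(family$genes, function(g)
      list(new_allele("intact"), new_allele("intact")))
    names(alleles) <- names(family$genes)
    pair <- allele_pair_for_class(classes[i], gt)
    pair <- lapply(pair, realize_allele, family = family, target = target,
                   partner_id = partner_id)
    alleles[[target]] <- pair
    structure(list(specimen_id = spec_ids[i], region = regions[i],
                   genotype_class = classes[i], alleles = alleles),
              class = "GenotypeSpec")
  })
}

type_word <- function(t) switch(t, deleted = "deletion", fusion = "fusion",
                                frameshift = "frameshift",
                                divergent = "divergent", t)

# attach validated parameters / realized edits to an allele
realize_allele <- function(allele, family, target, partner_id) {
  gene <- family$genes[[target]]
  if (allele$type == "fusion") {
    allele$partner_gene_id <- allele$partner_gene_id %||% partner_id
    if (is.null(allele$partner_gene_id) || is.na(allele$partner_gene_id) ||
        !allele$partner_gene_id %in% names(family$genes))
      stop("configuration error: fusion partner gene not in family")
    p_ex <- nrow(family$genes[[allele$partner_gene_id]]$exons)
    if (allele$breakpoint_exon < 1L || allele$breakpoint_exon > p_ex ||
        allele$breakpoint_exon >= nrow(gene$exons))
      stop("configuration error: fusion breakpoint exon out of range")
  }
  if (allele$type == "frameshift") {
    if (allele$indel_length %% 3L == 0L)
      stop("configuration error: frameshift indel length is a multiple of 3")
    allele$edit <- choose_frameshift_edit(family, target, allele$exon_index,
                                          allele$indel_length)
  }
  if (allele$type == "divergent") {
    allele$edits <- draw_divergent_edits(family, target,
                                         allele$substitution_rate)
  }
  allele
}

# Pick an insertion (offset within the exon, inserted bases) whose edited
# spliced CDS hits a premature stop strictly before the final
# metalloproteinase-domain exon. Deterministic scan over offsets and
# insertion strings; the edited suffix alone is translated (the unedited
# prefix is stop-free by construction).
choose_frameshift_edit <- function(family, gene_id, exon_index, indel_length) {
  gene <- family$genes[[gene_id]]
  exlen <- gene$exons$end[1] - gene$exons$start[1]
  dom_ex <- gene$exons$exon_index[gene$exons$domain_label ==
                                    "metalloproteinase"]
  last_dom <- max(dom_ex)
  tx <- gene$transcript_seq
  ex_off <- (exon_index - 1L) * exlen          # transcript offset of the exon
  stop_aa_limit <- ((last_dom - 1L) * exlen) %/% 3L
  base_sets <- list("1" = c("T", "A", "G", "C"))
  ins_cands <- if (indel_length %in% c(1L, 2L)) {
    combos <- expand.grid(rep(list(c("T", "A", "G", "C")), indel_length),
                          stringsAsFactors = FALSE)
    apply(combos, 1L, paste, collapse = "")
  } else strrep(c("T", "A", "G", "C"), indel_length)
  for (off in seq(9L, exlen - 9L)) {
    for (ins in ins_cands) {
      suffix <- paste0(substr(tx, ex_off + 1L, ex_off + off), ins,
                       substr(tx, ex_off + off + 1L, nchar(tx)))
      aa <- tl_translate(suffix)
      stop_pos <- regexpr("*", aa, fixed = TRUE)
      if (stop_pos > 0 &&
          ex_off %/% 3L + stop_pos <= stop_aa_limit)
        return(list(exon_offset = off, bases = ins))
    }
  }
  stop("could not construct a premature-stop frameshift edit")
}

draw_divergent_edits <- function(family, gene_id, rate) {
  gene <- family$genes[[gene_id]]
  n_cod <- nchar(gene$transcript_seq) %/% 3L
  hit <- which(runif(n_cod) < rate)
  hit <- hit[hit > 1L]
  if (length(hit) == 0L) hit <- 2L                  # at least one substitution
  data.frame(codon_index = hit,
             new_codon = vapply(hit, function(i) {
               old <- substr(gene$transcript_seq, 3L * i - 2L, 3L * i)
               old_aa <- GENETIC_CODE_SENSE[[old]]
               codon_for_aa(sample(setdiff(AA_ALPHABET20, old_aa), 1L))
             }, character(1)))
}

# ---------------------------------------------------------------------------
# haplotype construction

#' Build the haplotype sequence carried by one allele
#'
#' Returns the genomic sequence of a gene locus as carried by a given allele,
#' with any fusion/frameshift/divergence edits applied verbatim, plus the
#' exon coordinates on that haplotype. Deleted alleles return `NULL`.
#'
#' @param family A `FamilyReference`.
#' @param gene_id Gene whose locus the haplotype spans.
#' @param allele One allele entry from a `GenotypeSpec`.
#' @return `NULL` for a deleted allele, otherwise a list with `seq`,
#'   `exons` (0-based half-open, relative to the haplotype) and `allele_type`.
#' @export
build_haplotype <- function(family, gene_id, allele) {
  gene <- family$genes[[gene_id]]
  locus <- gene$locus_interval
  rel_exons <- data.frame(exon_index = gene$exons$exon_index,
                          start = gene$exons$start - locus[1],
                          end = gene$exons$end - locus[1])
  base_seq <- substr(family$reference_seq, locus[1] + 1L, locus[2])
  switch(allele$type,
    deleted = NULL,
    intact = list(seq = base_seq, exons = rel_exons, allele_type = "intact"),
    divergent = {
      s <- base_seq
      exlen <- rel_exons$end[1] - rel_exons$start[1]
      cpe <- exlen %/% 3L
      for (k in seq_len(nrow(allele$edits))) {
        ci <- allele$edits$codon_index[k]
        ex <- (ci - 1L) %/% cpe + 1L
        within <- (ci - 1L) %% cpe
        p <- rel_exons$start[ex] + 3L * within       # 0-based codon start
        substr(s, p + 1L, p + 3L) <- allele$edits$new_codon[k]
      }
      list(seq = s, exons = rel_exons, allele_type = "divergent")
    },
    frameshift = {
      ex <- allele$exon_index
      ins_at <- rel_exons$start[ex] + allele$edit$exon_offset   # 0-based
      ins <- allele$edit$bases
      s <- paste0(substr(base_seq, 1L, ins_at), ins,
                  substr(base_seq, ins_at + 1L, nchar(base_seq)))
      sh <- nchar(ins)
      exons <- rel_exons
      exons$end[ex] <- exons$end[ex] + sh
      if (ex < nrow(exons)) {
        idx <- (ex + 1L):nrow(exons)
        exons$start[idx] <- exons$start[idx] + sh
        exons$end[idx] <- exons$end[idx] + sh
      }
      list(seq = s, exons = exons, allele_type = "frameshift")
    },
    fusion = {
      partner <- family$genes[[allele$partner_gene_id]]
      b <- allele$breakpoint_exon
      p_locus <- partner$locus_interval
      p_seq <- substr(family$reference_seq, p_locus[1] + 1L, p_locus[2])
      cut_donor <- partner$exons$end[b] - p_locus[1]
      cut_target <- gene$exons$end[b] - locus[1]
      s <- paste0(substr(p_seq, 1L, cut_donor),
                  substr(base_seq, cut_target + 1L, nchar(base_seq)))
      # identical exon layout across the shared exon range keeps coordinates
      # parallel, so the target's relative exon frame applies to the chimera
      list(seq = s, exons = rel_exons, allele_type = "fusion",
           donor_gene_id = allele$partner_gene_id, breakpoint_exon = b)
    },
    stop("unknown allele type: ", allele$type))
}

#' Ground-truth final status per gene and specimen
#'
#' The status the integrated pipeline is expected to recover, derived from
#' the genotypes alone. Heterozygous carriers with one functional allele are
#' `EXPRESSED` (loss is recessive at the phenotype level).
#'
#' @param family A `FamilyReference`.
#' @param genotypes Output of [assign_genotypes()].
#' @return data.frame with `specimen_id`, `gene_id`, `true_status`.
#' @export
truth_gene_status <- function(family, genotypes) {
  do.call(rbind, lapply(genotypes, function(g) {
    st <- vapply(names(family$genes), function(gid) {
      types <- vapply(g$alleles[[gid]], `[[`, character(1), "type")
      if (any(types %in% c("intact", "divergent"))) return("EXPRESSED")
      if (any(types == "fusion")) return("LOST_FUSION")
      if (any(types == "frameshift")) return("LOST_DISRUPTED")
      "LOST_DELETED"
    }, character(1))
    data.frame(specimen_id = g$specimen_id, region = g$region,
               gene_id = names(family$genes), true_status = unname(st))
  }))
}
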