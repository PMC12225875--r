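#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data generator.
#' The default ("desk-scale") configuration emulates the structure of a
#' rattlesnake SVMP gene complex at a size where a full study simulates in
#' seconds: 8 paralogs on one ~50 kb reference contig, 8 specimens split
#' evenly between a western and an eastern cohort. The 30-gene scale of the
#' real complex is reachable via `n_genes = 30`.
#'
#' @param n_genes Number of paralogs in the family (>= 1). Exactly one gene is
#'   class P1 (metalloproteinase domain only; the focal gene whose loss the
#'   pipeline detects) and one P3 gene adjacent to it is the capture control.
#' @param n_specimens_west,n_specimens_east Cohort sizes.
#' @param identity_mean,identity_sd Target mean pairwise protein identity
#'   between paralogs and its spread (per-gene divergence jitter).
#' @param identity_band Accepted band for realized pairwise protein
#'   identities; generation fails if the band is infeasible.
#' @param exon_length Exon length in nucleotides (codon-aligned; multiple of 3).
#' @param intron_length,spacer_length Intron and intergenic spacer lengths.
#' @param abundance_tpm Per-gene expression on a transcripts-per-million-like
#'   scale; scalar (recycled) or vector of length `n_genes`.
#' @param peptide_depth Expected total peptide-spectrum counts per gene in a
#'   diploid expressing specimen.
#' @param contamination_rate Fraction of a donor specimen's per-peptide
#'   expectation leaked into every other specimen (instrument carry-over).
#' @param transcript_depth Expected per-position short-read depth over an
#'   expressed transcript (diploid).
#' @param hard_region_factor Multiplier on depth inside "hard" near-identical
#'   paralog segments, where unambiguous mapping mostly fails.
#' @param capture_depth Expected targeted-capture depth at diploid dosage.
#' @param capture_noise Reserved for future over-dispersion; depth is Poisson.
#' @param bait_spacing Capture bait spacing in nucleotides; capture depth is
#'   simulated per bait window of this size (default 125).
#' @param min_peptide_length Tryptic peptides shorter than this are kept in
#'   digests but excluded from matching.
#' @param genotypes Genotype-assignment specification, see
#'   [genotype_preset()]. Defaults to the `"atrox_like"` preset.
#' @param seed Integer seed; every simulation operation derives its RNG stream
#'   from it.
#'
#' @return A list of class `"toxinloss_config"`.
#' @export
simulation_config <- function(n_genes = 8L,
                              n_specimens_west = 4L,
                              n_specimens_east = 4L,
                              identity_mean = 0.75,
                              identity_sd = 0.03,
                              identity_band = c(0.55, 0.97),
                              exon_length = 120L,
                              intron_length = 300L,
                              spacer_length = 800L,
                              abundance_tpm = 1000,
                              peptide_depth = 600,
                              contamination_rate = 0.001,
                              transcript_depth = 200,
                              hard_region_factor = 0.02,
                              capture_depth = 40,
                              capture_noise = 0,
                              bait_spacing = 125L,
                              min_peptide_length = 6L,
                              genotypes = genotype_preset("atrox_like"),
                              seed = 1L) {
  stopifnot(n_genes >= 1L, exon_length %% 3L == 0L, exon_length > 0L,
            intron_length > 0L, spacer_length > 0L, bait_spacing > 0L,
            peptide_depth > 0, transcript_depth > 0, capture_depth > 0)
  if (contamination_rate < 0 || contamination_rate > 1)
    stop("contamination_rate must be in [0, 1]")
  if (hard_region_factor < 0 || hard_region_factor > 1)
    stop("hard_region_factor must be in [0, 1]")
  if (identity_mean <= 0 || identity_mean >= 1)
    stop("identity_mean must be in (0, 1)")
  if (identity_band[1] >= identity_band[2])
    stop("identity_band must be an increasing pair")
  abundance_tpm <- rep_len(abundance_tpm, n_genes)
  structure(list(
    n_genes = as.integer(n_genes),
    n_specimens_west = as.integer(n_specimens_west),
    n_specimens_east = as.integer(n_specimens_east),
    identity_mean = identity_mean, identity_sd = identity_sd,
    identity_band = identity_band,
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    spacer_length = as.integer(spacer_length),
    abundance_tpm = abundance_tpm,
    peptide_depth = peptide_depth,
    contamination_rate = contamination_rate,
    transcript_depth = transcript_depth,
    hard_region_factor = hard_region_factor,
    capture_depth = capture_depth, capture_noise = capture_noise,
    bait_spacing = as.integer(bait_spacing),
    min_peptide_length = as.integer(min_peptide_length),
    genotypes = genotypes,
    seed = as.integer(seed)
  ), class = "toxinloss_config")
}

#' Genotype-assignment presets
#'
#' Two assignment modes are supported. `"counts"` mode places an exact,
#' configured number of each mutation class on the focal (P1) gene among the
#' specimens of each cohort (placement shuffled under the seed). In
#' `"frequency"` mode each focal-gene allele is independently drawn as a loss
#' allele with a cohort-specific probability and the loss type is then drawn
#' from `loss_type_probs`.
#'
#' Presets:
#' * `"all_intact"` — every allele of every gene intact.
#' * `"atrox_like"` — the default study condition: the western cohort carries
#'   two homozygous deletions, one heterozygous deletion and one homozygous
#'   chimeric fusion of the focal gene; the eastern cohort carries one
#'   heterozygous frameshift (an expressing carrier) and is otherwise intact.
#'
#' @param name Preset name, `"atrox_like"` or `"all_intact"`.
#' @return A list describing the genotype assignment.
#' @export
genotype_preset <- function(name = c("atrox_like", "all_intact")) {
  name <- match.arg(name)
  if (name == "all_intact") {
    return(list(mode = "counts", preset = "all_intact",
                west = list(), east = list(),
                fusion_breakpoint_exon = 10L,
                frameshift_exon = 10L, frameshift_indel = 1L))
  }
  list(mode = "counts", preset = "atrox_like",
       west = list(hom_deletion = 2L, het_deletion = 1L, hom_fusion = 1L),
       east = list(het_frameshift = 1L),
       fusion_breakpoint_exon = 10L,
       frameshift_exon = 10L, frameshift_indel = 1L)
}

#' Frequency-mode genotype specification
#'
#' @param west_loss_freq,east_loss_freq Per-allele probability that a focal
#'   gene allele is a loss allele in each cohort.
#' @param loss_type_probs Named probabilities over loss allele types
#'   (`deleted`, `fusion`, `frameshift`); must sum to 1.
#' @inheritParams genotype_preset
#' @export
genotype_frequencies <- function(west_loss_freq = 0.6, east_loss_freq = 0.1,
                                 loss_type_probs = c(deleted = 0.7,
                                                     fusion = 0.15,
                                                     frameshift = 0.15)) {
  stopifnot(west_loss_freq >= 0, west_loss_freq <= 1,
            east_loss_freq >= 0, east_loss_freq <= 1,
            abs(sum(loss_type_probs) - 1) < 1e-9)
  list(mode = "frequency",
       west_loss_freq = west_loss_freq, east_loss_freq = east_loss_freq,
       loss_type_probs = loss_type_probs,
       fusion_breakpoint_exon = 10L,
       frameshift_exon = 10L, frameshift_indel = 1L)
}
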