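---
title: "Calling toxin gene loss and its mechanism in a paralogous venom gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling toxin gene loss and its mechanism in a paralogous venom gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxinloss)
```

## The problem

Snake venom metalloproteinases (SVMPs) form large tandem arrays of
paralogs — in a rattlesnake complex, up to ~30 genes over ~1.2 Mb — that are
so similar to one another that every standard assay becomes ambiguous:
peptides map to several proteins, short RNA-seq reads map to several
transcripts, and capture reads map to several loci. Against that background,
`toxinloss` answers a deceptively simple question per specimen and per gene:
*is this gene present and expressed, and if not, what broke it?* The three
inactivation mechanisms it distinguishes are whole-gene deletion (homozygous
or heterozygous), chimeric gene fusion with a paralog, and frameshift
disruption, and it tests whether loss of the focal gene is associated with
the geographic origin of the specimens.

No single evidence layer can carry that call on its own; the package
implements one module per layer and a fusion rule on top.

## Proteomic layer: exclusive-unique peptides and domain coverage

A detected tryptic peptide is attributed to a gene only when its sequence
occurs in exactly one member of the family proteome (an *exclusive-unique
peptide*, EUP). Matching is exact substring matching of identified peptide
strings: missed cleavages, I/L equivalence and modifications belong to the
upstream search engine, which is out of scope here. Digestion cleaves
C-terminal to K or R except before P, with no missed cleavages; peptides
shorter than 6 residues (configurable) are kept in the digest but never
matched.

Presence calls are then made on the protease (metalloproteinase) domain
only, and only on its *assignable* positions — those overlapped by at least
one theoretical EUP of the gene. Segments conserved between paralogs
generate no EUPs and are excluded from the denominator, so a gene is never
penalised for being undetectable where detection is impossible. The
classifier resolves the strongly bimodal coverage seen in practice (well
under half the domain covered at trace counts, versus >90% covered at high
counts) into four states:

* `NOT_DETECTED` — no EUP at all;
* `PARTIAL_LOW` — coverage < 0.50 *and* mean EUP count < 2;
* `EXPRESSED` — coverage > 0.90 *and* mean EUP count >= 5;
* `INTERMEDIATE` — anything else, reported rather than coerced, because the
  regime between the two observed modes should be looked at, not guessed.

The count thresholds (2 and 5) are operational defaults — the underlying
observation is relative ("extremely low" versus abundant) — and are exposed
in `protein_state_thresholds()`.

## Transcript layer: separating low expression from no full-length transcript

Zero coverage on a reference transcript is not, by itself, evidence of
absence: near-identical paralog segments (in this family, a pair of exons
carried almost verbatim by two genes) lose essentially all unambiguously
mapped reads, so even strong expressors show a dip there. The package
therefore learns a *mappability mask* from the data: specimens in the top
half of total mapped counts for the transcript (minimum one) are taken as
high expressors, and a position is masked when every high expressor shows at
most `low_depth_threshold` reads per `ref_depth` units of its own median
transcript depth — by default, at or below 10% of the specimen median. The
masked-fraction rule is an operational choice: the qualitative signature it
encodes is "depressed even where expression is high".

Three votes are then combined per gene and specimen:

1. **Short reads** — `NO_FULL_LENGTH` if any zero-coverage run (>= 10 bp)
   lies wholly outside the mask; `INCONCLUSIVE` if all zero runs are inside
   it (the specimen may simply express at low level); `SUPPORTS_FULL` if
   there are none. A run that only partially overlaps the mask is treated as
   inconclusive rather than as absence evidence — the conservative reading.
2. **Tiling** — assembled transcript fragments must overlap every coding
   exon and span every adjacent exon junction with consecutive alignment
   blocks.
3. **Isoforms** — long reads are clustered with the standard full-length
   non-concatemer tolerances: merge two reads when the 5' starts differ by
   < 100 bp, the 3' ends by < 30 bp, and every internal block-structure
   difference is < 10 bp. Clusters are connected components of that
   relation (order-independent; transitive chains merge — the criteria
   themselves do not specify chain handling, and components are the only
   order-free choice). Each cluster collapses to its longest member, with
   no polishing. A gene has isoform support when some cluster consensus
   overlaps all of its coding exons.

The final rule: `FULL_LENGTH` iff an isoform is observed, or tiling passes
and short reads do not positively contradict it. Isoforms can rescue a
failed tiling vote — high expressors sometimes assemble poorly — but when no
long-read data exist the isoform vote is ignored and an inconclusive
short-read vote with no tiling resolves to `NO_FULL_LENGTH`.

## Genomic layer: capture ratios and contig annotation

Targeted capture gives a per-locus depth that is meaningful only relative to
a control: the adjacent, never-lost P3 gene serves as the within-specimen
denominator. The copy-state bands on the target/control ratio are
operational (the underlying data are qualitative "zero or low coverage"):
<= 0.05 homozygous deletion, 0.30–0.70 heterozygous, >= 0.80 intact, and
anything between is reported `AMBIGUOUS_RATIO` rather than forced. A zero
control mean is a capture failure (`NO_DATA`), never a deletion call.

Assembled contigs are annotated at exon level against the family exon
library in three phases: exact matches first (one dictionary search per
contig; a contig fully explained as an unmutated haplotype stops there),
then a substitution-tolerant scan (up to 15% of the exon length) for exons
without an exact hit, then an indel-tolerant scan restricted to the window
where a missing exon is expected given its called neighbours. Amino-acid
identity is computed on the translated called segment; overlapping
candidates are resolved by identity then alignment length, and exact ties
across genes — the near-identical exon pair — are reported as *ambiguous*
calls rather than assigned to either gene. The identity floor for any call
is 0.60, matching the weakest informative exon match the method must
tolerate; pairwise alignments use the Biostrings local aligner with
BLOSUM62.

On top of the exon calls:

* **Fusion** — a maximal run of >= 2 unambiguous calls to one non-target
  gene, each at identity >= 0.90, adjacent (ignoring ambiguous calls) to a
  target-gene call or the contig boundary, on a contig that also carries
  target exons. A single stray paralog call is never a fusion.
* **Frameshift** — an exon call in the protease domain (before its final
  exon) whose segment length shifts the frame or whose translation stops;
  split half-matches of one exon around an indel are merged first so the
  shift is visible, and the spliced chain downstream of the damage is
  translated to confirm the premature stop.
* **Divergent allele** — at least two exon calls in the identity band
  [0.60, 0.98) with no frame damage. The 0.98 ceiling reflects that
  same-gene matches sit at or above 98% identity; below that band lies
  paralog territory.

Contig evidence overrides the ratio call: a fusion or frameshift found on
any haplotype contig determines the locus state.

## Integration and the association test

The fusion rule is deliberately conservative and ordered: protein expressed
plus full-length transcript is `EXPRESSED` regardless of carried alleles
(heterozygous deletion/fusion/frameshift carriers are phenotypically
expressing; the note records the carried allele); then mechanism states
(`LOST_DELETED`, `LOST_FUSION`, `LOST_DISRUPTED`) require the corresponding
locus evidence with absent or partial protein; protein and transcript both
absent over an apparently intact locus is `SILENCED_UNEXPLAINED`; every
remaining combination is `CONFLICT`. Nothing is silently coerced, and a
specimen with a homozygous deletion can never be reported `EXPRESSED`.

Geographic association uses the 2x2 table of cohort (west/east) against
focal-gene status (low/undetected vs detected) and the continuity-corrected
chi-squared statistic

$$\chi^2 = \frac{N\,(\max(|ad-bc| - N/2,\,0))^2}{(a+b)(c+d)(a+c)(b+d)},\qquad df = 1,$$

with the upper-tail p-value. The correction is used because it reproduces
the published statistic on the published table (7.73 on counts 7, 1, 4, 15;
uncorrected the same table gives ~10.3); the uncorrected variant sits behind
`correct = FALSE`. On that table the formula evaluates to 7.727, consistent
with both published roundings (7.73 and 7.72). When an antibody (blot) label
table is supplied, its weak/undetected labels override the pipeline
phenotype — band intensity is the phenotype the survey measured. p-values
are reported, never used for automated decisions; there is exactly one
pre-specified test, so no multiplicity control.

## The synthetic-data generator

All validation runs on synthetic studies that reproduce the statistical
structure the analysis assumes, with ground truth attached. Design choices,
fixed once:

* **Scale.** Desk scale is 8 genes on one ~50 kb forward-strand contig and
  8 specimens (4 west, 4 east); the 30-gene scale remains available via
  `n_genes`. Exons are 120 nt and codon-aligned, introns 300 nt, spacers
  800 nt: exon length is a simplification that keeps every exon in frame 0
  and makes frame arithmetic exact, and nothing downstream depends on it.
* **Classes.** One P1 gene (signal/pro/protease domains only; 12 exons) is
  the focal gene; P2 adds a disintegrin domain (14 exons); P3 adds
  disintegrin and cysteine-rich domains (16 exons). One P3 gene adjacent to
  the focal gene is the capture control and is never mutated.
* **Divergence.** Paralogs descend from one simulated ancestral CDS with
  per-gene amino-acid divergence targeting mean pairwise identity 0.75
  (realized identities are checked against the configured band and the
  build fails rather than drift). The hard region is made by copying the
  focal gene's exons 3–4 verbatim into a P2 partner — the direct analog of
  the near-identical exon pair that defeats read mapping in the real
  complex.
* **Genotypes.** The default study condition places, on the focal gene: two
  homozygous deletions, one heterozygous deletion and one homozygous fusion
  in the west, and one heterozygous frameshift (an expressing carrier) in
  the east. A frequency mode draws loss alleles per cohort probability
  instead. Fusion haplotypes are donor exons 1–10 followed by target exons
  11–12; frameshift alleles carry a 1-nt insertion in exon 10 whose edited
  spliced CDS is verified at construction to stop before the final protease
  exon.
* **Evidence.** Peptide counts are Poisson with expectation proportional to
  abundance x protein-producing dosage, split evenly over the usable
  digest; contamination adds a fixed fraction (default 0.1% — a free
  parameter, as the real carry-over rate is not quantified) of every other
  specimen's expectation. Fusion and frameshift products are modeled as
  undetectable in venom (truncated or chimeric protein), while frameshift
  alleles still transcribe fully and fusion alleles transcribe only the
  target-derived exons downstream of the breakpoint. Transcript depth is
  Poisson per position with hard-region positions depressed to 2% of the
  combined expectation of both near-identical copies; capture depth is
  Poisson per 125-nt bait window at `capture_depth` x dosage / 2. Contigs
  are the literal haplotype sequences, deduplicated.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level sequencing error and quality,
alignment and assembly artifacts beyond coordinate-level evidence,
incomplete deletions that relocate exons near active regulatory sequence,
index hopping (contamination is modeled as a uniform leak), UTR/TSS
variation among isoforms, and real spectral identification error. The
simulated hard region is a single verbatim copy; real families grade from
98% to 60% identity across many segments.

## Problem sizes and reproducibility

The shipped validation (`scripts/acceptance.R`, `tests/testthat/`) scores
20 independent desk-scale simulations — 1,280 gene-by-specimen cells — for
status accuracy (>= 95% required; in practice it is essentially exact),
exact recovery of every constructed fusion (donor and breakpoint) and
frameshift (first affected exon), and zero fusion calls on non-fusion
haplotypes. Oracle suites check the EUP classifier against a brute-force
substring scan, the digest against a pattern-scan oracle, the aligner-based
identities against a hand-rolled Needleman–Wunsch, and the chi-squared
statistic against `stats::chisq.test` to 1e-9. Identical configuration and
seed give byte-identical output files; every emitted file reparses into the
structures that generated it.

## Known limitations

Annotation sensitivity bottoms out at ~15% nucleotide divergence per exon
(more divergent exons are reported only when anchored by called neighbours),
strand handling is out of scope (everything is forward-strand), the
heterozygosity band on capture ratios is an operational stand-in for what
the source material infers from combined blot and coverage evidence, and
`INTERMEDIATE`/`AMBIGUOUS_RATIO`/`CONFLICT` states are surfaced for human
review rather than resolved automatically.
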