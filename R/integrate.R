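# Evidence fusion and the geography association test.

LOSS_STATES <- c("LOST_DELETED", "LOST_FUSION", "LOST_DISRUPTED",
                 "SILENCED_UNEXPLAINED")

#' Fuse the three evidence layers into one gene status
#'
#' Decision rules, in order:
#' 1. `EXPRESSED` — protein expressed and a full-length transcript is
#'    supported. Heterozygous carriers of a deletion, fusion or frameshift
#'    allele land here (loss is recessive); the mechanism note records the
#'    carried allele.
#' 2. `LOST_DELETED` — homozygous deletion, or heterozygous deletion with
#'    absent/partial protein.
#' 3. `LOST_FUSION` — chimeric locus without expressed protein.
#' 4. `LOST_DISRUPTED` — frameshift-disrupted locus without expressed
#'    protein.
#' 5. `SILENCED_UNEXPLAINED` — protein and transcript both absent yet the
#'    locus looks intact: a real conflict worth flagging, not forcing.
#' 6. `CONFLICT` — any remaining combination (never silently coerced).
#'
#' @param expression `expression_state` from [call_expression_states()].
#' @param transcript `transcript_final` from [call_transcript_states()].
#' @param locus `locus_state` from [call_locus_states()]; `NA` allowed.
#' @return List with `final` and `mechanism_note`.
#' @export
call_gene_status <- function(expression, transcript, locus) {
  locus <- if (is.na(locus)) "NO_DATA" else locus
  prot_absent <- expression %in% c("NOT_DETECTED", "PARTIAL_LOW")
  note <- sprintf("protein=%s transcript=%s locus=%s", expression,
                  transcript, locus)
  if (expression == "EXPRESSED" && transcript == "FULL_LENGTH") {
    carrier <- switch(locus, HET_DELETION = "het deletion carrier",
                      FRAMESHIFT = "frameshift allele carrier",
                      FUSION = "fusion allele carrier",
                      DIVERGENT_ALLELE = "divergent allele carrier", NULL)
    return(list(final = "EXPRESSED",
                note = paste(c(note, carrier), collapse = "; ")))
  }
  if (locus == "HOM_DELETION" || (locus == "HET_DELETION" && prot_absent))
    return(list(final = "LOST_DELETED", note = note))
  if (locus == "FUSION" && expression != "EXPRESSED")
    return(list(final = "LOST_FUSION", note = note))
  if (locus == "FRAMESHIFT" && (prot_absent ||
                                expression == "INTERMEDIATE"))
    return(list(final = "LOST_DISRUPTED", note = note))
  if (prot_absent && transcript == "NO_FULL_LENGTH" &&
      locus %in% c("INTACT", "NO_DATA", "DIVERGENT_ALLELE"))
    return(list(final = "SILENCED_UNEXPLAINED", note = note))
  list(final = "CONFLICT", note = note)
}

#' Continuity-corrected chi-squared test for a 2x2 table
#'
#' The statistic is `N * (max(|ad - bc| - N/2, 0))^2 /
#' ((a+b)(c+d)(a+c)(b+d))` with the Yates continuity correction floored at
#' zero, compared against the chi-squared distribution with one degree of
#' freedom (upper tail). The uncorrected statistic is available with
#' `correct = FALSE`.
#'
#' @param a,b,c,d Cell counts: rows are cohorts (e.g. west/east), columns
#'   are target-gene status (low/undetected, detected).
#' @param correct Apply the continuity correction (default TRUE).
#' @return List of class `ContingencyResult`: `table` (2x2 matrix), `chi2`,
#'   `df = 1`, `p`, `correct`.
#' @export
yates_chi_squared <- function(a, b, c, d, correct = TRUE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  n <- a + b + c + d
  margins <- c("row1 (a+b)" = a + b, "row2 (c+d)" = c + d,
               "col1 (a+c)" = a + c, "col2 (b+d)" = b + d)
  if (any(margins == 0))
    stop("undefined statistic: zero margin in ",
         paste(names(margins)[margins == 0], collapse = ", "))
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(dev - n / 2, 0)
  chi2 <- n * dev^2 / prod(margins)
  structure(list(table = matrix(c(a, c, b, d), 2, 2,
                                dimnames = list(cohort = c("row1", "row2"),
                                                status = c("low", "detected"))),
                 chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 correct = correct),
            class = "ContingencyResult")
}

#' Test geographic association of target-gene loss
#'
#' Builds the 2x2 table — rows west/east, columns low/undetected vs
#' detected — and applies [yates_chi_squared()]. Loss phenotypes from the
#' pipeline are the `LOST_*` and `SILENCED_UNEXPLAINED` finals; when a
#' per-specimen antibody (blot) label table is supplied it overrides the
#' pipeline phenotype (`weak`/`undetected` count as low).
#'
#' @param statuses data.frame with `specimen_id`, `gene_id`, `final` (from
#'   [run_pipeline()] / [call_gene_status()]); may be `NULL` when `labels`
#'   are given.
#' @param specimens data.frame with `specimen_id`, `region`
#'   (`"west"`/`"east"`).
#' @param target_gene Gene tested for association.
#' @param labels Optional data.frame with `specimen_id`, `label` in
#'   `detected`/`weak`/`undetected`.
#' @param correct Continuity correction, default TRUE.
#' @return A `ContingencyResult` with an added `counts` entry
#'   (a = west low, b = west detected, c = east low, d = east detected).
#' @export
associate_geography <- function(statuses, specimens, target_gene,
                                labels = NULL, correct = TRUE) {
  if (!all(specimens$region %in% c("west", "east")))
    stop("regions must be 'west' or 'east'")
  for (rg in c("west", "east"))
    if (sum(specimens$region == rg) < 2L)
      warning("fewer than 2 specimens in the ", rg, " cohort")
  if (!is.null(labels)) {
    low <- setNames(labels$label %in% c("weak", "undetected"),
                    labels$specimen_id)
  } else {
    st <- statuses[statuses$gene_id == target_gene, , drop = FALSE]
    low <- setNames(st$final %in% LOSS_STATES, st$specimen_id)
  }
  if (!all(specimens$specimen_id %in% names(low)))
    stop("missing status/label for specimen(s): ",
         paste(setdiff(specimens$specimen_id, names(low)), collapse = ", "))
  is_west <- specimens$region == "west"
  lw <- low[specimens$specimen_id]
  a <- sum(is_west & lw); b <- sum(is_west & !lw)
  cc <- sum(!is_west & lw); d <- sum(!is_west & !lw)
  res <- yates_chi_squared(a, b, cc, d, correct = correct)
  dimnames(res$table) <- list(cohort = c("west", "east"),
                              status = c("low_undetected", "detected"))
  res$counts <- c(a = a, b = b, c = cc, d = d)
  res
}

#' Published antibody survey of the focal P-I metalloproteinase
#'
#' The 27-specimen western-blot survey used for the geography association:
#' 7 of 8 western specimens show weak or undetected signal, 15 of 19
#' eastern specimens show clear signal. Specimen identifiers named in the
#' published survey are used where reported (weak: AZ1, AZ5, AZ8, TX5;
#' undetected: NM7, TX4, TX6; detected: TX1, TX3, NM1); the remaining
#' identifiers are positional placeholders consistent with the published
#' cohort counts.
#'
#' @return data.frame with `specimen_id`, `region`, `label`.
#' @export
blot_survey_table <- function() {
  west <- data.frame(
    specimen_id = paste0("AZ", 1:8), region = "west",
    label = c("weak", "undetected", "undetected", "undetected", "weak",
              "undetected", "detected", "weak"))
  east <- data.frame(
    specimen_id = c(paste0("NM", 1:7), paste0("TX", 1:12)), region = "east",
    label = c("detected", "detected", "detected", "detected", "detected",
              "detected", "undetected",
              "detected", "detected", "detected", "undetected", "weak",
              "undetected", "detected", "detected", "detected", "detected",
              "detected", "detected"))
  rbind(west, east)
}

#' Descriptive expression summary (TPM)
#'
#' Transcripts-per-million: counts are divided by transcript length and
#' scaled so each specimen sums to one million; reported with
#' `log2(TPM + 1)`.
#'
#' @param counts Matrix or data.frame of nonnegative counts, genes x
#'   specimens.
#' @param lengths Transcript lengths (named or positional per gene row).
#' @return data.frame with `gene_id`, `specimen_id`, `tpm`, `log2_tpm1`.
#' @export
expression_summary <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(lengths <= 0))
    stop("counts must be nonnegative and lengths positive")
  rate <- counts / lengths
  out <- list()
  for (j in seq_len(ncol(counts))) {
    tot <- sum(rate[, j])
    tpm <- if (tot > 0) rate[, j] / tot * 1e6 else {
      warning("zero total counts for specimen ", colnames(counts)[j] %||% j)
      rep(0, nrow(counts))
    }
    out[[j]] <- data.frame(
      gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
      specimen_id = colnames(counts)[j] %||% as.character(j),
      tpm = unname(tpm), log2_tpm1 = unname(log2(tpm + 1)))
  }
  do.call(rbind, out)
}
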