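# Genomic evidence from targeted capture: depth of the target locus relative
# to an adjacent control locus (copy-state), and exon-level annotation of
# assembled contigs against the family exon library to recognise chimeric
# fusions, frameshift disruptions and divergent alleles.

#' Summarize capture coverage of a target locus against a control locus
#'
#' @param target_depth,control_depth Integer depth vectors over the two gene
#'   intervals.
#' @param gene_id,specimen_id,control_gene_id Labels carried into the result.
#' @return List of class `LocusCoverageSummary` with `mean_depth_target`,
#'   `mean_depth_control` and `ratio` (`NA` with `no_data = TRUE` when the
#'   control mean is zero — a capture failure, not a deletion).
#' @export
summarize_locus_coverage <- function(target_depth, control_depth,
                                     gene_id = NA_character_,
                                     specimen_id = NA_character_,
                                     control_gene_id = NA_character_) {
  mt <- mean(target_depth); mc <- mean(control_depth)
  structure(list(gene_id = gene_id, specimen_id = specimen_id,
                 control_gene_id = control_gene_id,
                 mean_depth_target = mt, mean_depth_control = mc,
                 ratio = if (mc > 0) mt / mc else NA_real_,
                 no_data = mc <= 0),
            class = "LocusCoverageSummary")
}

#' Copy-state thresholds
#'
#' Operational bands on the target/control depth ratio. Ratios falling in
#' the gaps between bands are reported `AMBIGUOUS_RATIO`, never forced into
#' a state.
#'
#' @param hom_max Ratio at or below which the locus is homozygously deleted.
#' @param het_band Two-sided band for a heterozygous deletion.
#' @param intact_min Ratio at or above which the locus is intact (diploid).
#' @export
copy_state_thresholds <- function(hom_max = 0.05, het_band = c(0.30, 0.70),
                                  intact_min = 0.80) {
  list(hom_max = hom_max, het_band = het_band, intact_min = intact_min)
}

#' Call copy state from a coverage summary
#'
#' @param summary A `LocusCoverageSummary`.
#' @param thresholds A [copy_state_thresholds()] list.
#' @return `"HOM_DELETION"`, `"HET_DELETION"`, `"INTACT"`,
#'   `"AMBIGUOUS_RATIO"` or `"NO_DATA"`.
#' @export
call_copy_state <- function(summary, thresholds = copy_state_thresholds()) {
  if (isTRUE(summary$no_data) || is.na(summary$ratio)) return("NO_DATA")
  r <- summary$ratio
  if (r <= thresholds$hom_max) return("HOM_DELETION")
  if (r >= thresholds$het_band[1] && r <= thresholds$het_band[2])
    return("HET_DELETION")
  if (r >= thresholds$intact_min) return("INTACT")
  "AMBIGUOUS_RATIO"
}

# ---------------------------------------------------------------------------
# contig exon annotation

#' Family exon library
#'
#' Every gene's coding exons, nucleotide and translated (exons are
#' codon-aligned so each translates in frame 0).
#'
#' @param family A `FamilyReference`.
#' @return data.frame with `gene_id`, `exon_index`, `nt`, `aa`, and
#'   `rel_start`/`rel_end` (exon position relative to its locus start, used
#'   to project expected exon windows on a contig).
#' @export
exon_library <- function(family) {
  out <- do.call(rbind, lapply(family$genes, function(g) {
    nt <- substring(family$reference_seq, g$exons$start + 1L, g$exons$end)
    data.frame(gene_id = g$gene_id, exon_index = g$exons$exon_index,
               nt = nt, aa = vapply(nt, tl_translate, character(1),
                                    USE.NAMES = FALSE),
               rel_start = g$exons$start - g$locus_interval[1],
               rel_end = g$exons$end - g$locus_interval[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Prebuilt exact-match index over an exon library
#'
#' Groups the library by exon width and builds one `PDict` per group so the
#' exact-match phase of [annotate_contig_exons()] costs one `matchPDict()`
#' call per contig instead of one search per exon.
#'
#' @param library Output of [exon_library()].
#' @return Named list (by width) of `list(idx, pdict)`.
#' @export
exon_search_index <- function(library) {
  lib_len <- nchar(library$nt)
  out <- list()
  for (w in unique(lib_len)) {
    idx <- which(lib_len == w)
    out[[as.character(w)]] <- list(
      idx = idx,
      pdict = Biostrings::PDict(Biostrings::DNAStringSet(library$nt[idx])))
  }
  out
}

# amino-acid identity of a contig segment against an exon translation:
# positionwise when the segment length matches the exon exactly; otherwise
# (indel-containing segment) the exon and segment are aligned at nucleotide
# level and each exon codon is compared with its aligned bases translated in
# the local frame, so a frame-shifted copy still scores by what it encodes
# rather than by a single garbled frame
aa_segment_identity <- function(contig_seq, seg_start, seg_end, exon_aa,
                                exon_nt = NULL) {
  seg <- substr(contig_seq, seg_start + 1L, seg_end)
  if (nchar(seg) == 3L * nchar(exon_aa)) {
    seg_aa <- tl_translate(seg)
    a <- strsplit(seg_aa, "")[[1]]; b <- strsplit(exon_aa, "")[[1]]
    return(mean(a == b))
  }
  if (is.null(exon_nt)) {
    seg_aa <- tl_translate(substr(seg, 1L, (nchar(seg) %/% 3L) * 3L))
    res <- align_exon_aa(exon_aa, gsub("*", "X", seg_aa, fixed = TRUE))
    return(if (is.null(res)) NA_real_ else res$identity)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(exon_nt), Biostrings::DNAString(seg),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -2),
    gapOpening = 8, gapExtension = 4)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- 0L; total <- 0L
  codon_p <- character(0); codon_s <- character(0)
  for (col in seq_along(pat)) {
    if (pat[col] == "-") next          # inserted contig base: skip
    codon_p <- c(codon_p, pat[col])
    codon_s <- c(codon_s, if (sub[col] == "-") NA_character_ else sub[col])
    if (length(codon_p) == 3L) {
      total <- total + 1L
      if (!anyNA(codon_s)) {
        aa_p <- Biostrings::GENETIC_CODE[[paste(codon_p, collapse = "")]]
        aa_s <- Biostrings::GENETIC_CODE[[paste(codon_s, collapse = "")]]
        if (identical(aa_p, aa_s)) matches <- matches + 1L
      }
      codon_p <- character(0); codon_s <- character(0)
    }
  }
  matches / max(total, 1L)
}

# amino-acid local alignment of one exon against a translated contig frame;
# returns NULL or list(identity, aa_start, aa_end) (1-based on the frame)
align_exon_aa <- function(exon_aa, frame_aa) {
  if (nchar(frame_aa) < 5L) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(exon_aa), Biostrings::AAString(frame_aa),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols < 0.5 * nchar(exon_aa)) return(NULL)
  list(identity = Biostrings::nmatch(aln) / cols,
       aa_start = BiocGenerics::start(Biostrings::subject(aln)),
       aa_end = BiocGenerics::end(Biostrings::subject(aln)),
       cols = cols)
}

# frame status of one called exon segment on the contig: indel-induced frame
# shift (segment length differs from the exon mod 3) beats stop-codon scan
call_frame_status <- function(contig_seq, seg_start, seg_end, exon_nt) {
  seg <- substr(contig_seq, seg_start + 1L, seg_end)
  shift <- (nchar(seg) - nchar(exon_nt)) %% 3L
  if (shift != 0L) return("frameshift")
  aa <- tl_translate(substr(seg, 1L, (nchar(seg) %/% 3L) * 3L))
  if (grepl("*", aa, fixed = TRUE)) return("premature_stop")
  "in_frame"
}

#' Annotate a contig with family exons
#'
#' Three-phase annotation. Exact nucleotide matches of all library exons are
#' found first; a contig fully explained as one gene's unmutated haplotype
#' stops there. Otherwise remaining exons are searched with a
#' mismatch-tolerant scan (up to 15% substitutions), and exons still missing
#' are searched with an indel-tolerant scan inside the window where the exon
#' is expected given called exons of the same gene. Amino-acid identity of
#' each called segment is computed from its translation. Overlapping
#' candidates are resolved by highest amino-acid identity, then longest
#' alignment; exact ties across genes (near-identical paralog segments) are
#' reported as ambiguous. Split matches of one exon separated by a small gap
#' (internal indel) are merged so the frame shift is visible in the merged
#' segment length.
#'
#' @param contig_seq Contig nucleotide string.
#' @param library Output of [exon_library()].
#' @param min_identity Minimum amino-acid identity for a call (default 0.60,
#'   matching the weakest informative exon match the method must tolerate).
#' @param index Optional prebuilt [exon_search_index()]; supply it when
#'   annotating many contigs against the same library.
#' @return data.frame of `ExonCall`s sorted by contig position: `start`,
#'   `end` (0-based half-open on the contig), `best_gene_id`, `exon_index`,
#'   `aa_identity`, `ambiguous`, `tied_gene_ids`, `frame_status`.
#' @export
annotate_contig_exons <- function(contig_seq, library, min_identity = 0.60,
                                  index = NULL) {
  empty <- data.frame(start = integer(), end = integer(),
                      best_gene_id = character(), exon_index = integer(),
                      aa_identity = numeric(), ambiguous = logical(),
                      tied_gene_ids = character(), frame_status = character(),
                      stringsAsFactors = FALSE)
  if (nchar(contig_seq) < min(nchar(library$nt))) return(empty)
  contig <- Biostrings::DNAString(contig_seq)
  n_lib <- nrow(library)
  lib_len <- nchar(library$nt)
  mk_cand <- function(k, s, e, ident) data.frame(
    start = s, end = e, gene_id = library$gene_id[k],
    exon_index = library$exon_index[k], aa_identity = ident,
    aln_len = nchar(library$aa[k]), stringsAsFactors = FALSE)

  # phase 1: exact hits for the whole library at once (grouped by width)
  if (is.null(index)) index <- exon_search_index(library)
  cand <- list()
  hit_any <- logical(n_lib)
  for (w in names(index)) {
    idx <- index[[w]]$idx
    mm <- Biostrings::matchPDict(index[[w]]$pdict, contig)
    counts <- S4Vectors::elementNROWS(mm)
    if (sum(counts) == 0L) next
    flat <- unlist(mm, use.names = FALSE)
    ks <- idx[rep(seq_along(idx), counts)]
    hit_any[ks] <- TRUE
    cand[[length(cand) + 1L]] <- data.frame(
      start = BiocGenerics::start(flat) - 1L, end = BiocGenerics::end(flat),
      gene_id = library$gene_id[ks], exon_index = library$exon_index[ks],
      aa_identity = 1.0, aln_len = nchar(library$aa[ks]),
      stringsAsFactors = FALSE)
  }

  # an unmutated haplotype is fully explained by phase 1: some gene has all
  # of its exons hit exactly and every exact hit coincides with one of that
  # gene's hit intervals (near-identical paralog copies land on the same
  # intervals and surface as ties); only unexplained contigs are searched
  # inexactly
  explained <- FALSE
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    for (g in unique(cd$gene_id)) {
      gi <- cd$gene_id == g
      if (length(unique(cd$exon_index[gi])) < sum(library$gene_id == g)) next
      keys_g <- unique(paste(cd$start[gi], cd$end[gi]))
      if (all(paste(cd$start, cd$end) %in% keys_g)) { explained <- TRUE; break }
    }
  }

  if (!explained) {
    # phase 2: mismatch-tolerant search (substitutions only, 15% of exon
    # length) for exons without an exact hit
    for (k in which(!hit_any)) {
      mm <- Biostrings::matchPattern(Biostrings::DNAString(library$nt[k]),
                                     contig,
                                     max.mismatch = floor(0.15 * lib_len[k]))
      for (h in seq_along(mm)) {
        s <- BiocGenerics::start(mm)[h] - 1L
        e <- BiocGenerics::end(mm)[h]
        ident <- aa_segment_identity(contig_seq, s, e, library$aa[k], library$nt[k])
        if (is.na(ident) || ident < min_identity) next
        hit_any[k] <- TRUE
        cand[[length(cand) + 1L]] <- mk_cand(k, s, e, ident)
      }
    }
    # phase 3: indel-tolerant search, restricted to the window where the
    # exon is expected from called exons of the same gene (collinearity)
    if (length(cand)) {
      cd <- do.call(rbind, cand)
      for (k in which(!hit_any)) {
        g <- library$gene_id[k]
        anchors <- cd[cd$gene_id == g, , drop = FALSE]
        if (nrow(anchors) == 0L) next
        arow <- anchors[which.min(abs(anchors$exon_index -
                                        library$exon_index[k])), ]
        a_k <- which(library$gene_id == g &
                       library$exon_index == arow$exon_index)[1]
        off <- library$rel_start[k] - library$rel_start[a_k]
        w_lo <- max(0L, arow$start + off - 50L)
        w_hi <- min(nchar(contig_seq), arow$start + off + lib_len[k] + 50L)
        if (w_hi - w_lo < lib_len[k] %/% 2L) next
        win <- Biostrings::DNAString(substr(contig_seq, w_lo + 1L, w_hi))
        mm <- Biostrings::matchPattern(
          Biostrings::DNAString(library$nt[k]), win,
          max.mismatch = floor(0.15 * lib_len[k]), with.indels = TRUE)
        for (h in seq_along(mm)) {
          s <- w_lo + BiocGenerics::start(mm)[h] - 1L
          e <- w_lo + BiocGenerics::end(mm)[h]
          ident <- aa_segment_identity(contig_seq, s, e, library$aa[k], library$nt[k])
          if (is.na(ident) || ident < min_identity) next
          cand[[length(cand) + 1L]] <- mk_cand(k, s, e, ident)
        }
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[cand$aa_identity >= min_identity, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  # overlap resolution: greedy by identity, then alignment length
  ord <- order(-cand$aa_identity, -cand$aln_len, cand$gene_id,
               cand$exon_index)
  cand <- cand[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    for (a in accepted) {
      ov <- min(cand$end[i], cand$end[a]) - max(cand$start[i], cand$start[a])
      if (ov > 0.25 * min(cand$end[i] - cand$start[i],
                          cand$end[a] - cand$start[a])) { clash <- TRUE; break }
    }
    if (!clash) accepted <- c(accepted, i)
  }
  acc <- cand[accepted, , drop = FALSE]

  # merge split matches of the same exon separated by a small unaligned gap
  # (the signature of an internal indel): the combined segment carries the
  # indel so its length difference reveals the frame shift
  acc <- acc[order(acc$gene_id, acc$exon_index, acc$start), , drop = FALSE]
  merged <- list()
  i <- 1L
  while (i <= nrow(acc)) {
    row <- acc[i, ]
    while (i < nrow(acc) &&
           acc$gene_id[i + 1L] == row$gene_id &&
           acc$exon_index[i + 1L] == row$exon_index &&
           acc$start[i + 1L] - row$end < 30L && acc$start[i + 1L] >= row$end) {
      w1 <- row$end - row$start; w2 <- acc$end[i + 1L] - acc$start[i + 1L]
      row$aa_identity <- (row$aa_identity * w1 +
                            acc$aa_identity[i + 1L] * w2) / (w1 + w2)
      row$end <- acc$end[i + 1L]
      row$aln_len <- row$aln_len + acc$aln_len[i + 1L]
      i <- i + 1L
    }
    merged[[length(merged) + 1L]] <- row
    i <- i + 1L
  }
  acc <- do.call(rbind, merged)

  # snap inexact calls to the boundaries implied by exact same-gene
  # neighbours (collinear exon layout): an approximate matcher can absorb an
  # internal indel into flanking mismatches and return an exon-width window
  # that hides the frame shift
  lib_key <- paste(library$gene_id, library$exon_index)
  for (i in seq_len(nrow(acc))) {
    key <- paste(acc$gene_id[i], acc$exon_index[i])
    k <- match(key, lib_key)
    w <- nchar(library$nt[k])
    exact_i <- acc$aa_identity[i] >= 1 - 1e-9 &&
      (acc$end[i] - acc$start[i]) == w
    if (exact_i) next
    is_anchor <- acc$gene_id == acc$gene_id[i] &
      abs(acc$aa_identity - 1) < 1e-9 &
      (acc$end - acc$start) == nchar(library$nt[match(
        paste(acc$gene_id, acc$exon_index), lib_key)])
    anchors <- acc[is_anchor, , drop = FALSE]
    prev <- anchors[anchors$exon_index < acc$exon_index[i], , drop = FALSE]
    nxt <- anchors[anchors$exon_index > acc$exon_index[i], , drop = FALSE]
    new_s <- acc$start[i]; new_e <- acc$end[i]
    if (nrow(prev)) {
      p <- prev[which.max(prev$exon_index), ]
      pk <- match(paste(p$gene_id, p$exon_index), lib_key)
      cpos <- p$end + (library$rel_start[k] - library$rel_end[pk])
      if (abs(cpos - new_s) <= 30L && cpos >= 0L) new_s <- cpos
    }
    if (nrow(nxt)) {
      nx <- nxt[which.min(nxt$exon_index), ]
      nk <- match(paste(nx$gene_id, nx$exon_index), lib_key)
      cpos <- nx$start - (library$rel_start[nk] - library$rel_end[k])
      if (abs(cpos - new_e) <= 30L && cpos <= nchar(contig_seq))
        new_e <- cpos
    }
    if ((new_s != acc$start[i] || new_e != acc$end[i]) && new_e > new_s) {
      ident <- aa_segment_identity(contig_seq, new_s, new_e,
                                   library$aa[k], library$nt[k])
      if (!is.na(ident) && ident >= min_identity) {
        acc$start[i] <- new_s; acc$end[i] <- new_e
        acc$aa_identity[i] <- ident
      }
    }
  }

  lib_nt <- setNames(library$nt, paste(library$gene_id, library$exon_index))
  out <- lapply(seq_len(nrow(acc)), function(i) {
    # exact-tie detection against all candidates on the same segment
    same <- cand$start < acc$end[i] & acc$start[i] < cand$end &
      abs(cand$aa_identity - acc$aa_identity[i]) < 1e-9 &
      (pmin(cand$end, acc$end[i]) - pmax(cand$start, acc$start[i])) >=
        0.8 * (acc$end[i] - acc$start[i])
    tied <- sort(unique(cand$gene_id[same]))
    fs <- call_frame_status(contig_seq, acc$start[i], acc$end[i],
                            lib_nt[[paste(acc$gene_id[i], acc$exon_index[i])]])
    data.frame(start = acc$start[i], end = acc$end[i],
               best_gene_id = acc$gene_id[i], exon_index = acc$exon_index[i],
               aa_identity = acc$aa_identity[i],
               ambiguous = length(tied) > 1L,
               tied_gene_ids = paste(tied, collapse = ","),
               frame_status = fs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start), , drop = FALSE]
  attr(out, "contig_seq") <- contig_seq
  out
}

#' Detect a chimeric gene fusion from exon calls
#'
#' Reports a fusion when the gene assignment along one contig contains a
#' maximal run of at least two unambiguous exon calls to a single non-target
#' gene (all at identity >= `min_run_identity`), adjacent — ignoring
#' ambiguous calls — to at least one target-gene call or to the contig
#' boundary, on a contig that also carries target-gene exons.
#'
#' @param exon_calls Output of [annotate_contig_exons()] for one contig.
#' @param target_gene Target gene id.
#' @param min_run_identity Minimum identity of every run member (default
#'   0.90).
#' @return `NULL`, or a list with `donor_gene_id`, `donor_exons`,
#'   `breakpoint` (donor exon index, following target exon index).
#' @export
detect_fusion <- function(exon_calls, target_gene, min_run_identity = 0.90) {
  calls <- exon_calls[!exon_calls$ambiguous, , drop = FALSE]
  if (nrow(calls) == 0L) return(NULL)
  if (!any(calls$best_gene_id == target_gene)) return(NULL)
  r <- rle(calls$best_gene_id)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    gid <- r$values[k]
    if (gid == target_gene || r$lengths[k] < 2L) next
    idx <- starts[k]:ends[k]
    if (any(calls$aa_identity[idx] < min_run_identity)) next
    flank_ok <- (k == 1L) || (k == length(r$values)) ||
      r$values[k - 1L] == target_gene || r$values[k + 1L] == target_gene
    if (!flank_ok) next
    nxt <- if (k < length(r$values) && r$values[k + 1L] == target_gene)
      calls$exon_index[starts[k + 1L]] else NA_integer_
    return(list(donor_gene_id = gid,
                donor_exons = calls$exon_index[idx],
                breakpoint = c(after_donor_exon = max(calls$exon_index[idx]),
                               before_target_exon = nxt)))
  }
  NULL
}

#' Detect frameshift disruption or a divergent allele from exon calls
#'
#' A disruption is reported when a target-gene exon call within the
#' metalloproteinase domain (before its final exon) carries frame damage —
#' an indel-shifted frame or a premature stop in translation. A contig whose
#' target-gene exon identities fall in `divergent_band` across at least two
#' exons, without frame damage, is labelled a divergent allele.
#'
#' @param exon_calls Output of [annotate_contig_exons()].
#' @param gene The target `GeneModel`.
#' @param divergent_band Identity band `[low, high)` interpreted as a
#'   divergent same-gene allele (default `c(0.60, 0.98)`; same-gene matches
#'   sit at or above 0.98).
#' @return `NULL`, or a list with `type` (`"FRAMESHIFT"` or
#'   `"DIVERGENT_ALLELE"`), `first_affected_exon` and `frame_status`.
#' @export
detect_disruption <- function(exon_calls, gene,
                              divergent_band = c(0.60, 0.98)) {
  target <- gene$gene_id
  calls <- exon_calls[exon_calls$best_gene_id == target |
                        (exon_calls$ambiguous &
                           grepl(paste0("(^|,)", target, "(,|$)"),
                                 exon_calls$tied_gene_ids)), , drop = FALSE]
  if (nrow(calls) == 0L) return(NULL)
  dom_ex <- gene$exons$exon_index[gene$exons$domain_label ==
                                    "metalloproteinase"]
  last_dom <- max(dom_ex)
  damaged <- calls$frame_status != "in_frame" & calls$exon_index < last_dom &
    calls$exon_index %in% dom_ex
  if (any(damaged)) {
    first <- calls[which(damaged)[1L], ]
    fs <- first$frame_status
    if (fs == "frameshift") {
      # chain-level check: splice the called segments from the damaged exon
      # onward and scan the translation for the induced premature stop
      after <- calls[calls$start >= first$start, , drop = FALSE]
      chain <- paste(substring(attr(exon_calls, "contig_seq") %||% "",
                               after$start + 1L, after$end), collapse = "")
      if (nzchar(chain) &&
          grepl("*", tl_translate(chain), fixed = TRUE))
        fs <- "premature_stop"
    }
    return(list(type = "FRAMESHIFT",
                first_affected_exon = first$exon_index,
                frame_status = fs))
  }
  unamb <- calls[!calls$ambiguous, , drop = FALSE]
  div <- unamb$aa_identity >= divergent_band[1] &
    unamb$aa_identity < divergent_band[2]
  if (sum(div) >= 2L)
    return(list(type = "DIVERGENT_ALLELE",
                first_affected_exon = min(unamb$exon_index[div]),
                frame_status = "in_frame"))
  NULL
}

#' Genomic state for every gene and specimen
#'
#' Pipeline wrapper. Copy state comes from the capture depth ratio against
#' the control locus; contigs assembled over each locus are annotated at
#' exon level and override the ratio call when they reveal a fusion,
#' frameshift or divergent allele. Contigs are attributed to loci by naming
#' convention `specimen|gene|hapN` when available, otherwise by best exact
#' placement.
#'
#' @param family A `FamilyReference`.
#' @param locus_coverage Per-specimen depth vectors over the reference.
#' @param contigs Per-specimen named character vectors of contig sequences.
#' @param thresholds A [copy_state_thresholds()] list.
#' @param min_identity Minimum exon-call identity.
#' @return List with `calls` (data.frame per specimen x gene: `ratio`,
#'   `copy_state`, `locus_state`) and `details` (per specimen x gene exon
#'   calls and fusion/disruption reports).
#' @export
call_locus_states <- function(family, locus_coverage, contigs,
                              thresholds = copy_state_thresholds(),
                              min_identity = 0.60) {
  lib <- exon_library(family)
  lib_index <- exon_search_index(lib)
  ctrl <- family$control_gene_id
  rows <- list(); details <- list()
  for (sp in names(locus_coverage)) {
    depth <- locus_coverage[[sp]]
    ctrl_depth <- if (!is.na(ctrl)) {
      loc <- family$genes[[ctrl]]$locus_interval
      depth[(loc[1] + 1L):loc[2]]
    } else NULL
    sp_contigs <- contigs[[sp]] %||% character(0)
    for (gid in names(family$genes)) {
      loc <- family$genes[[gid]]$locus_interval
      tdepth <- depth[(loc[1] + 1L):loc[2]]
      summ <- if (!is.null(ctrl_depth))
        summarize_locus_coverage(tdepth, ctrl_depth, gid, sp, ctrl)
      else summarize_locus_coverage(tdepth, numeric(0), gid, sp, ctrl)
      copy_state <- call_copy_state(summ, thresholds)

      gene_ctgs <- sp_contigs[grepl(paste0("\\|", gid, "\\|"),
                                    names(sp_contigs))]
      fusion <- NULL; disruption <- NULL; all_calls <- list()
      for (cn in names(gene_ctgs)) {
        ec <- annotate_contig_exons(gene_ctgs[[cn]], lib, min_identity,
                                    index = lib_index)
        all_calls[[cn]] <- ec
        if (is.null(fusion)) fusion <- detect_fusion(ec, gid)
        if (is.null(disruption))
          disruption <- detect_disruption(ec, family$genes[[gid]])
      }
      state <- if (!is.null(fusion)) "FUSION"
        else if (!is.null(disruption) && disruption$type == "FRAMESHIFT")
          "FRAMESHIFT"
        else if (!is.null(disruption)) "DIVERGENT_ALLELE"
        else copy_state
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sp, gene_id = gid,
        mean_depth_target = summ$mean_depth_target,
        mean_depth_control = summ$mean_depth_control,
        ratio = summ$ratio, copy_state = copy_state, locus_state = state,
        stringsAsFactors = FALSE)
      details[[paste(sp, gid, sep = "|")]] <-
        list(exon_calls = all_calls, fusion = fusion,
             disruption = disruption)
    }
  }
  list(calls = do.call(rbind, rows), details = details)
}
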