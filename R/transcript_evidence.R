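# Transcript-level evidence for full-length expression: zero-coverage
# regions on the reference transcript (with a mappability mask learned from
# high-expressing specimens), exon tiling/linkage of assembled transcript
# fragments, and clustered long-read isoforms. Short reads alone cannot
# separate "low expression" from "no full-length transcript"; the three
# votes combined can.

#' Maximal zero-coverage regions of a coverage track
#'
#' @param depth Integer vector of per-position depth over the transcript.
#' @param min_length Minimum run length reported.
#' @return data.frame of 0-based half-open transcript intervals, sorted.
#' @export
detect_zero_regions <- function(depth, min_length = 10L) {
  iv <- mask_to_intervals(depth == 0L)
  iv[iv$end - iv$start >= min_length, , drop = FALSE]
}

#' Mappability mask from high-expressing specimens
#'
#' High expressors (top half of specimens by total mapped counts on the
#' transcript, minimum one) define where a full-length transcript *can* be
#' observed. A position is masked when every high expressor shows at most
#' `low_depth_threshold` reads per `ref_depth` units of its own median
#' transcript depth — i.e. depressed coverage even where expression is high,
#' the signature of a difficult-to-map (near-identical paralog) segment.
#' Masked positions have limited utility for absence calls.
#'
#' @param tracks Named list (by specimen) of depth vectors over one
#'   transcript.
#' @param low_depth_threshold Reads tolerated per `ref_depth` units of median
#'   depth (default 1).
#' @param ref_depth Median-depth scaling unit (default 10; together with the
#'   default threshold, positions at <= 10% of a specimen's median depth in
#'   every high expressor are masked).
#' @return Logical mask vector; attribute `"high_expressors"` lists the
#'   specimens used. `NULL` (mask undefined) when no specimen has positive
#'   counts, in which case zero-region calls are inconclusive.
#' @export
build_mappability_mask <- function(tracks, low_depth_threshold = 1,
                                   ref_depth = 10) {
  totals <- vapply(tracks, sum, numeric(1))
  if (all(totals == 0)) return(NULL)
  n_high <- max(1L, sum(totals > 0) %/% 2L + (sum(totals > 0) %% 2L))
  pos <- names(sort(totals[totals > 0], decreasing = TRUE))
  high <- pos[seq_len(min(n_high, length(pos)))]
  len <- length(tracks[[1]])
  masked <- rep(TRUE, len)
  for (sp in high) {
    d <- tracks[[sp]]
    med <- median(d[d > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    masked <- masked & (d <= low_depth_threshold * med / ref_depth)
  }
  attr(masked, "high_expressors") <- high
  masked
}

#' Short-read vote on full-length transcript support
#'
#' `NO_FULL_LENGTH` when at least one zero region lies wholly outside the
#' mask (reproducibly-covered sequence is absent); `INCONCLUSIVE` when every
#' zero region is explained by the mask, or the mask is undefined;
#' `SUPPORTS_FULL` when there are no zero regions at all. A zero region that
#' only partially overlaps the mask is treated as inconclusive rather than
#' as absence evidence.
#'
#' @param zero_regions data.frame from [detect_zero_regions()].
#' @param mask Logical mask from [build_mappability_mask()], or `NULL`.
#' @return `"SUPPORTS_FULL"`, `"NO_FULL_LENGTH"` or `"INCONCLUSIVE"`.
#' @export
short_read_vote <- function(zero_regions, mask) {
  if (nrow(zero_regions) == 0L) return("SUPPORTS_FULL")
  if (is.null(mask)) return("INCONCLUSIVE")
  wholly_outside <- vapply(seq_len(nrow(zero_regions)), function(i) {
    idx <- (zero_regions$start[i] + 1L):zero_regions$end[i]
    !any(mask[idx])
  }, logical(1))
  if (any(wholly_outside)) "NO_FULL_LENGTH" else "INCONCLUSIVE"
}

#' Do assembled fragments tile and link all coding exons?
#'
#' TRUE iff every coding exon is overlapped by at least one fragment block
#' and, for every adjacent exon pair, some fragment has consecutive blocks
#' overlapping both exons (a junction-spanning link).
#'
#' @param fragments BED12-style data.frame with a `blocks` list-column of
#'   absolute 0-based half-open genomic intervals.
#' @param gene A `GeneModel`.
#' @return Logical.
#' @export
exon_linkage_complete <- function(fragments, gene) {
  ex <- gene$exons
  if (nrow(ex) == 0L) stop("gene ", gene$gene_id, " has no coding exons")
  n <- nrow(ex)
  exon_hit <- logical(n)
  junction_hit <- logical(max(n - 1L, 0L))
  for (i in seq_len(nrow(fragments))) {
    b <- fragments$blocks[[i]]
    hits <- lapply(seq_len(nrow(b)), function(j)
      which(overlaps(b$start[j], b$end[j], ex$start, ex$end)))
    exon_hit[unlist(hits)] <- TRUE
    if (nrow(b) >= 2L) for (j in seq_len(nrow(b) - 1L)) {
      for (e in seq_len(n - 1L)) {
        if (e %in% hits[[j]] && (e + 1L) %in% hits[[j + 1L]])
          junction_hit[e] <- TRUE
      }
    }
    # a single block covering two adjacent exons also links them
    for (j in seq_len(nrow(b))) for (e in seq_len(n - 1L)) {
      if (e %in% hits[[j]] && (e + 1L) %in% hits[[j]]) junction_hit[e] <- TRUE
    }
  }
  all(exon_hit) && all(junction_hit)
}

#' Long-read clustering criteria
#'
#' The three-tolerance rule for merging two full-length non-concatemer reads
#' into one isoform cluster: 5' start difference under 100 bp, 3' end
#' difference under 30 bp, and every internal block-structure difference
#' (gap) under 10 bp.
#'
#' @param max_5prime_overhang,max_3prime_overhang,max_gap Tolerances in bp.
#' @export
clustering_criteria <- function(max_5prime_overhang = 100L,
                                max_3prime_overhang = 30L,
                                max_gap = 10L) {
  stopifnot(max_5prime_overhang > 0L, max_3prime_overhang > 0L, max_gap > 0L)
  list(max_5prime_overhang = as.integer(max_5prime_overhang),
       max_3prime_overhang = as.integer(max_3prime_overhang),
       max_gap = as.integer(max_gap))
}

# block-coverage mask of a read over [lo, hi)
read_block_mask <- function(blocks, lo, hi) {
  m <- logical(hi - lo)
  for (j in seq_len(nrow(blocks))) {
    s <- max(blocks$start[j], lo); e <- min(blocks$end[j], hi)
    if (e > s) m[(s - lo + 1L):(e - lo)] <- TRUE
  }
  m
}

pair_mergeable <- function(r1_start, r1_end, b1, r2_start, r2_end, b2,
                           criteria) {
  if (abs(r1_start - r2_start) >= criteria$max_5prime_overhang) return(FALSE)
  if (abs(r1_end - r2_end) >= criteria$max_3prime_overhang) return(FALSE)
  lo <- max(r1_start, r2_start); hi <- min(r1_end, r2_end)
  if (hi <= lo) return(FALSE)
  diff <- xor(read_block_mask(b1, lo, hi), read_block_mask(b2, lo, hi))
  runs <- mask_to_intervals(diff)
  all(runs$end - runs$start < criteria$max_gap)
}

#' Cluster long reads into isoform clusters
#'
#' Two reads are pair-mergeable under [clustering_criteria()]; clusters are
#' the connected components of the pair-mergeable relation (order
#' independent; transitive chains merge). Each cluster collapses to its
#' longest member (total aligned block length, ties broken by name) as
#' consensus — no polishing.
#'
#' @param reads BED12-style data.frame (`chrom`, `start`, `end`, `name`,
#'   `blocks` list-column).
#' @param criteria A [clustering_criteria()] list.
#' @return List of clusters, each a list with `members` (read names) and
#'   `consensus` (the consensus read as a one-row data.frame).
#' @export
cluster_long_reads <- function(reads, criteria = clustering_criteria()) {
  n <- nrow(reads)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (reads$chrom[i] != reads$chrom[j]) next
    if (pair_mergeable(reads$start[i], reads$end[i], reads$blocks[[i]],
                       reads$start[j], reads$end[j], reads$blocks[[j]],
                       criteria)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    blen <- vapply(idx, function(i)
      sum(reads$blocks[[i]]$end - reads$blocks[[i]]$start), numeric(1))
    ord <- idx[order(-blen, reads$name[idx])]
    list(members = reads$name[idx], consensus = reads[ord[1L], , drop = FALSE])
  })
}

#' Is a full-length isoform present for a gene?
#'
#' TRUE iff some cluster consensus has blocks overlapping every coding exon
#' of the gene.
#'
#' @param clusters Output of [cluster_long_reads()].
#' @param gene A `GeneModel`.
#' @export
full_length_isoform_present <- function(clusters, gene) {
  ex <- gene$exons
  any(vapply(clusters, function(cl) {
    b <- cl$consensus$blocks[[1]]
    all(vapply(seq_len(nrow(ex)), function(e)
      any(overlaps(b$start, b$end, ex$start[e], ex$end[e])), logical(1)))
  }, logical(1)))
}

#' Combine transcript votes into a final status
#'
#' `FULL_LENGTH` iff a full-length isoform is observed (long reads can
#' rescue a failed tiling vote), or the tiling vote passes and short reads
#' do not positively contradict it. When no long-read data exist the isoform
#' vote is ignored. Everything else — including an inconclusive short-read
#' vote with no tiling support — is `NO_FULL_LENGTH`.
#'
#' @param short_vote Output of [short_read_vote()].
#' @param tiling Logical from [exon_linkage_complete()].
#' @param isoform Logical from [full_length_isoform_present()], or `NA`.
#' @param has_longreads Logical; whether long-read data exist for this
#'   specimen.
#' @return List with the three votes and `final`
#'   (`"FULL_LENGTH"`/`"NO_FULL_LENGTH"`).
#' @export
transcript_status <- function(short_vote, tiling, isoform = NA,
                              has_longreads = !is.na(isoform)) {
  iso_vote <- if (has_longreads && !is.na(isoform)) isoform else FALSE
  final <- if (iso_vote || (tiling && short_vote != "NO_FULL_LENGTH"))
    "FULL_LENGTH" else "NO_FULL_LENGTH"
  list(short_read_vote = short_vote, tiling_vote = tiling,
       isoform_vote = if (has_longreads) isoform else NA, final = final)
}

#' Transcript status for every gene and specimen
#'
#' Pipeline wrapper. For each gene, a mappability mask is learned from that
#' gene's coverage tracks across specimens; each specimen is then voted on
#' with short-read zero regions, fragment tiling and isoform clusters.
#' Fragments and isoforms are attributed to genes by genomic overlap with
#' the gene locus.
#'
#' @param family A `FamilyReference`.
#' @param coverage `coverage[[specimen]][[gene]]` depth vectors.
#' @param fragments,isoforms BED12-style data.frames with `specimen_id`.
#' @param min_zero_length Minimum zero-region length.
#' @param criteria [clustering_criteria()] for isoform clustering.
#' @param low_depth_threshold,ref_depth Passed to
#'   [build_mappability_mask()].
#' @return data.frame per specimen x gene with the three votes and `final`.
#' @export
call_transcript_states <- function(family, coverage, fragments, isoforms,
                                   min_zero_length = 10L,
                                   criteria = clustering_criteria(),
                                   low_depth_threshold = 1, ref_depth = 10) {
  specimens <- names(coverage)
  rows <- list()
  for (gid in names(family$genes)) {
    gene <- family$genes[[gid]]
    loc <- gene$locus_interval
    tracks <- lapply(coverage, `[[`, gid)
    mask <- build_mappability_mask(tracks, low_depth_threshold, ref_depth)
    for (sp in specimens) {
      zr <- detect_zero_regions(tracks[[sp]], min_zero_length)
      sv <- short_read_vote(zr, mask)
      fr <- fragments[fragments$specimen_id == sp &
                        overlaps(fragments$start, fragments$end,
                                 loc[1], loc[2]), , drop = FALSE]
      tiling <- exon_linkage_complete(fr, gene)
      iso <- isoforms[isoforms$specimen_id == sp &
                        overlaps(isoforms$start, isoforms$end,
                                 loc[1], loc[2]), , drop = FALSE]
      has_lr <- nrow(isoforms[isoforms$specimen_id == sp, , drop = FALSE]) > 0L
      iso_vote <- if (has_lr)
        full_length_isoform_present(cluster_long_reads(iso, criteria), gene)
      else NA
      st <- transcript_status(sv, tiling, iso_vote, has_lr)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sp, gene_id = gid, short_read_vote = sv,
        tiling_vote = tiling, isoform_vote = iso_vote,
        transcript_final = st$final, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
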