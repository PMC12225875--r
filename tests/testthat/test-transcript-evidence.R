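test_that("zero regions are maximal runs above the minimum length", {
  expect_equal(nrow(detect_zero_regions(rep(5L, 50))), 0L)
  expect_equal(detect_zero_regions(rep(0L, 25)), iv(0, 25),
               ignore_attr = TRUE)
  track <- c(5L, 5L, rep(0L, 10), 7L)
  expect_equal(detect_zero_regions(track, min_length = 10L), iv(2, 12),
               ignore_attr = TRUE)
  expect_equal(nrow(detect_zero_regions(track, min_length = 11L)), 0L)
})

test_that("mappability mask equals the positionwise rule evaluation", {
  set.seed(42)
  len <- 200L
  tracks <- list(
    S1 = rpois(len, 100), S2 = rpois(len, 80),
    S3 = rpois(len, 2), S4 = rpois(len, 0.2))
  # a shared hard segment: depressed in everyone
  for (s in names(tracks)) tracks[[s]][51:70] <-
    rpois(20, 0.02 * median(tracks[[s]][tracks[[s]] > 0]))
  mask <- build_mappability_mask(tracks)
  high <- attr(mask, "high_expressors")
  expect_setequal(high, c("S1", "S2"))
  oracle <- rep(TRUE, len)
  for (s in high) {
    med <- median(tracks[[s]][tracks[[s]] > 0])
    for (i in seq_len(len))
      oracle[i] <- oracle[i] && (tracks[[s]][i] <= med / 10)
  }
  expect_identical(as.logical(mask), oracle)
  expect_true(all(mask[51:70]))
  expect_false(mask[which.max(tracks$S1)])
  expect_null(build_mappability_mask(list(A = rep(0L, 10))))
})

test_that("short-read vote separates masked gaps from genuine absence", {
  len <- 100L
  mask <- rep(FALSE, len); mask[41:60] <- TRUE
  expect_equal(short_read_vote(iv(integer(0), integer(0)), mask),
               "SUPPORTS_FULL")
  # one zero region fully inside the masked hard segment: low expression
  # cannot be distinguished from absence there
  expect_equal(short_read_vote(iv(42, 58), mask), "INCONCLUSIVE")
  # an additional unmasked zero region is positive evidence of absence
  expect_equal(short_read_vote(iv(c(5, 42), c(25, 58)), mask),
               "NO_FULL_LENGTH")
  expect_equal(short_read_vote(iv(5, 25), NULL), "INCONCLUSIVE")
})

test_that("exon linkage requires every exon and every junction", {
  gene <- default_bundle()$family$genes[["MPO1"]]
  ex <- gene$exons
  all_ex <- bed_row("full", iv(ex$start, ex$end))
  expect_true(exon_linkage_complete(all_ex, gene))
  part <- rbind(bed_row("a", iv(ex$start[1:3], ex$end[1:3])),
                bed_row("b", iv(ex$start[5:7], ex$end[5:7])))
  expect_false(exon_linkage_complete(part, gene))
  # a fragment skipping exons 9-10 while joining 8 to 11 leaves junctions
  # unlinked for the reference model
  skip <- rbind(bed_row("left", iv(ex$start[1:8], ex$end[1:8])),
                bed_row("skip", iv(ex$start[c(8, 11)], ex$end[c(8, 11)])),
                bed_row("right", iv(ex$start[11:12], ex$end[11:12])))
  expect_false(exon_linkage_complete(skip, gene))
  # monotonicity: adding fragments can only turn linkage on, never off
  set.seed(7)
  for (i in 1:10) {
    k <- sample(nrow(ex) - 1L, 1)
    frags <- bed_row("w", iv(ex$start[k:(k + 1)], ex$end[k:(k + 1)]))
    expect_false(exon_linkage_complete(frags, gene))
    expect_true(exon_linkage_complete(rbind(frags, all_ex), gene))
  }
})

test_that("isoform clustering honors the 5'/3'/gap tolerances exactly", {
  blocks <- iv(c(1000, 2000, 3000), c(1500, 2500, 3600))
  base <- bed_row("A", blocks)
  shift5 <- function(d, name) bed_row(name, iv(blocks$start + c(d, 0, 0),
                                               blocks$end))
  shift3 <- function(d, name) bed_row(name, iv(blocks$start,
                                               blocks$end + c(0, 0, d)))
  n_clusters <- function(reads) length(cluster_long_reads(reads))
  expect_equal(n_clusters(rbind(base, base)), 1L)
  expect_equal(n_clusters(rbind(base, shift5(99, "B"))), 1L)
  expect_equal(n_clusters(rbind(base, shift5(100, "B"))), 2L)
  expect_equal(n_clusters(rbind(base, shift5(150, "B"))), 2L)
  expect_equal(n_clusters(rbind(base, shift3(-29, "B"))), 1L)
  expect_equal(n_clusters(rbind(base, shift3(-30, "B"))), 2L)
  # internal block-structure differences: a 9-bp dent merges, 10-bp splits
  dent <- function(d, name) bed_row(name, iv(c(1000, 2000 + d, 3000),
                                             c(1500, 2500, 3600)))
  expect_equal(n_clusters(rbind(base, dent(9, "B"))), 1L)
  expect_equal(n_clusters(rbind(base, dent(10, "B"))), 2L)
  # a 15-bp mini exon-skip is its own isoform
  skip <- bed_row("S", iv(c(1000, 2000, 2265, 3000),
                          c(1500, 2250, 2500, 3600)))
  expect_equal(n_clusters(rbind(base, skip)), 2L)
})

test_that("clustering is order-independent and transitive", {
  blocks <- iv(c(1000, 2000), c(1500, 2600))
  a <- bed_row("A", blocks)
  b <- bed_row("B", iv(c(1060, 2000), c(1500, 2600)))   # ~A, ~C
  c_ <- bed_row("C", iv(c(1120, 2000), c(1500, 2600)))  # ~B, not ~A
  reads <- rbind(a, b, c_)
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    cl <- cluster_long_reads(reads[perm, ])
    expect_length(cl, 1L)
    expect_setequal(cl[[1]]$members, c("A", "B", "C"))
  }
  # consensus is the longest member
  expect_equal(cluster_long_reads(reads)[[1]]$consensus$name, "A")
})

test_that("full-length isoform detection needs every coding exon", {
  gene <- default_bundle()$family$genes[["MPO1"]]
  ex <- gene$exons
  full <- cluster_long_reads(bed_row("A", iv(ex$start, ex$end)))
  expect_true(full_length_isoform_present(full, gene))
  partial <- cluster_long_reads(bed_row("A", iv(ex$start[-4], ex$end[-4])))
  expect_false(full_length_isoform_present(partial, gene))
  expect_false(full_length_isoform_present(list(), gene))
})

test_that("vote combination distinguishes low expression from absence", {
  # nothing supports a transcript
  expect_equal(transcript_status("NO_FULL_LENGTH", FALSE, FALSE)$final,
               "NO_FULL_LENGTH")
  # isoforms rescue a failed tiling vote (the high-expressor exception)
  expect_equal(transcript_status("NO_FULL_LENGTH", FALSE, TRUE)$final,
               "FULL_LENGTH")
  # inconclusive short reads with no tiling and no long reads resolve to
  # absence
  st <- transcript_status("INCONCLUSIVE", FALSE, NA, has_longreads = FALSE)
  expect_equal(st$final, "NO_FULL_LENGTH")
  expect_true(is.na(st$isoform_vote))
  expect_equal(transcript_status("SUPPORTS_FULL", TRUE, NA,
                                 has_longreads = FALSE)$final, "FULL_LENGTH")
  expect_equal(transcript_status("NO_FULL_LENGTH", TRUE, FALSE)$final,
               "NO_FULL_LENGTH")
})

test_that("simulated transcript calls track the genotypes", {
  b <- default_bundle()
  tx <- call_transcript_states(b$family, b$transcript$coverage,
                               b$transcript$fragments, b$transcript$isoforms)
  target <- b$family$target_gene_id
  pick <- function(sp) tx$transcript_final[tx$specimen_id == sp &
                                             tx$gene_id == target]
  for (sp in specimens_of_class(b, "intact")) expect_equal(pick(sp),
                                                           "FULL_LENGTH")
  for (sp in specimens_of_class(b, "het_frameshift")) expect_equal(pick(sp),
                                                                   "FULL_LENGTH")
  for (sp in specimens_of_class(b, "hom_deletion")) expect_equal(pick(sp),
                                                                 "NO_FULL_LENGTH")
  for (sp in specimens_of_class(b, "hom_fusion")) expect_equal(pick(sp),
                                                               "NO_FULL_LENGTH")
  # hard-region positions are masked for the focal gene
  mask <- build_mappability_mask(lapply(b$transcript$coverage, `[[`, target))
  hard <- toxinloss:::hard_tx_intervals(b$family, target)
  hard_pos <- unlist(lapply(seq_len(nrow(hard)), function(i)
    (hard$start[i] + 1L):hard$end[i]))
  expect_gt(mean(mask[hard_pos]), 0.9)
  expect_lt(mean(mask[-hard_pos]), 0.05)
})
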