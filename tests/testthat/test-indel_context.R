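# indel detection and region classification in pairwise alignments

make_deletion_alignment <- function(seq, start, len,
                                    id_a = "rec", id_b = "hyb") {
  # derived (side b) carries a deletion of [start, start+len) (0-based)
  chars <- strsplit(seq, "")[[1]]
  b <- chars
  b[(start + 1):(start + len)] <- "-"
  pairwise_alignment(id_a, id_b, seq, paste(b, collapse = ""))
}

test_that("pairwise_alignment validates its invariants", {
  expect_error(pairwise_alignment("a", "b", "ACGT", "ACG"), "equal length")
  expect_error(pairwise_alignment("a", "b", "A-GT", "A-GT"), "both")
  aln <- pairwise_alignment("a", "b", "ATG-CA", "ATGGCA")
  expect_s3_class(aln, "pairwise_alignment")
})

test_that("align_pair recovers identity and a unique gap", {
  aln <- align_pair("ATGGCAGCT", "ATGGCAGCT")
  expect_equal(aln$aligned_a, "ATGGCAGCT")
  expect_equal(aln$aligned_b, "ATGGCAGCT")
  expect_equal(nrow(find_indels(aln)), 0L)
  aln2 <- align_pair("ATGGCAAAAGCT", "ATGGCAGCT")
  ind <- find_indels(aln2)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length_nt, 3L)
  expect_equal(ind$gapped_side, "b")
  # round trip: ungapping reproduces the inputs byte-exactly
  expect_equal(ungap(aln2$aligned_a), "ATGGCAAAAGCT")
  expect_equal(ungap(aln2$aligned_b), "ATGGCAGCT")
  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("find_indels reports maximal runs with both coordinate systems", {
  aln <- pairwise_alignment("r", "h", "ATGGCA---GCT", "ATGGCAAAAGCT")
  ind <- find_indels(aln)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$col_start, 6L)
  expect_equal(ind$col_end, 9L)
  expect_equal(ind$length_nt, 3L)
  expect_equal(ind$gapped_side, "a")
  expect_equal(c(ind$ua_start, ind$ua_end), c(6L, 6L)) # point in a
  expect_equal(c(ind$ub_start, ind$ub_end), c(6L, 9L)) # residues in b
  # one run per side
  ind2 <- find_indels(pairwise_alignment("r", "h", "A--A", "AAA-"))
  expect_equal(nrow(ind2), 2L)
  expect_setequal(ind2$gapped_side, c("a", "b"))
})

test_that("filter_eligible_indels enforces the strict 45-nt terminal rule", {
  seq <- random_cds(100, seed = 53) # 300 nt
  # indel at ungapped position 30: too close to the start (30 <= 45)
  a30 <- make_deletion_alignment(seq, 30, 3)
  expect_equal(nrow(filter_eligible_indels(find_indels(a30), a30)), 0L)
  # position 48: 48 > 45 and 300 - 51 = 249 > 45 -> retained
  a48 <- make_deletion_alignment(seq, 48, 3)
  expect_equal(nrow(filter_eligible_indels(find_indels(a48), a48)), 1L)
  # position 46 in a pure-insertion sense: boundary of the strict rule
  a46 <- make_deletion_alignment(seq, 46, 3)
  expect_equal(nrow(filter_eligible_indels(find_indels(a46), a46)), 1L)
  a45 <- make_deletion_alignment(seq, 45, 3)
  expect_equal(nrow(filter_eligible_indels(find_indels(a45), a45)), 0L)
  # ends 40 nt before the CDS end in the gapped sequence -> excluded
  aend <- make_deletion_alignment(seq, 300 - 40 - 3, 3)
  expect_equal(nrow(filter_eligible_indels(find_indels(aend), aend)), 0L)
})

test_that("flanking windows follow the complete-codon arithmetic", {
  seq <- random_cds(200, seed = 59) # 600 nt
  # codon-boundary deletion at nt 120
  aln <- make_deletion_alignment(seq, 120, 6)
  ind <- filter_eligible_indels(find_indels(aln), aln)
  w <- extract_flanking_windows(aln, ind)
  # side a carries the residues: interval [120, 126)
  expect_equal(c(w$a$flank5$start, w$a$flank5$end), c(75L, 120L))
  expect_equal(c(w$a$flank3$start, w$a$flank3$end), c(126L, 171L))
  # side b: zero-length point at 120
  expect_equal(c(w$b$flank5$start, w$b$flank5$end), c(75L, 120L))
  expect_equal(c(w$b$flank3$start, w$b$flank3$end), c(120L, 165L))
  expect_length(w$a$flank5$codons, 15L)
  expect_length(w$b$flank3$codons, 15L)
  # windows contain the actual sequence content
  expect_equal(
    paste(w$a$flank5$codons, collapse = ""),
    substr(seq, 76, 120)
  )
})

test_that("mid-codon indels discard the broken codon", {
  seq <- random_cds(200, seed = 61)
  # deletion [121, 125): starts mid-codon in side a
  chars <- strsplit(seq, "")[[1]]
  b <- paste(c(chars[1:121], chars[126:600]), collapse = "")
  aln <- pairwise_alignment("r", "h", seq, paste(
    c(chars[1:121], rep("-", 4), chars[126:600]),
    collapse = ""
  ))
  ind <- filter_eligible_indels(find_indels(aln), aln)
  w <- extract_flanking_windows(aln, ind)
  # side a interval [121, 125): flank5 ends at 120, flank3 starts at 126
  expect_equal(w$a$flank5$end, 120L)
  expect_equal(w$a$flank3$start, 126L)
  # side b point at 121 (mid-codon): flank5 ends 120, flank3 starts 123
  expect_equal(w$b$flank5$end, 120L)
  expect_equal(w$b$flank3$start, 123L)
})

test_that("inter-indel segments shorter than 90 nt yield no flanks", {
  seq <- random_cds(300, seed = 67) # 900 nt
  chars <- strsplit(seq, "")[[1]]
  # two 3-nt deletions with 80 nt between them (gap-to-gap distance)
  g <- chars
  g[301:303] <- "-"
  g[384:386] <- "-" # second indel starts 80 nt after the first ends
  aln <- pairwise_alignment("r", "h", seq, paste(g, collapse = ""))
  ind <- filter_eligible_indels(find_indels(aln), aln)
  expect_equal(nrow(ind), 2L)
  w1 <- extract_flanking_windows(aln, ind[1, ])
  w2 <- extract_flanking_windows(aln, ind[2, ])
  # the segment between them contributes to no flank on either side
  expect_false(w1$a$flank3$kept)
  expect_false(w2$a$flank5$kept)
  expect_false(w1$b$flank3$kept)
  expect_false(w2$b$flank5$kept)
  # outward-facing windows survive
  expect_true(w1$a$flank5$kept)
  expect_true(w2$a$flank3$kept)
  # and no codon of the inter-indel segment is remote either
  rem <- extract_remote_regions(aln)
  expect_false(any(rem$a$codon_start >= 303 & rem$a$codon_start < 383))
})

test_that("remote extraction matches the set complement", {
  seq <- random_cds(200, seed = 71) # 600 nt
  # no indels: whole CDS is remote
  aln0 <- pairwise_alignment("r", "h", seq, seq)
  rem0 <- extract_remote_regions(aln0)
  expect_length(rem0$a$codons, 200L)
  expect_equal(paste(rem0$a$codons, collapse = ""), seq)
  # single mid-CDS deletion: 45-nt collar each side, codon-rounded
  aln <- make_deletion_alignment(seq, 300, 9)
  rem <- extract_remote_regions(aln)
  # side a: interval [300, 309); remote codons end <= 255 or start >= 354
  expect_true(all(rem$a$codon_start + 3 <= 255 | rem$a$codon_start >= 354))
  expect_true(any(rem$a$codon_start == 252))
  expect_true(any(rem$a$codon_start == 354))
  expect_false(any(rem$a$codon_start %in% seq(255, 351, 3)))
})

test_that("flank and remote codon sets partition cleanly", {
  seq <- random_cds(300, seed = 73)
  aln <- make_deletion_alignment(seq, 450, 6)
  rg <- alignment_region_codons(aln)
  for (side in c("a", "b")) {
    # disjoint: no codon start can be both flank and remote; compare via
    # content windows (codon strings may repeat, so compare coordinates)
    rem_starts <- extract_remote_regions(aln)[[side]]$codon_start
    ind <- filter_eligible_indels(find_indels(aln), aln)
    w <- extract_flanking_windows(aln, ind)
    f5 <- seq(w[[side]]$flank5$start, w[[side]]$flank5$end - 3, 3)
    f3 <- seq(w[[side]]$flank3$start, w[[side]]$flank3$end - 3, 3)
    expect_length(intersect(c(f5, f3), rem_starts), 0L)
    # pooled region codon counts: two_sides = flank5 + flank3
    sc <- suppressWarnings(regional_scub(rg[[side]]))
    expect_equal(
      sc$two_sides$n,
      sc$flank5$n + sc$flank3$n
    )
    expect_equal(sc$whole$n_sc, count_synonymous_codons(
      extract_codons(ungap(aln[[paste0("aligned_", side)]]))
    )$n_sc)
  }
})

test_that("aligned FASTA round-trips through write and read", {
  seq <- random_cds(60, seed = 79)
  aln <- make_deletion_alignment(seq, 60, 3, id_a = "x|rec", id_b = "x|hyb")
  path <- tempfile(fileext = ".fasta")
  write_aligned_fasta(list(aln), path)
  back <- read_aligned_fasta(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$aligned_a, aln$aligned_a)
  expect_equal(back[[1]]$aligned_b, aln$aligned_b)
  expect_equal(back[[1]]$id_a, "x|rec")
})
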