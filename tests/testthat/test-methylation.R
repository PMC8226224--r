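# CpG-deamination signature ratios

test_that("second_third_counts attributes A/G-ending SCs by second base", {
  d <- second_third_counts(counts_from(GCA = 2, GCG = 1))
  expect_equal(d["C", "A"], 2)
  expect_equal(d["C", "G"], 1)
  expect_equal(sum(d), 3)
  d2 <- second_third_counts(counts_from(GGA = 1, GGG = 1, GCT = 5))
  expect_equal(d2["G", "A"], 1)
  expect_equal(d2["G", "G"], 1)
  expect_equal(sum(d2), 2) # GCT (T-ending) ignored
  d3 <- second_third_counts(counts_from(GCC = 3, GCT = 2))
  expect_equal(sum(d3), 0)
  # ATG and TGG must not leak in (both end in G but are not SCs)
  d4 <- second_third_counts(counts_from(ATG = 5, TGG = 5, AAG = 1))
  expect_equal(sum(d4), 1)
})

test_that("nxa_nxg_ratio handles values and undefined flags", {
  d <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), c("A", "G")))
  d["C", ] <- c(20, 10)
  d["T", ] <- c(0, 7)
  expect_equal(nxa_nxg_ratio(d, "C"), 2.0)
  expect_equal(nxa_nxg_ratio(d, "T"), 0.0)
  expect_true(is.na(nxa_nxg_ratio(d, "A"))) # 0/0 denominator
})

test_that("uniform codon pools give multiplicity-share NXA/NXG ratios", {
  # enumeration oracle: expected ratio = (# SCs with second X, third A) /
  # (# SCs with second X, third G)
  tab <- codon_metadata()
  sc <- tab[tab$sc, ]
  counts <- count_synonymous_codons(sc$codon) # one of each SC
  d <- second_third_counts(counts)
  for (X in c("A", "C", "G", "T")) {
    n_a <- sum(sc$second == X & sc$third == "A")
    n_g <- sum(sc$second == X & sc$third == "G")
    expected <- if (n_g == 0) NA_real_ else n_a / n_g
    got <- nxa_nxg_ratio(d, X)
    if (is.na(expected)) expect_true(is.na(got)) else expect_equal(got, expected)
  }
})

test_that("boundary_pair_counts matches hand enumeration", {
  m <- boundary_pair_counts(c("GCT", "GGA", "CTC", "GAA"))
  expect_equal(m["T", "G"], 1L)
  expect_equal(m["C", "G"], 1L)
  expect_equal(sum(m), 2L) # GGA -> CTC skipped (A-ending focal)
  m2 <- boundary_pair_counts(c("GCC", "GCC", "GCC"))
  expect_equal(m2["C", "G"], 2L)
  expect_equal(sum(boundary_pair_counts("GCC")), 0L) # < 2 codons, no error
  # non-SC focal codons contribute nothing even when C/T-ending
  m3 <- boundary_pair_counts(c("TGA", "GCA")) # TGA is a stop
  expect_equal(sum(m3), 0L)
})

test_that("splitting a CDS loses exactly the pair spanning the split", {
  set.seed(23)
  codons <- extract_codons(random_cds(60))
  whole <- boundary_pair_counts(codons)
  for (k in c(10, 30, 50)) {
    split_counts <- boundary_pair_counts(
      list(codons[1:k], codons[(k + 1):length(codons)])
    )
    lost <- whole - split_counts
    expect_true(sum(lost) <= 1L)
    focal <- codons[k]
    spanning <- focal %in% sc_codons() &&
      substr(focal, 3, 3) %in% c("C", "T")
    expect_equal(sum(lost), as.integer(spanning))
  }
})

test_that("boundary counting conserves the eligible pair total", {
  set.seed(29)
  codons <- extract_codons(random_cds(500))
  m <- boundary_pair_counts(codons)
  focal <- codons[-length(codons)]
  eligible <- focal %in% sc_codons() & substr(focal, 3, 3) %in% c("C", "T")
  expect_equal(sum(m), sum(eligible))
})

test_that("ntx_ncx_ratio values, flags, and the symmetric pool identity", {
  b <- matrix(0, 2, 4, dimnames = list(c("C", "T"), c("A", "C", "G", "T")))
  b["T", "G"] <- 30
  b["C", "G"] <- 20
  b["T", "A"] <- 5
  b["C", "A"] <- 5
  expect_equal(ntx_ncx_ratio(b, "G"), 1.5)
  expect_equal(ntx_ncx_ratio(b, "A"), 1.0)
  expect_true(is.na(ntx_ncx_ratio(b, "C")))
  # constructed pool: each C-ending focal paired with its T-ending
  # sibling before every successor first base -> all ratios exactly 1
  pool <- unlist(lapply(c("AAA", "CAA", "GAA", "TGG"), function(succ) {
    c("GCC", succ, "GCT", succ)
  }))
  m <- boundary_pair_counts(pool)
  for (X in c("A", "C", "G", "T")) {
    r <- ntx_ncx_ratio(m, X)
    if (!is.na(r)) expect_equal(r, 1.0)
  }
  expect_equal(ntx_ncx_ratio(m, "A"), 1.0)
  expect_equal(ntx_ncx_ratio(m, "G"), 1.0)
})

test_that("per_aa_ag_pair_ratio uses the XYA/XYG family", {
  expect_equal(per_aa_ag_pair_ratio(counts_from(CCA = 4, CCG = 2), "Pro"), 2.0)
  expect_equal(per_aa_ag_pair_ratio(counts_from(AAA = 3, AAG = 3), "Lys"), 1.0)
  # Ala: identical to NXA/NXG restricted to the GC prefix
  cc <- counts_from(GCA = 6, GCG = 3, ACA = 10, ACG = 1)
  expect_equal(per_aa_ag_pair_ratio(cc, "Ala"), 2.0)
  expect_equal(per_aa_ag_pair_ratio(cc, "Thr"), 10.0)
  # six-codon amino acids: default family vs alt family
  cc_leu <- counts_from(CTA = 2, CTG = 4, TTA = 9, TTG = 3)
  expect_equal(per_aa_ag_pair_ratio(cc_leu, "Leu"), 0.5)
  expect_equal(per_aa_ag_pair_ratio(cc_leu, "Leu", family = "alt"), 3.0)
  expect_equal(
    per_aa_ag_pair_ratio(counts_from(AGA = 4, AGG = 2), "Arg", family = "alt"),
    2.0
  )
  expect_true(is.na(per_aa_ag_pair_ratio(counts_from(CCA = 4), "Pro")))
  expect_error(per_aa_ag_pair_ratio(counts_from(CCA = 1), "Ile"), "no A/G")
  expect_error(per_aa_ag_pair_ratio(counts_from(CCA = 1), "Pro", "alt"))
  expect_length(ag_pair_amino_acids(), 11L)
})

test_that("cross_sample_ratio propagates undefined flags", {
  expect_equal(cross_sample_ratio(2.0, 2.0), 1.0)
  expect_equal(cross_sample_ratio(3.0, 2.0), 1.5)
  expect_true(is.na(cross_sample_ratio(NA_real_, 2)))
  expect_true(is.na(cross_sample_ratio(2, NA_real_)))
  expect_true(is.na(cross_sample_ratio(2, 0)))
})

test_that("methylation_ratio_table assembles the eight comparisons", {
  set.seed(31)
  codons <- extract_codons(random_cds(2000))
  cc <- count_synonymous_codons(codons)
  pairs <- boundary_pair_counts(codons)
  tab <- methylation_ratio_table(cc, cc, pairs, pairs)
  expect_equal(nrow(tab), 8L)
  expect_setequal(
    tab$ratio,
    c(
      "NAA/NAG", "NCA/NCG", "NGA/NGG", "NTA/NTG",
      "NT|A/NC|A", "NT|C/NC|C", "NT|G/NC|G", "NT|T/NC|T"
    )
  )
  # identical samples: cross-sample ratio 1, statistic exactly 0
  expect_true(all(tab$cross_sample == 1, na.rm = TRUE))
  expect_true(all(tab$chisq == 0, na.rm = TRUE))
})
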