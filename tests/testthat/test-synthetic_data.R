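# synthetic CDS evolution with ground truth

test_that("generate_ancestral_cds is deterministic and validated", {
  a1 <- generate_ancestral_cds(25, seed = 7)
  a2 <- generate_ancestral_cds(25, seed = 7)
  expect_identical(a1, a2)
  a3 <- generate_ancestral_cds(25, seed = 8)
  expect_false(identical(a1$sequence, a3$sequence))
  expect_equal(nrow(generate_ancestral_cds(0, seed = 1)), 0L)
  expect_true(all(substr(a1$sequence, 1, 3) == "ATG"))
  # no internal stops by construction
  stops_found <- vapply(a1$sequence, function(s) {
    any(extract_codons(s) %in% stop_codons())
  }, logical(1))
  expect_false(any(stops_found))
  bad_usage <- default_codon_usage()
  bad_usage[1] <- bad_usage[1] + 0.1
  expect_error(
    generate_ancestral_cds(5, codon_usage = bad_usage),
    "sum to 1"
  )
  expect_error(
    generate_ancestral_cds(5, codon_usage = c(GCA = 1)),
    "59 synonymous"
  )
})

test_that("uniform codon usage reproduces multiplicity-share endings", {
  usage <- setNames(
    rep(1 / 59, 59),
    sc_codons()
  )
  cds <- generate_ancestral_cds(40,
    lengths = 500, codon_usage = usage,
    seed = 11
  )
  cc <- pool_codon_counts(cds_codon_counts(cds))
  ef <- total_ending_frequencies(cc)
  tab <- codon_metadata()
  sc <- tab[tab$sc, ]
  for (b in c("A", "T", "C", "G")) {
    expect_equal(ef$f[[b]], sum(sc$third == b) / 59, tolerance = 0.02)
  }
})

test_that("default codon usage has C/G-ending dominance", {
  cds <- generate_ancestral_cds(40, lengths = 300, seed = 13)
  r <- cg_to_at_ratio(pool_codon_counts(cds_codon_counts(cds)))
  expect_gt(r, 1.3)
  expect_lt(r, 1.7) # weight 1.5 world
})

test_that("zero-rate mutation is the identity with empty truth", {
  cds <- generate_ancestral_cds(10, seed = 17)
  p <- mutation_params(sub_rate = 0, indel_rate = 0, seed = 17)
  sim <- mutate_genome(cds, p)
  expect_identical(sim$derived$sequence, cds$sequence)
  expect_equal(nrow(sim$truth$substitutions), 0L)
  expect_equal(nrow(sim$truth$indels), 0L)
})

test_that("truth replay reproduces derived sequences byte-exactly", {
  cds <- generate_ancestral_cds(30, seed = 19)
  p <- mutation_params(
    sub_rate = 0.02, cpg_multiplier = 5, indel_rate = 1,
    flank_multiplier = 5, seed = 19
  )
  sim <- mutate_genome(cds, p)
  expect_gt(nrow(sim$truth$substitutions), 0L)
  expect_gt(nrow(sim$truth$indels), 0L)
  expect_identical(
    unname(replay_truth(cds, sim$truth)),
    sim$derived$sequence
  )
  # alignments are gap-exact: ungapping reproduces both sequences
  for (i in seq_along(sim$alignments)) {
    expect_identical(ungap(sim$alignments[[i]]$aligned_a), cds$sequence[i])
    expect_identical(
      ungap(sim$alignments[[i]]$aligned_b),
      sim$derived$sequence[i]
    )
  }
  # derived sequences contain no internal stop codons
  stops_found <- vapply(sim$derived$sequence, function(s) {
    any(extract_codons(s) %in% stop_codons())
  }, logical(1))
  expect_false(any(stops_found))
  # mutation is seed-deterministic
  sim2 <- mutate_genome(cds, p)
  expect_identical(sim$derived$sequence, sim2$derived$sequence)
})

test_that("indels respect clearance, separation and frame", {
  cds <- generate_ancestral_cds(40, lengths = 400, seed = 23)
  p <- mutation_params(sub_rate = 0, indel_rate = 2, seed = 23)
  sim <- mutate_genome(cds, p)
  ind <- sim$truth$indels
  expect_gt(nrow(ind), 10L)
  expect_true(all(ind$pos %% 3 == 0))
  expect_true(all(ind$length %% 3 == 0))
  lens <- setNames(nchar(cds$sequence), cds$id)
  expect_true(all(ind$pos > 45))
  expect_true(all(lens[ind$record_id] - (ind$pos + ind$length) > 45))
  # pairwise separation within each record
  for (id in unique(ind$record_id)) {
    d <- ind[ind$record_id == id, ]
    if (nrow(d) < 2) next
    d <- d[order(d$pos), ]
    gaps <- d$pos[-1] - (d$pos[-nrow(d)] + d$length[-nrow(d)])
    expect_true(all(gaps >= 90))
  }
})

test_that("CpG flags in truth match context frequency when unbiased", {
  cds <- generate_ancestral_cds(60, lengths = 400, seed = 29)
  p <- mutation_params(
    sub_rate = 0.02, cpg_multiplier = 1, indel_rate = 0,
    seed = 29
  )
  sim <- mutate_genome(cds, p)
  subs <- sim$truth$substitutions
  # fraction of substitutions at CpG-context sites ~ fraction of sites in
  # CpG context (binomial check at 4 sd)
  cpg_sites <- sum(vapply(cds$sequence, function(s) {
    b <- strsplit(s, "")[[1]]
    cg <- b[-length(b)] == "C" & b[-1] == "G"
    sum(cg) * 2L
  }, integer(1)))
  total_sites <- sum(nchar(cds$sequence))
  p_cpg <- cpg_sites / total_sites
  obs <- mean(subs$cpg)
  se <- sqrt(p_cpg * (1 - p_cpg) / nrow(subs))
  expect_lt(abs(obs - p_cpg), 4 * se + 0.01)
})

test_that("assign_chromosomes is reproducible and near uniform", {
  ids <- sprintf("u%05d", 1:2100)
  m1 <- assign_chromosomes(ids, unmapped_frac = 0, seed = 31)
  m2 <- assign_chromosomes(ids, unmapped_frac = 0, seed = 31)
  expect_identical(m1, m2)
  tab <- table(m1$chromosome)
  expect_length(tab, 21L)
  expect_true(all(tab > 100 * 0.6 & tab < 100 * 1.4))
  all_un <- assign_chromosomes(ids[1:50], unmapped_frac = 1, seed = 1)
  expect_true(all(all_un$chromosome == "unmapped"))
  expect_error(
    assign_chromosomes(ids[1:5], introgressed = "9Q"),
    "wheat chromosome"
  )
})
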