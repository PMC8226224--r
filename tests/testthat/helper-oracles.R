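# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops and dictionary tallies only.

# Naive per-triplet codon tally: walks the sequence three characters at a
# time and counts into an environment keyed by codon string.
naive_codon_tally <- function(sequence, frame_offset = 0) {
  env <- new.env(parent = emptyenv())
  i <- frame_offset + 1
  while (i + 2 <= nchar(sequence)) {
    codon <- substr(sequence, i, i + 2)
    prev <- if (exists(codon, envir = env)) get(codon, envir = env) else 0
    assign(codon, prev + 1, envir = env)
    i <- i + 3
  }
  out <- setNames(rep(0, 64), scubshift::all_codons())
  for (codon in ls(env)) {
    if (codon %in% names(out)) out[codon] <- get(codon, envir = env)
  }
  out
}

# The 59 synonymous codons, re-derived from first principles (standard
# code via Biostrings, minus stops and single-codon amino acids).
oracle_sc_set <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa_counts <- table(gc)
  names(gc)[gc != "*" & aa_counts[gc] >= 2]
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
    collapse = ""
  )
}

# Textbook chi-square via R's own implementation (no continuity
# correction), used as the independent route for the package's version.
oracle_chisq <- function(tab) {
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}

# Brute-force indel-region classifier for one sequence: for every complete
# codon, applies the distance predicates literally, position by position.
# indel_ivs: matrix with columns start, end (0-based half-open intervals
# in this sequence's coordinates; zero-length for the gapped side).
brute_force_regions <- function(L, indel_ivs, clearance = 45,
                                flank_codons = 15, min_sep = 90) {
  n_codons <- L %/% 3
  starts <- 3 * (seq_len(n_codons) - 1)
  dist_to_indel <- function(pos, s, e) {
    if (pos >= s && pos < e) {
      return(0)
    }
    if (pos < s) s - pos else pos - e + 1
  }
  remote <- vapply(starts, function(cs) {
    all(vapply(seq_len(nrow(indel_ivs)), function(k) {
      all(vapply(cs:(cs + 2), dist_to_indel,
        numeric(1),
        s = indel_ivs[k, 1], e = indel_ivs[k, 2]
      ) > clearance)
    }, logical(1)))
  }, logical(1))
  flank5 <- flank3 <- rep(FALSE, n_codons)
  for (k in seq_len(nrow(indel_ivs))) {
    s <- indel_ivs[k, 1]
    e <- indel_ivs[k, 2]
    # eligibility at the terminals
    if (!(s > clearance && (L - e) > clearance)) next
    others <- indel_ivs[-k, , drop = FALSE]
    # 5' flank: the flank_codons whole codons ending at or before s
    prev_end <- if (nrow(others) > 0) {
      suppressWarnings(max(others[others[, 2] <= s, 2]))
    } else {
      -Inf
    }
    if (!(is.finite(prev_end) && s - prev_end < min_sep)) {
      # whole codons fully inside [cb5 - 45, cb5)
      cb5 <- (s %/% 3) * 3
      flank5 <- flank5 | (starts >= cb5 - 3 * flank_codons & starts + 3 <= cb5)
    }
    next_start <- if (nrow(others) > 0) {
      suppressWarnings(min(others[others[, 1] >= e, 1]))
    } else {
      Inf
    }
    if (!(is.finite(next_start) && next_start - e < min_sep)) {
      cb3 <- as.integer(ceiling(e / 3)) * 3
      flank3 <- flank3 | (starts >= cb3 & starts + 3 <= cb3 + 3 * flank_codons)
    }
  }
  list(
    flank5 = starts[flank5], flank3 = starts[flank3],
    remote = starts[remote]
  )
}

# Shared small fixtures ------------------------------------------------

# codon_counts built from an explicit named codon multiset
counts_from <- function(...) {
  spec <- c(...)
  scubshift::count_synonymous_codons(rep(names(spec), spec))
}
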