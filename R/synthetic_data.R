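# Ground-truthed synthetic data: ancestral CDS sets with C/G-ending codon
# dominance, a derived set produced by single-generation point mutation
# with elevated CpG deamination (C->T at the C of CpG, G->A at the G of
# CpG, equal weight), frame-preserving deletions, and substitution
# enrichment within a window of each indel. Every mutation event is
# recorded so the derived sequences can be replayed exactly.

#' Default synonymous codon usage with C/G-ending dominance
#'
#' Probability vector over the 59 synonymous codons in which C/G-ending
#' codons carry `cg_weight` times the weight of A/T-ending ones,
#' emulating the GC3-rich composition typical of grass (Poaceae) coding
#' sequences.
#'
#' @param cg_weight Relative weight of C/G-ending codons (default 1.5).
#' @return Named probability vector over [sc_codons()].
#' @export
default_codon_usage <- function(cg_weight = 1.5) {
  stopifnot(cg_weight > 0)
  tab <- codon_metadata()
  sc <- tab[tab$sc, ]
  w <- ifelse(sc$third %in% c("C", "G"), cg_weight, 1)
  setNames(w / sum(w), sc$codon)
}

#' Generate an ancestral CDS set
#'
#' Each record is an ATG start codon followed by codons drawn i.i.d. from
#' `codon_usage` (a distribution over the synonymous set, so no internal
#' stops arise). Reproducible for a fixed seed.
#'
#' @param n_records Number of CDS records.
#' @param lengths Body lengths in codons (excluding the ATG start):
#'   either an integer vector of length `n_records`, a single integer
#'   recycled, or `NULL` for the default log-normal length model
#'   (median 150 codons, sdlog 0.35, clamped to 50..800), the scale of
#'   EST-derived unigene CDSs.
#' @param codon_usage Named probability vector over [sc_codons()]
#'   (must sum to 1 within 1e-9).
#' @param seed Integer seed.
#' @param sample Sample label for the returned cds set.
#' @param id_prefix Record id prefix.
#' @return A cds-set `data.frame` (`id`, `sequence`, `sample`,
#'   `frame_offset`).
#' @export
generate_ancestral_cds <- function(n_records, lengths = NULL,
                                   codon_usage = default_codon_usage(),
                                   seed = 1L, sample = "recipient",
                                   id_prefix = "cds") {
  stopifnot(n_records >= 0)
  if (!setequal(names(codon_usage), sc_codons())) {
    stop("codon_usage must be named by the 59 synonymous codons",
      call. = FALSE
    )
  }
  if (abs(sum(codon_usage) - 1) > 1e-9) {
    stop("codon_usage must sum to 1 (within 1e-9)", call. = FALSE)
  }
  empty <- data.frame(
    id = character(), sequence = character(), sample = character(),
    frame_offset = integer(), stringsAsFactors = FALSE
  )
  if (n_records == 0L) {
    return(empty)
  }
  set.seed(seed)
  if (is.null(lengths)) {
    lengths <- pmin(pmax(round(rlnorm(n_records, log(150), 0.35)), 50L), 800L)
  } else {
    lengths <- as.integer(rep_len(lengths, n_records))
    stopifnot(all(lengths >= 1L))
  }
  codons <- base::sample(names(codon_usage), sum(lengths),
    replace = TRUE, prob = codon_usage
  )
  grp <- rep.int(seq_len(n_records), lengths)
  bodies <- vapply(
    split(codons, grp),
    paste0,
    character(1),
    collapse = ""
  )
  data.frame(
    id = sprintf("%s%05d", id_prefix, seq_len(n_records)),
    sequence = paste0("ATG", unname(bodies)),
    sample = sample,
    frame_offset = 0L,
    stringsAsFactors = FALSE
  )
}

#' Mutation model parameters
#'
#' @param sub_rate Per-site substitution probability (baseline).
#' @param cpg_multiplier Rate multiplier for sites in CpG context,
#'   applied as deterministic deamination: C->T at the C of a CpG and,
#'   with equal weight, G->A at the G.
#' @param indel_rate Expected number of indels per CDS (Poisson).
#' @param indel_len Candidate indel lengths in nt (default multiples of 3
#'   so frame is preserved).
#' @param indel_len_prob Sampling weights for `indel_len`.
#' @param flank_multiplier Substitution multiplier within `flank_window`
#'   nt of an indel (composes with the CpG multiplier; the effective
#'   per-site probability is clamped to 1 with a logged count).
#' @param flank_window Enrichment window in nt (default 45).
#' @param seed Integer master seed; per-record substreams are derived
#'   deterministically from it.
#' @return A `mutation_params` list.
#' @export
mutation_params <- function(sub_rate = 0.01, cpg_multiplier = 10,
                            indel_rate = 0.5, indel_len = c(3L, 6L, 9L),
                            indel_len_prob = c(0.5, 0.3, 0.2),
                            flank_multiplier = 10, flank_window = 45L,
                            seed = 1L) {
  stopifnot(
    sub_rate >= 0, sub_rate <= 1,
    cpg_multiplier >= 1, flank_multiplier >= 1,
    indel_rate >= 0, flank_window >= 0,
    length(indel_len) == length(indel_len_prob),
    all(indel_len >= 1L)
  )
  structure(
    list(
      sub_rate = sub_rate, cpg_multiplier = cpg_multiplier,
      indel_rate = indel_rate, indel_len = as.integer(indel_len),
      indel_len_prob = indel_len_prob / sum(indel_len_prob),
      flank_multiplier = flank_multiplier,
      flank_window = as.integer(flank_window),
      seed = as.integer(seed)
    ),
    class = "mutation_params"
  )
}

# deterministic per-record substream seed, kept within 32-bit range
record_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483647)
}

# Place k codon-aligned deletion intervals in an n-nt CDS, respecting
# terminal clearance (> 45 nt to either end) and a minimum edge-to-edge
# separation. Returns a matrix with columns start, end (0-based
# half-open); may place fewer than k when space runs out.
place_indels <- function(n, k, lens, min_sep = 90L, clearance = 45L) {
  placed <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  for (j in seq_len(k)) {
    len <- lens[j]
    starts <- seq.int(0L, n - len, by = 3L)
    ok <- starts > clearance & (n - (starts + len)) > clearance
    if (nrow(placed) > 0L) {
      for (r in seq_len(nrow(placed))) {
        ok <- ok & (starts >= placed[r, "end"] + min_sep |
          starts + len <= placed[r, "start"] - min_sep)
      }
    }
    cand <- starts[ok]
    if (length(cand) == 0L) next
    s <- cand[base::sample.int(length(cand), 1L)]
    placed <- rbind(placed, c(start = s, end = s + len))
  }
  placed[order(placed[, "start"]), , drop = FALSE]
}

#' Mutate an ancestral CDS set into a derived (hybrid) set
#'
#' Single-generation point mutation plus frame-preserving deletions.
#' Substitution probability per site is `sub_rate`, multiplied by
#' `cpg_multiplier` in CpG context (evaluated on the pre-mutation
#' ancestral sequence) and by `flank_multiplier` within `flank_window` nt
#' of an indel; multipliers compose and the result is clamped to 1.
#' CpG-context hits deaminate deterministically (C->T, G->A); other hits
#' mutate to one of the three alternative bases uniformly. A substitution
#' that would create an internal stop codon is resampled among
#' non-stop-producing alternatives (or dropped if none exists); the
#' resample count is recorded. Deleted sites do not mutate. Alignments
#' are emitted gap-exactly from the truth, no realignment involved.
#'
#' @param ancestral A cds-set `data.frame` from
#'   [generate_ancestral_cds()] (frame offset 0).
#' @param params A [mutation_params()] object.
#' @param sample Sample label for the derived set.
#' @return List with `derived` (cds set), `alignments` (list of
#'   `pairwise_alignment`, ancestral as side a), and `truth` (list with
#'   `substitutions` and `indels` data.frames, `n_resampled`,
#'   `n_clamped`, and the `params`).
#' @export
mutate_genome <- function(ancestral, params, sample = "hybrid") {
  stopifnot(inherits(params, "mutation_params"))
  n_rec <- nrow(ancestral)
  derived_seqs <- character(n_rec)
  alignments <- vector("list", n_rec)
  subs_list <- vector("list", n_rec)
  indel_list <- vector("list", n_rec)
  n_resampled <- 0L
  n_clamped <- 0L
  stops <- stop_codons()
  for (i in seq_len(n_rec)) {
    set.seed(record_seed(params$seed, i))
    b <- strsplit(ancestral$sequence[i], "", fixed = TRUE)[[1]]
    n <- length(b)
    # --- indel placement (ancestral coordinates, codon aligned) ---
    k <- rpois(1L, params$indel_rate)
    ivs <- matrix(integer(), 0L, 2L,
      dimnames = list(NULL, c("start", "end"))
    )
    if (k > 0L && n >= 3L) {
      lens <- params$indel_len[base::sample.int(
        length(params$indel_len), k,
        replace = TRUE, prob = params$indel_len_prob
      )]
      # fixed 45-nt terminal clearance so placed indels are eligible for
      # flank extraction by construction
      ivs <- place_indels(n, k, lens, min_sep = 90L, clearance = 45L)
    }
    deleted <- rep(FALSE, n)
    if (nrow(ivs) > 0L) {
      for (r in seq_len(nrow(ivs))) {
        deleted[(ivs[r, "start"] + 1L):ivs[r, "end"]] <- TRUE
      }
    }
    # --- per-site substitution probability ---
    is_cpg <- rep(FALSE, n)
    if (n >= 2L) {
      cg <- b[-n] == "C" & b[-1L] == "G"
      is_cpg[-n] <- cg # the C of CpG
      is_cpg[-1L] <- is_cpg[-1L] | cg # the G of CpG
    }
    in_flank <- rep(FALSE, n)
    if (nrow(ivs) > 0L && params$flank_window > 0L) {
      pos <- seq_len(n) - 1L
      for (r in seq_len(nrow(ivs))) {
        in_flank <- in_flank |
          (pos >= ivs[r, "start"] - params$flank_window &
            pos < ivs[r, "end"] + params$flank_window)
      }
    }
    p <- rep.int(params$sub_rate, n)
    if (params$cpg_multiplier != 1) {
      p[is_cpg] <- p[is_cpg] * params$cpg_multiplier
    }
    if (any(in_flank) && params$flank_multiplier != 1) {
      p[in_flank] <- p[in_flank] * params$flank_multiplier
    }
    n_clamped <- n_clamped + sum(p > 1)
    p <- pmin(p, 1)
    p[deleted] <- 0
    hits <- which(runif(n) < p)
    b2 <- b
    if (length(hits) > 0L) {
      target <- character(length(hits))
      hit_cpg <- is_cpg[hits]
      target[hit_cpg & b[hits] == "C"] <- "T"
      target[hit_cpg & b[hits] == "G"] <- "A"
      rest <- which(target == "")
      if (length(rest) > 0L) {
        # row r of ALT_BASES holds the three alternatives to base r
        alt <- matrix(
          c(
            "C", "G", "T", # A ->
            "A", "G", "T", # C ->
            "A", "C", "T", # G ->
            "A", "C", "G" # T ->
          ),
          nrow = 4L, byrow = TRUE, dimnames = list(DNA_BASES, NULL)
        )
        target[rest] <- alt[cbind(
          match(b[hits[rest]], DNA_BASES),
          base::sample.int(3L, length(rest), replace = TRUE)
        )]
      }
      b2[hits] <- target
      # --- resample substitutions creating internal stop codons ---
      n_full <- n %/% 3L
      touched <- unique((hits - 1L) %/% 3L)
      touched <- touched[touched < n_full]
      for (ci in touched) {
        span <- (3L * ci + 1L):(3L * ci + 3L)
        if (!paste0(b2[span], collapse = "") %in% stops) next
        for (pos in intersect(hits, span)) {
          alts <- setdiff(DNA_BASES, b[pos])
          ok_alts <- alts[vapply(alts, function(a) {
            trial <- b2[span]
            trial[span == pos] <- a
            !paste0(trial, collapse = "") %in% stops
          }, logical(1))]
          if (length(ok_alts) > 0L) {
            b2[pos] <- ok_alts[base::sample.int(length(ok_alts), 1L)]
          } else {
            b2[pos] <- b[pos] # drop the substitution
          }
          n_resampled <- n_resampled + 1L
          if (!paste0(b2[span], collapse = "") %in% stops) break
        }
      }
      changed <- hits[b2[hits] != b[hits]]
      if (length(changed) > 0L) {
        subs_list[[i]] <- data.frame(
          record_id = ancestral$id[i],
          pos = changed - 1L,
          from = b[changed],
          to = b2[changed],
          cpg = is_cpg[changed],
          flank = in_flank[changed],
          stringsAsFactors = FALSE
        )
      }
    }
    if (nrow(ivs) > 0L) {
      indel_list[[i]] <- data.frame(
        record_id = ancestral$id[i],
        pos = unname(ivs[, "start"]),
        length = unname(ivs[, "end"] - ivs[, "start"]),
        type = "deletion",
        stringsAsFactors = FALSE
      )
    }
    derived_seqs[i] <- paste0(b2[!deleted], collapse = "")
    aligned_b <- b2
    aligned_b[deleted] <- "-"
    alignments[[i]] <- pairwise_alignment(
      ancestral$id[i], ancestral$id[i],
      ancestral$sequence[i], paste0(aligned_b, collapse = "")
    )
  }
  if (n_clamped > 0L) {
    message(
      "mutate_genome: ", n_clamped,
      " site probabilities clamped to 1 (multipliers compose)"
    )
  }
  empty_subs <- data.frame(
    record_id = character(), pos = integer(), from = character(),
    to = character(), cpg = logical(), flank = logical(),
    stringsAsFactors = FALSE
  )
  empty_indels <- data.frame(
    record_id = character(), pos = integer(), length = integer(),
    type = character(), stringsAsFactors = FALSE
  )
  subs <- do.call(rbind, c(list(empty_subs), subs_list[!vapply(
    subs_list, is.null, logical(1)
  )]))
  indels <- do.call(rbind, c(list(empty_indels), indel_list[!vapply(
    indel_list, is.null, logical(1)
  )]))
  list(
    derived = data.frame(
      id = ancestral$id,
      sequence = derived_seqs,
      sample = sample,
      frame_offset = 0L,
      stringsAsFactors = FALSE
    ),
    alignments = alignments,
    truth = list(
      substitutions = subs,
      indels = indels,
      n_resampled = n_resampled,
      n_clamped = n_clamped,
      params = unclass(params)
    )
  )
}

#' Replay recorded mutation events
#'
#' Applies the substitution and deletion events of a truth record to the
#' ancestral sequences; the result must equal the derived set
#' byte-exactly (truth invariant).
#'
#' @param ancestral The ancestral cds set.
#' @param truth The `truth` element of a [mutate_genome()] result.
#' @return Character vector of derived sequences, named by record id.
#' @export
replay_truth <- function(ancestral, truth) {
  out <- setNames(character(nrow(ancestral)), ancestral$id)
  for (i in seq_len(nrow(ancestral))) {
    id <- ancestral$id[i]
    b <- strsplit(ancestral$sequence[i], "", fixed = TRUE)[[1]]
    s <- truth$substitutions[truth$substitutions$record_id == id, ,
      drop = FALSE
    ]
    if (nrow(s) > 0L) b[s$pos + 1L] <- s$to
    d <- truth$indels[truth$indels$record_id == id, , drop = FALSE]
    if (nrow(d) > 0L) {
      drop_idx <- unlist(lapply(seq_len(nrow(d)), function(r) {
        (d$pos[r] + 1L):(d$pos[r] + d$length[r])
      }))
      b <- b[-drop_idx]
    }
    out[i] <- paste0(b, collapse = "")
  }
  out
}

#' Assign records to wheat chromosomes
#'
#' Uniform assignment over the 21 chromosomes, with a fraction left
#' unmapped. Reproducible for a fixed seed.
#'
#' @param record_ids Character vector of record ids.
#' @param introgressed Introgressed chromosome set (validated against the
#'   21 wheat chromosome names); stored only for downstream convenience.
#' @param unmapped_frac Probability a record is unmapped.
#' @param seed Integer seed.
#' @return `data.frame` with columns `record_id`, `chromosome`.
#' @export
assign_chromosomes <- function(record_ids,
                               introgressed =
                                 default_introgressed_chromosomes(),
                               unmapped_frac = 0.05, seed = 1L) {
  stopifnot(unmapped_frac >= 0, unmapped_frac <= 1)
  introgressed <- vapply(introgressed, parse_chromosome, character(1))
  if (anyNA(introgressed) ||
    !all(introgressed %in% wheat_chromosomes())) {
    stop("introgressed set must be valid wheat chromosome names",
      call. = FALSE
    )
  }
  set.seed(seed)
  n <- length(record_ids)
  chrom <- base::sample(wheat_chromosomes(), n, replace = TRUE)
  chrom[runif(n) < unmapped_frac] <- "unmapped"
  data.frame(
    record_id = record_ids,
    chromosome = chrom,
    stringsAsFactors = FALSE
  )
}
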