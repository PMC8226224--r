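# Indel detection in recipient/hybrid pairwise CDS alignments and
# classification of codons into 5'-flank, 3'-flank and remote regions.
#
# Distance conventions (all 0-based, half-open, measured in each
# sequence's own ungapped coordinates):
#   * an indel occupies an interval [s, e) in the sequence that carries
#     the residues and a zero-length point [p, p) in the gapped sequence;
#   * flanks are the 15 complete in-frame codons (45 nt) immediately 5'
#     and 3' of the indel; a codon broken by the indel boundary belongs to
#     neither flank;
#   * indels closer than 46 nt to either CDS terminus are ineligible for
#     flank extraction; an inter-indel segment shorter than 90 nt
#     contributes to no flank (and, by geometry, to no remote set);
#   * remote codons have every nucleotide more than 45 nt away from every
#     indel.

#' Construct a pairwise alignment object
#'
#' @param id_a,id_b Record ids.
#' @param aligned_a,aligned_b Equal-length gapped sequences (gap `-`).
#' @param frame_offset_a,frame_offset_b 0-based frame offsets of the
#'   ungapped sequences.
#' @return A `pairwise_alignment` object.
#' @export
pairwise_alignment <- function(id_a, id_b, aligned_a, aligned_b,
                               frame_offset_a = 0L, frame_offset_b = 0L) {
  aligned_a <- toupper(aligned_a)
  aligned_b <- toupper(aligned_b)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ga <- strsplit(aligned_a, "", fixed = TRUE)[[1]] == "-"
  gb <- strsplit(aligned_b, "", fixed = TRUE)[[1]] == "-"
  if (any(ga & gb)) {
    stop("alignment has a column gapped in both sequences", call. = FALSE)
  }
  structure(
    list(
      id_a = id_a, id_b = id_b,
      aligned_a = aligned_a, aligned_b = aligned_b,
      frame_offset_a = as.integer(frame_offset_a),
      frame_offset_b = as.integer(frame_offset_b)
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(
    "<pairwise_alignment>", x$id_a, "vs", x$id_b,
    "| columns:", nchar(x$aligned_a),
    "| indels:", nrow(find_indels(x)), "\n"
  )
  invisible(x)
}

#' Remove gap characters
#' @param x Gapped sequence string.
#' @return Ungapped sequence.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Globally align two CDS sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' `Biostrings::pairwiseAlignment()`. Deterministic for fixed inputs and
#' parameters; gap placement on ties follows the underlying dynamic
#' program. Pre-aligned input should be wrapped with
#' [pairwise_alignment()] directly instead.
#'
#' @param seq_a,seq_b Nucleotide strings (nonempty).
#' @param id_a,id_b Record ids stored in the result.
#' @param match,mismatch Substitution scores.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return A `pairwise_alignment`.
#' @export
align_pair <- function(seq_a, seq_b, id_a = "a", id_b = "b",
                       match = 1, mismatch = -2,
                       gap_opening = 4, gap_extension = 1) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pairwise_alignment(
    id_a, id_b,
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln))
  )
}

#' Find all indels in a pairwise alignment
#'
#' Maximal gap runs on either side, sorted by alignment column. Adjacent
#' runs on opposite sides are distinct events. Coordinates are 0-based
#' half-open: `col_start`/`col_end` in alignment columns, `ua_*`/`ub_*`
#' the event's span in each sequence's ungapped coordinates (a zero-length
#' interval on the side carrying the gap).
#'
#' @param aln A `pairwise_alignment`.
#' @return `data.frame` with one row per indel: `col_start`, `col_end`,
#'   `length_nt`, `gapped_side` ("a"/"b"), `ua_start`, `ua_end`,
#'   `ub_start`, `ub_end`.
#' @export
find_indels <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  ga <- ca == "-"
  gb <- cb == "-"
  # residues strictly before column i (1-based) in each sequence
  before_a <- c(0L, cumsum(!ga))
  before_b <- c(0L, cumsum(!gb))
  runs_for <- function(g, side) {
    if (!any(g)) {
      return(NULL)
    }
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(
      col_start = starts[keep] - 1L,
      col_end = ends[keep],
      length_nt = r$lengths[keep],
      gapped_side = side,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(runs_for(ga, "a"), runs_for(gb, "b"))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(
      col_start = integer(), col_end = integer(), length_nt = integer(),
      gapped_side = character(), ua_start = integer(), ua_end = integer(),
      ub_start = integer(), ub_end = integer(), stringsAsFactors = FALSE
    ))
  }
  out$ua_start <- before_a[out$col_start + 1L]
  out$ua_end <- before_a[out$col_end + 1L]
  out$ub_start <- before_b[out$col_start + 1L]
  out$ub_end <- before_b[out$col_end + 1L]
  out <- out[order(out$col_start, out$gapped_side), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter indels eligible for flank extraction
#'
#' Keeps indels whose ungapped distance from the CDS start and from the
#' CDS end strictly exceeds `clearance` nucleotides in both sequences,
#' avoiding terminal effects.
#'
#' @param indels `data.frame` from [find_indels()].
#' @param aln The `pairwise_alignment` the indels came from.
#' @param clearance Minimum terminal distance in nt (default 45; the rule
#'   is strict, i.e. distance > 45).
#' @return The eligible subset of `indels`.
#' @export
filter_eligible_indels <- function(indels, aln, clearance = 45L) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (nrow(indels) == 0L) {
    return(indels)
  }
  la <- nchar(ungap(aln$aligned_a))
  lb <- nchar(ungap(aln$aligned_b))
  keep <- indels$ua_start > clearance & (la - indels$ua_end) > clearance &
    indels$ub_start > clearance & (lb - indels$ub_end) > clearance
  out <- indels[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Indel intervals [start, end) in one sequence's ungapped coordinates.
indel_intervals <- function(indels, side = c("a", "b")) {
  side <- match.arg(side)
  if (side == "a") {
    cbind(start = indels$ua_start, end = indels$ua_end)
  } else {
    cbind(start = indels$ub_start, end = indels$ub_end)
  }
}

# Window of complete in-frame codons for one flank of one indel, in one
# sequence. Returns list(start, end, kept, truncated); start/end are nt
# coordinates (0-based half-open), NULL window encoded as kept = FALSE.
flank_window <- function(s0, e0, L, off, intervals, self,
                         flank_codons = 15L, min_sep = 90L, side5 = TRUE) {
  win_nt <- 3L * flank_codons
  if (side5) {
    cb <- off + ((s0 - off) %/% 3L) * 3L # codon boundary at or before s0
    w_start <- cb - win_nt
    w_end <- cb
    # nearest indel wholly 5' of this one
    others <- intervals[-self, , drop = FALSE]
    prev_end <- suppressWarnings(max(others[others[, "end"] <= s0, "end"]))
    if (is.finite(prev_end) && (s0 - prev_end) < min_sep) {
      return(list(start = NA_integer_, end = NA_integer_, kept = FALSE,
        truncated = FALSE))
    }
    truncated <- FALSE
    if (w_start < off) {
      w_start <- off
      truncated <- TRUE
    }
  } else {
    cb <- off + as.integer(ceiling((e0 - off) / 3)) * 3L
    w_start <- cb
    w_end <- cb + win_nt
    others <- intervals[-self, , drop = FALSE]
    next_start <- suppressWarnings(
      min(others[others[, "start"] >= e0, "start"])
    )
    if (is.finite(next_start) && (next_start - e0) < min_sep) {
      return(list(start = NA_integer_, end = NA_integer_, kept = FALSE,
        truncated = FALSE))
    }
    last_cb <- off + ((L - off) %/% 3L) * 3L
    truncated <- FALSE
    if (w_end > last_cb) {
      w_end <- last_cb
      truncated <- TRUE
    }
  }
  if (w_end <= w_start) {
    return(list(start = NA_integer_, end = NA_integer_, kept = FALSE,
      truncated = truncated))
  }
  list(
    start = as.integer(unname(w_start)), end = as.integer(unname(w_end)),
    kept = TRUE, truncated = truncated
  )
}

codons_in_span <- function(sequence, start, end) {
  # complete codons covering nt span [start, end); caller guarantees the
  # span is codon-aligned
  n <- (end - start) %/% 3L
  if (n < 1L) {
    return(character())
  }
  starts <- start + 3L * seq_len(n) - 2L
  substring(sequence, starts, starts + 2L)
}

#' Extract 5'- and 3'-flanking codon windows of one indel
#'
#' For each sequence of the alignment, the 15 complete in-frame codons
#' immediately 5' and immediately 3' of the indel, in that sequence's own
#' ungapped coordinates. A codon broken by the indel boundary is
#' discarded. A window adjoining an inter-indel segment shorter than
#' `min_sep` nt is dropped entirely (`kept = FALSE`); a window running
#' into the CDS terminus is truncated and flagged.
#'
#' @param aln A `pairwise_alignment`.
#' @param indel One row of [find_indels()] output (eligible per
#'   [filter_eligible_indels()]).
#' @param indels All indels of the alignment (used for the inter-indel
#'   rule); defaults to `find_indels(aln)`.
#' @param flank_codons Window size in codons (default 15, i.e. 45 nt).
#' @param min_sep Minimum inter-indel segment length in nt (default 90).
#' @return List with elements `a` and `b`; each holds `flank5` and
#'   `flank3`, each a list with `start`, `end` (nt, 0-based half-open),
#'   `codons` (character vector), `kept` and `truncated`.
#' @export
extract_flanking_windows <- function(aln, indel, indels = find_indels(aln),
                                     flank_codons = 15L, min_sep = 90L) {
  stopifnot(inherits(aln, "pairwise_alignment"), nrow(indel) == 1L)
  self <- which(
    indels$col_start == indel$col_start &
      indels$gapped_side == indel$gapped_side
  )
  if (length(self) != 1L) {
    stop("indel not found among the alignment's indels", call. = FALSE)
  }
  out <- list()
  for (side in c("a", "b")) {
    seq_s <- ungap(aln[[paste0("aligned_", side)]])
    off <- aln[[paste0("frame_offset_", side)]]
    ivs <- indel_intervals(indels, side)
    s0 <- ivs[self, "start"]
    e0 <- ivs[self, "end"]
    w5 <- flank_window(s0, e0, nchar(seq_s), off, ivs, self,
      flank_codons, min_sep,
      side5 = TRUE
    )
    w3 <- flank_window(s0, e0, nchar(seq_s), off, ivs, self,
      flank_codons, min_sep,
      side5 = FALSE
    )
    w5$codons <- if (w5$kept) codons_in_span(seq_s, w5$start, w5$end) else character()
    w3$codons <- if (w3$kept) codons_in_span(seq_s, w3$start, w3$end) else character()
    out[[side]] <- list(flank5 = w5, flank3 = w3)
  }
  out
}

#' Extract indel-remote codons
#'
#' All complete in-frame codons whose every nucleotide lies strictly more
#' than `clearance` nt (ungapped) from every indel. For an alignment with
#' no indels the whole CDS is remote. Inter-indel segments shorter than
#' 90 nt are excluded automatically by the distance predicate.
#'
#' @param aln A `pairwise_alignment`.
#' @param indels Indels to stay clear of; defaults to all indels of the
#'   alignment.
#' @param clearance Distance threshold in nt (default 45).
#' @return List with elements `a` and `b`; each a list with `codon_start`
#'   (0-based nt starts) and `codons`.
#' @export
extract_remote_regions <- function(aln, indels = find_indels(aln),
                                   clearance = 45L) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  out <- list()
  for (side in c("a", "b")) {
    seq_s <- ungap(aln[[paste0("aligned_", side)]])
    off <- aln[[paste0("frame_offset_", side)]]
    L <- nchar(seq_s)
    n_codons <- (L - off) %/% 3L
    if (n_codons < 1L) {
      out[[side]] <- list(codon_start = integer(), codons = character())
      next
    }
    cs <- off + 3L * (seq_len(n_codons) - 1L) # codon starts
    remote <- rep(TRUE, n_codons)
    if (nrow(indels) > 0L) {
      ivs <- indel_intervals(indels, side)
      for (k in seq_len(nrow(ivs))) {
        s0 <- ivs[k, "start"]
        e0 <- ivs[k, "end"]
        # codon [c, c+3) is clear of this indel iff it ends at least
        # clearance+1 nt before it starts, or starts at least clearance
        # nt after it ends
        remote <- remote & (cs + 3L <= s0 - clearance | cs >= e0 + clearance)
      }
    }
    keep <- cs[remote]
    out[[side]] <- list(
      codon_start = keep,
      codons = substring(seq_s, keep + 1L, keep + 3L)
    )
  }
  out
}

#' Pool region codon lists for one alignment
#'
#' Convenience wrapper: for each sequence of the alignment, collects the
#' whole-CDS codon list, the pooled 5'- and 3'-flank codons over all
#' eligible indels, and the remote codons.
#'
#' @param aln A `pairwise_alignment`.
#' @param flank_codons,min_sep,clearance See [extract_flanking_windows()]
#'   and [extract_remote_regions()].
#' @return List with elements `a` and `b`; each a list of codon vectors
#'   `whole`, `flank5`, `flank3`, `remote`, plus `n_eligible_indels`.
#' @export
alignment_region_codons <- function(aln, flank_codons = 15L, min_sep = 90L,
                                    clearance = 45L) {
  indels <- find_indels(aln)
  eligible <- filter_eligible_indels(indels, aln, clearance)
  remote <- extract_remote_regions(aln, indels, clearance)
  out <- list()
  for (side in c("a", "b")) {
    seq_s <- ungap(aln[[paste0("aligned_", side)]])
    off <- aln[[paste0("frame_offset_", side)]]
    out[[side]] <- list(
      whole = if (nchar(seq_s) - off >= 3L) {
        extract_codons(seq_s, off)
      } else {
        character()
      },
      flank5 = character(),
      flank3 = character(),
      remote = remote[[side]]$codons,
      n_eligible_indels = nrow(eligible)
    )
  }
  if (nrow(eligible) > 0L) {
    for (k in seq_len(nrow(eligible))) {
      wins <- extract_flanking_windows(
        aln, eligible[k, , drop = FALSE], indels, flank_codons, min_sep
      )
      for (side in c("a", "b")) {
        out[[side]]$flank5 <- c(out[[side]]$flank5, wins[[side]]$flank5$codons)
        out[[side]]$flank3 <- c(out[[side]]$flank3, wins[[side]]$flank3$codons)
      }
    }
  }
  out
}

#' Region-wise SCUB frequencies
#'
#' Pools codon lists per region class and computes ending frequencies.
#' `two_sides` is the pool of `flank5` and `flank3`.
#'
#' @param regions Named list with codon vectors (or lists of vectors)
#'   `whole`, `flank5`, `flank3`, `remote`.
#' @return Named list of `ending_frequencies` for `whole`, `flank5`,
#'   `flank3`, `two_sides`, `remote`; an empty region yields `NA` with a
#'   warning.
#' @export
regional_scub <- function(regions) {
  stopifnot(all(c("whole", "flank5", "flank3", "remote") %in% names(regions)))
  pools <- list(
    whole = regions$whole,
    flank5 = regions$flank5,
    flank3 = regions$flank3,
    two_sides = c(
      unlist(regions$flank5, use.names = FALSE),
      unlist(regions$flank3, use.names = FALSE)
    ),
    remote = regions$remote
  )
  lapply(names(pools), function(nm) {
    cc <- count_synonymous_codons(pools[[nm]])
    if (cc$n_sc == 0L) {
      warning("region '", nm, "' has an empty synonymous-codon pool",
        call. = FALSE
      )
      return(NA)
    }
    total_ending_frequencies(cc)
  }) |> setNames(names(pools))
}

#' Read pre-aligned FASTA pairs
#'
#' Reads an aligned FASTA in which consecutive records form
#' recipient/hybrid pairs of equal gapped length.
#'
#' @param path Aligned FASTA file (gap character `-`), records in pairs.
#' @return List of `pairwise_alignment` objects.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) %% 2L != 0L) {
    stop("aligned FASTA must contain an even number of records",
      call. = FALSE
    )
  }
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_len(length(set) / 2L), function(k) {
    i <- 2L * k - 1L
    pairwise_alignment(
      ids[i], ids[i + 1L],
      as.character(set[[i]]), as.character(set[[i + 1L]])
    )
  })
}

#' Write an alignment list to aligned FASTA
#'
#' @param alignments List of `pairwise_alignment` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(alignments, path) {
  seqs <- unlist(lapply(alignments, function(a) {
    setNames(c(a$aligned_a, a$aligned_b), c(a$id_a, a$id_b))
  }))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
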