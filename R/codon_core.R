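# SCUB core: codon extraction from CDS sequences and third-position
# frequency computation over the 59-codon synonymous set.

#' Split a CDS into in-frame codons
#'
#' Reads `floor((nchar - frame_offset) / 3)` codons starting at
#' `frame_offset` (0-based); a trailing partial codon is dropped. The
#' sequence is uppercased first. No alphabet check is done here: codons
#' containing ambiguity codes are dropped later, at counting time.
#'
#' @param sequence Single nucleotide string.
#' @param frame_offset Integer 0-2, 0-based position of the first in-frame
#'   base.
#' @return Character vector of codons, in order.
#' @export
extract_codons <- function(sequence, frame_offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0L || frame_offset > 2L) {
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  n_codons <- (n - frame_offset) %/% 3L
  if (n_codons < 1L) {
    stop("sequence shorter than one complete codon", call. = FALSE)
  }
  starts <- frame_offset + 3L * seq_len(n_codons) - 2L
  substring(sequence, starts, starts + 2L)
}

#' Tally codons, tracking the synonymous subset
#'
#' Every ACGT codon is tallied; `n_sc` counts only members of the 59-codon
#' synonymous set (stops, ATG and TGG are tallied but excluded from
#' `n_sc`). Codons containing a character outside ACGT (ambiguity codes
#' such as N) are dropped from all tallies; the number dropped is kept in
#' the `n_dropped` field so attrition stays auditable.
#'
#' @param codons Character vector of codons (e.g. from
#'   [extract_codons()]), or a list of such vectors which is pooled.
#' @return A `codon_counts` object: list with `counts` (named integer
#'   vector over the 64 codons), `n_sc`, and `n_dropped`.
#' @export
count_synonymous_codons <- function(codons) {
  if (is.list(codons)) codons <- unlist(codons, use.names = FALSE)
  if (is.null(codons)) codons <- character()
  stopifnot(is.character(codons))
  codons <- toupper(codons)
  idx <- match(codons, all_codons())
  n_dropped <- sum(is.na(idx))
  counts <- tabulate(idx[!is.na(idx)], nbins = 64L)
  names(counts) <- all_codons()
  new_codon_counts(counts, n_dropped = n_dropped)
}

new_codon_counts <- function(counts, n_dropped = 0L) {
  stopifnot(length(counts) == 64L, all(counts >= 0))
  structure(
    list(
      counts = counts,
      n_sc = sum(counts[codon_metadata()$sc]),
      n_dropped = as.integer(n_dropped)
    ),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(
    "<codon_counts> total =", sum(x$counts),
    "| synonymous n_sc =", x$n_sc,
    "| dropped =", x$n_dropped, "\n"
  )
  invisible(x)
}

#' @export
`+.codon_counts` <- function(e1, e2) {
  stopifnot(inherits(e1, "codon_counts"), inherits(e2, "codon_counts"))
  new_codon_counts(e1$counts + e2$counts,
    n_dropped = e1$n_dropped + e2$n_dropped
  )
}

#' Pool a list of codon_counts objects
#' @param x List of `codon_counts`.
#' @return A single pooled `codon_counts`.
#' @export
pool_codon_counts <- function(x) {
  stopifnot(is.list(x))
  if (length(x) == 0L) {
    return(count_synonymous_codons(character()))
  }
  Reduce(`+`, x)
}

#' Per-amino-acid SCUB frequency
#'
#' Ratio of the amino acid's C/G-ending synonymous codon count to its
#' A/T-ending synonymous codon count. All codons of the amino acid are
#' pooled (serine's two codon families are counted together; see
#' `per_aa_ag_pair_ratio()` for the family-restricted analysis).
#'
#' @param counts A `codon_counts` object.
#' @param aa Amino acid, one-letter ("A") or three-letter ("Ala") symbol.
#'   Must be one of the 18 amino acids with degenerate coding.
#' @return The ratio, or `NA_real_` when the A/T-ending denominator is 0
#'   (explicit undefined flag).
#' @export
per_aa_scub_frequency <- function(counts, aa) {
  stopifnot(inherits(counts, "codon_counts"))
  aa <- normalize_aa(aa)
  if (!aa %in% sc_amino_acids()) {
    stop(
      "amino acid ", AA_THREE[[aa]],
      " is outside the 18 synonymous-coded amino acids",
      call. = FALSE
    )
  }
  tab <- codon_metadata()
  mine <- tab$sc & tab$aa == aa
  num <- sum(counts$counts[mine & tab$third %in% c("C", "G")])
  den <- sum(counts$counts[mine & tab$third %in% c("A", "T")])
  if (den == 0L) {
    return(NA_real_)
  }
  num / den
}

#' A/T- and C/G-ending counts for one amino acid
#'
#' The raw counts behind [per_aa_scub_frequency()], used for chi-square
#' cross tables.
#'
#' @inheritParams per_aa_scub_frequency
#' @return Named numeric vector `c(n_AT =, n_CG =)`.
#' @export
per_aa_ending_counts <- function(counts, aa) {
  stopifnot(inherits(counts, "codon_counts"))
  aa <- normalize_aa(aa)
  if (!aa %in% sc_amino_acids()) {
    stop("amino acid outside the synonymous set", call. = FALSE)
  }
  tab <- codon_metadata()
  mine <- tab$sc & tab$aa == aa
  c(
    n_AT = sum(counts$counts[mine & tab$third %in% c("A", "T")]),
    n_CG = sum(counts$counts[mine & tab$third %in% c("C", "G")])
  )
}

#' Total third-position ending frequencies
#'
#' Frequencies of synonymous codons ending in A, T, C and G, computed over
#' the 59-codon synonymous set only.
#'
#' @param counts A `codon_counts` object with `n_sc > 0`.
#' @return An `ending_frequencies` object: list with integer vector `n`
#'   (names A, T, C, G), frequency vector `f`, and `n_sc`.
#' @export
total_ending_frequencies <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_sc == 0L) {
    stop("empty synonymous-codon pool (n_sc = 0)", call. = FALSE)
  }
  tab <- codon_metadata()
  n <- vapply(
    c("A", "T", "C", "G"),
    function(b) sum(counts$counts[tab$sc & tab$third == b]),
    numeric(1)
  )
  structure(
    list(n = n, f = n / counts$n_sc, n_sc = counts$n_sc),
    class = "ending_frequencies"
  )
}

#' @export
print.ending_frequencies <- function(x, ...) {
  cat("<ending_frequencies> n_sc =", x$n_sc, "\n")
  print(round(x$f, 4))
  invisible(x)
}

#' NNC+NNG over NNA+NNT ratio
#'
#' The headline GC3-style summary: count of C/G-ending synonymous codons
#' divided by the count of A/T-ending ones.
#'
#' @param x A `codon_counts` or `ending_frequencies` object.
#' @return The ratio, or `NA_real_` when the A/T-ending count is 0.
#' @export
cg_to_at_ratio <- function(x) {
  if (inherits(x, "codon_counts")) {
    if (x$n_sc == 0L) {
      return(NA_real_)
    }
    x <- total_ending_frequencies(x)
  }
  stopifnot(inherits(x, "ending_frequencies"))
  den <- x$n[["A"]] + x$n[["T"]]
  if (den == 0) {
    return(NA_real_)
  }
  (x$n[["C"]] + x$n[["G"]]) / den
}
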