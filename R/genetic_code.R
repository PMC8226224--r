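# Standard genetic code, cached as a codon metadata table. The synonymous
# codon (SC) universe excludes the three stop codons (TAA, TAG, TGA) and the
# two non-degenerate codons ATG (Met) and TGG (Trp), leaving 59 codons that
# encode 18 amino acids.

.scub_cache <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")

# one-letter -> three-letter amino acid symbols (plus stop)
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stp"
)

#' Codon metadata table
#'
#' One row per codon of the standard genetic code, with the amino acid it
#' encodes (one-letter symbol, `*` for stop), its three base positions, and
#' whether it belongs to the 59-codon synonymous set.
#'
#' @return A `data.frame` with columns `codon`, `aa`, `first`, `second`,
#'   `third` and logical `sc`, in fixed codon order (A < C < G < T by
#'   position, first position slowest).
#' @export
codon_metadata <- function() {
  tab <- .scub_cache$codon_tab
  if (!is.null(tab)) {
    return(tab)
  }
  codons <- as.vector(t(outer(
    as.vector(t(outer(DNA_BASES, DNA_BASES, paste0))),
    DNA_BASES, paste0
  )))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  tab <- data.frame(
    codon = codons,
    aa = aa,
    first = substr(codons, 1L, 1L),
    second = substr(codons, 2L, 2L),
    third = substr(codons, 3L, 3L),
    sc = !(codons %in% c("TAA", "TAG", "TGA", "ATG", "TGG")),
    stringsAsFactors = FALSE
  )
  .scub_cache$codon_tab <- tab
  tab
}

#' The 64 codons in canonical order
#' @return Character vector of length 64.
#' @export
all_codons <- function() codon_metadata()$codon

#' The 59-codon synonymous set
#' @return Character vector of length 59.
#' @export
sc_codons <- function() {
  tab <- codon_metadata()
  tab$codon[tab$sc]
}

#' Amino acids covered by the synonymous set
#' @return The 18 one-letter amino-acid symbols (all but Met and Trp),
#'   sorted.
#' @export
sc_amino_acids <- function() {
  tab <- codon_metadata()
  sort(unique(tab$aa[tab$sc]))
}

#' Stop codons of the standard code
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

# Normalise an amino-acid symbol: accepts one-letter ("A") or three-letter
# ("Ala", case-insensitive) forms; returns the one-letter symbol.
normalize_aa <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L)
  if (nchar(aa) == 1L) {
    out <- toupper(aa)
    if (aa == "*") out <- "*"
  } else {
    hit <- match(
      tolower(aa),
      tolower(AA_THREE)
    )
    if (is.na(hit)) {
      stop("unknown amino-acid symbol: ", aa, call. = FALSE)
    }
    out <- names(AA_THREE)[hit]
  }
  if (!out %in% names(AA_THREE)) {
    stop("unknown amino-acid symbol: ", aa, call. = FALSE)
  }
  out
}
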