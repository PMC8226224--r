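# CpG-deamination (DNA methylation) signature ratios. Methylated cytosine
# in CpG context deaminates to thymine, producing C->T on the sense strand
# and G->A on the antisense strand (seen as G->A at the G of a sense CpG).
# At synonymous third positions this leaves two fingerprints:
#   * within a codon, NCG -> NCA (second-third dinucleotide CG), probed by
#     the NXA/NXG ratios;
#   * across a codon boundary, ...C|G... -> ...T|G..., probed by the
#     NT|X / NC|X ratios.

#' Second-base by third-base (A/G) counts
#'
#' For every synonymous codon ending in A or G, its count is attributed to
#' the cell (second base, third base). C/T-ending codons are ignored.
#'
#' @param counts A `codon_counts` object.
#' @return 4x2 integer matrix, rows A/C/G/T (second base), columns A/G
#'   (third base).
#' @export
second_third_counts <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  tab <- codon_metadata()
  keep <- tab$sc & tab$third %in% c("A", "G")
  m <- matrix(0, 4L, 2L, dimnames = list(DNA_BASES, c("A", "G")))
  sub <- tab[keep, ]
  cnt <- counts$counts[keep]
  for (i in seq_len(nrow(sub))) {
    m[sub$second[i], sub$third[i]] <- m[sub$second[i], sub$third[i]] + cnt[i]
  }
  m
}

#' NXA/NXG ratio for one second base
#'
#' @param d Matrix from [second_third_counts()].
#' @param X Second-position base, one of A, C, G, T.
#' @return `d[X, "A"] / d[X, "G"]`, or `NA_real_` when the NXG count is 0.
#' @export
nxa_nxg_ratio <- function(d, X) {
  X <- match.arg(toupper(X), DNA_BASES)
  if (d[X, "G"] == 0) {
    return(NA_real_)
  }
  d[X, "A"] / d[X, "G"]
}

#' Codon-boundary (third base, next first base) pair counts
#'
#' Over adjacent codon pairs within one CDS (or a list of CDSs), counts
#' pairs whose focal codon is a synonymous codon ending in C or T, by the
#' first base of the immediately following codon. The successor may be any
#' codon (only its first base matters); the last codon of a CDS
#' contributes no pair, and pairs never span records.
#'
#' @param codons Character vector of one CDS's in-order codons, or a list
#'   of such vectors (pooled).
#' @return 2x4 integer matrix, rows C/T (focal third base), columns
#'   A/C/G/T (successor first base).
#' @export
boundary_pair_counts <- function(codons) {
  if (!is.list(codons)) codons <- list(codons)
  m <- matrix(0L, 2L, 4L, dimnames = list(c("C", "T"), DNA_BASES))
  sc <- sc_codons()
  for (x in codons) {
    if (length(x) < 2L) next
    x <- toupper(x)
    focal <- x[-length(x)]
    nxt <- x[-1L]
    keep <- focal %in% sc & substr(focal, 3L, 3L) %in% c("C", "T") &
      substr(nxt, 1L, 1L) %in% DNA_BASES
    if (!any(keep)) next
    t3 <- factor(substr(focal[keep], 3L, 3L), levels = c("C", "T"))
    f1 <- factor(substr(nxt[keep], 1L, 1L), levels = DNA_BASES)
    m <- m + unclass(table(t3, f1))
  }
  dimnames(m) <- list(c("C", "T"), DNA_BASES)
  m
}

#' NT|X / NC|X ratio for one successor first base
#'
#' Probes third-position C->T conversion conditioned on the first base of
#' the next codon; when `X = "G"` the focal third base sits in a CpG
#' dinucleotide spanning the codon boundary.
#'
#' @param b Matrix from [boundary_pair_counts()].
#' @param X Successor first base, one of A, C, G, T.
#' @return `b["T", X] / b["C", X]`, or `NA_real_` when the NC|X count is 0.
#' @export
ntx_ncx_ratio <- function(b, X) {
  X <- match.arg(toupper(X), DNA_BASES)
  if (b["C", X] == 0) {
    return(NA_real_)
  }
  b["T", X] / b["C", X]
}

# XYA/XYG codon pairs sharing first and second bases, per amino acid.
# Leu, Arg and Ser have two codon families; the four-codon family with
# both endings (CTn, CGn, TCn) is the default, the two-codon AGA/AGG and
# TTA/TTG families are available as "alt".
AG_PAIR_FAMILIES <- list(
  A = list(default = c(A = "GCA", G = "GCG")), # Ala
  R = list(default = c(A = "CGA", G = "CGG"), alt = c(A = "AGA", G = "AGG")),
  Q = list(default = c(A = "CAA", G = "CAG")), # Gln
  E = list(default = c(A = "GAA", G = "GAG")), # Glu
  G = list(default = c(A = "GGA", G = "GGG")), # Gly
  L = list(default = c(A = "CTA", G = "CTG"), alt = c(A = "TTA", G = "TTG")),
  K = list(default = c(A = "AAA", G = "AAG")), # Lys
  P = list(default = c(A = "CCA", G = "CCG")), # Pro
  S = list(default = c(A = "TCA", G = "TCG")), # Ser
  T = list(default = c(A = "ACA", G = "ACG")), # Thr
  V = list(default = c(A = "GTA", G = "GTG")) # Val
)

#' Amino acids with an A/G-ending codon pair
#' @return One-letter symbols of the 11 amino acids encoded by XYA/XYG
#'   codon pairs (Ala, Arg, Gln, Glu, Gly, Leu, Lys, Pro, Ser, Thr, Val).
#' @export
ag_pair_amino_acids <- function() names(AG_PAIR_FAMILIES)

#' Per-amino-acid A-ending / G-ending pair ratio
#'
#' Ratio of the A-ending to the G-ending codon count within one XYA/XYG
#' codon family (shared first and second bases), the family-resolved
#' analogue of [nxa_nxg_ratio()].
#'
#' @param counts A `codon_counts` object.
#' @param aa One of the 11 amino acids in [ag_pair_amino_acids()]
#'   (one- or three-letter symbol).
#' @param family `"default"` (four-codon family for Leu/Arg/Ser) or
#'   `"alt"` (AGA/AGG for Arg, TTA/TTG for Leu).
#' @return The ratio, or `NA_real_` when the G-ending count is 0.
#' @export
per_aa_ag_pair_ratio <- function(counts, aa, family = c("default", "alt")) {
  stopifnot(inherits(counts, "codon_counts"))
  family <- match.arg(family)
  aa <- normalize_aa(aa)
  fams <- AG_PAIR_FAMILIES[[aa]]
  if (is.null(fams)) {
    stop(
      "amino acid ", AA_THREE[[aa]],
      " has no A/G-ending synonymous codon pair",
      call. = FALSE
    )
  }
  fam <- fams[[family]]
  if (is.null(fam)) {
    stop(
      "amino acid ", AA_THREE[[aa]], " has no '", family,
      "' codon family",
      call. = FALSE
    )
  }
  den <- counts$counts[[fam[["G"]]]]
  if (den == 0) {
    return(NA_real_)
  }
  counts$counts[[fam[["A"]]]] / den
}

#' Per-amino-acid A/G pair counts
#'
#' Raw counts behind [per_aa_ag_pair_ratio()], for chi-square tables.
#'
#' @inheritParams per_aa_ag_pair_ratio
#' @return Named numeric vector `c(n_A =, n_G =)`.
#' @export
per_aa_ag_pair_counts <- function(counts, aa, family = c("default", "alt")) {
  family <- match.arg(family)
  aa <- normalize_aa(aa)
  fam <- AG_PAIR_FAMILIES[[aa]][[family]]
  if (is.null(fam)) stop("no such codon family", call. = FALSE)
  c(
    n_A = unname(counts$counts[[fam[["A"]]]]),
    n_G = unname(counts$counts[[fam[["G"]]]])
  )
}

#' Hybrid-over-recipient ratio of ratios
#'
#' Used to express a methylation-signature ratio of the derived sample
#' relative to the recipient; values above 1 indicate the shift expected
#' under elevated CpG deamination.
#'
#' @param r_hybrid,r_recipient The two ratios.
#' @return `r_hybrid / r_recipient`; `NA_real_` when either input is
#'   undefined (`NA`) or the recipient ratio is 0.
#' @export
cross_sample_ratio <- function(r_hybrid, r_recipient) {
  if (is.na(r_hybrid) || is.na(r_recipient) || r_recipient == 0) {
    return(NA_real_)
  }
  r_hybrid / r_recipient
}

#' The eight methylation-signature comparisons
#'
#' Computes, for a recipient and a hybrid codon pool, the four NXA/NXG
#' ratios (X = A, C, G, T) and the four NT|X/NC|X ratios, their
#' cross-sample (hybrid / recipient) ratios, and the 2x2 chi-square
#' cross-table test on the underlying counts. CpG deamination is expected
#' to move only NCA/NCG and NT|G/NC|G.
#'
#' @param counts_recipient,counts_hybrid `codon_counts` per sample.
#' @param pairs_recipient,pairs_hybrid Matrices from
#'   [boundary_pair_counts()] per sample.
#' @return A `data.frame`, one row per ratio, with the per-sample counts,
#'   ratios, cross-sample ratio, chi-square statistic and p-value.
#' @export
methylation_ratio_table <- function(counts_recipient, counts_hybrid,
                                    pairs_recipient, pairs_hybrid) {
  d_r <- second_third_counts(counts_recipient)
  d_h <- second_third_counts(counts_hybrid)
  rows <- list()
  for (X in DNA_BASES) {
    rows[[length(rows) + 1L]] <- methylation_row(
      name = paste0("N", X, "A/N", X, "G"),
      num_r = d_r[X, "A"], den_r = d_r[X, "G"],
      num_h = d_h[X, "A"], den_h = d_h[X, "G"]
    )
  }
  for (X in DNA_BASES) {
    rows[[length(rows) + 1L]] <- methylation_row(
      name = paste0("NT|", X, "/NC|", X),
      num_r = pairs_recipient["T", X], den_r = pairs_recipient["C", X],
      num_h = pairs_hybrid["T", X], den_h = pairs_hybrid["C", X]
    )
  }
  do.call(rbind, rows)
}

methylation_row <- function(name, num_r, den_r, num_h, den_h) {
  ratio_r <- if (den_r == 0) NA_real_ else num_r / den_r
  ratio_h <- if (den_h == 0) NA_real_ else num_h / den_h
  tab <- rbind(recipient = c(num_r, den_r), hybrid = c(num_h, den_h))
  chi <- tryCatch(chi_square_cross_table(tab), error = function(e) NULL)
  data.frame(
    ratio = name,
    num_recipient = num_r, den_recipient = den_r,
    num_hybrid = num_h, den_hybrid = den_h,
    ratio_recipient = ratio_r, ratio_hybrid = ratio_h,
    cross_sample = cross_sample_ratio(ratio_h, ratio_r),
    chisq = if (is.null(chi)) NA_real_ else chi$statistic,
    p_value = if (is.null(chi)) NA_real_ else chi$p_value,
    stringsAsFactors = FALSE
  )
}
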