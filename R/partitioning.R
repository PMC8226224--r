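# Chromosome-based partitioning for an allohexaploid (wheat-like) genome:
# 21 chromosomes named 1A..7D, allelic (homoeologous) groups 1-7,
# sub-genomes A/B/D, and a configurable set of chromosomes carrying
# introgressed exogenous fragments.

#' Default introgressed chromosome set
#'
#' The six chromosomes carrying introgressed fragments in the somatic
#' hybrid line this package models (arm-level detection collapsed to
#' whole chromosomes).
#'
#' @return `c("1B", "1D", "2A", "2D", "5B", "6D")`.
#' @export
default_introgressed_chromosomes <- function() {
  c("1B", "1D", "2A", "2D", "5B", "6D")
}

#' The 21 wheat chromosome names
#' @return Character vector "1A".."7D".
#' @export
wheat_chromosomes <- function() {
  as.vector(outer(1:7, c("A", "B", "D"), paste0))
}

# Parse one chromosome label: "unmapped", or ^[1-7][ABD]([LS])?$ with the
# arm suffix stripped. Returns NA_character_ for malformed input.
parse_chromosome <- function(x) {
  x <- toupper(trimws(x))
  if (tolower(x) == "unmapped") {
    return("unmapped")
  }
  if (grepl("^[1-7][ABD][LS]?$", x)) {
    return(substr(x, 1L, 2L))
  }
  NA_character_
}

#' Load a record-to-chromosome assignment table
#'
#' Reads a TSV (or takes a data.frame) with columns `record_id` and
#' `chromosome` and derives allelic group (the leading digit), sub-genome
#' (the letter) and the introgression flag. Arm suffixes L/S are
#' stripped; introgression is tracked at whole-chromosome resolution.
#'
#' @param table Path to a TSV file, or a data.frame with columns
#'   `record_id`, `chromosome`.
#' @param introgressed Character vector of introgressed chromosome names
#'   (default [default_introgressed_chromosomes()]).
#' @return `data.frame` with columns `record_id`, `chromosome`,
#'   `allelic_group` (integer or `NA`), `subgenome` (or `NA`), and
#'   logical `introgressed`.
#' @export
load_chromosome_map <- function(table,
                                introgressed =
                                  default_introgressed_chromosomes()) {
  if (is.character(table) && length(table) == 1L) {
    table <- read.delim(table, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  if (!all(c("record_id", "chromosome") %in% names(table))) {
    stop("chromosome map needs columns 'record_id' and 'chromosome'",
      call. = FALSE
    )
  }
  introgressed <- vapply(introgressed, parse_chromosome, character(1))
  if (anyNA(introgressed)) {
    stop("invalid chromosome name in the introgressed set", call. = FALSE)
  }
  if (anyDuplicated(table$record_id)) {
    stop(
      "duplicate record_id in chromosome map: ",
      paste(unique(table$record_id[duplicated(table$record_id)]),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  chrom <- vapply(table$chromosome, parse_chromosome, character(1),
    USE.NAMES = FALSE
  )
  if (anyNA(chrom)) {
    bad <- which(is.na(chrom))[1L]
    stop(
      "malformed chromosome name '", table$chromosome[bad],
      "' at row ", bad,
      call. = FALSE
    )
  }
  mapped <- chrom != "unmapped"
  allelic_group <- rep(NA_integer_, length(chrom))
  allelic_group[mapped] <- as.integer(substr(chrom[mapped], 1L, 1L))
  subgenome <- rep(NA_character_, length(chrom))
  subgenome[mapped] <- substr(chrom[mapped], 2L, 2L)
  data.frame(
    record_id = table$record_id,
    chromosome = chrom,
    allelic_group = allelic_group,
    subgenome = subgenome,
    introgressed = mapped & chrom %in% introgressed,
    stringsAsFactors = FALSE
  )
}

#' Pool codon counts by a partition scheme
#'
#' @param counts_by_record Named list (by record id) of `codon_counts`,
#'   e.g. from [cds_codon_counts()].
#' @param assignments `data.frame` from [load_chromosome_map()]. Records
#'   absent from the table are treated as unmapped.
#' @param scheme One of `"all"`, `"mapped"` (labels mapped/unmapped),
#'   `"introgression"` (labels introgressed/non_introgressed over mapped
#'   records), `"allelic_group"` (labels "1".."7") or `"subgenome"`
#'   (labels A/B/D).
#' @return Named list of pooled `codon_counts`, one per partition label.
#'   Labels with no records yield an empty `codon_counts`.
#' @export
partition_counts <- function(counts_by_record, assignments,
                             scheme = c(
                               "all", "mapped", "introgression",
                               "allelic_group", "subgenome"
                             )) {
  scheme <- match.arg(scheme)
  stopifnot(is.list(counts_by_record))
  ids <- names(counts_by_record)
  if (is.null(ids)) {
    stop("counts_by_record must be named by record id", call. = FALSE)
  }
  idx <- match(ids, assignments$record_id)
  chrom <- ifelse(is.na(idx), "unmapped", assignments$chromosome[idx])
  labels <- switch(scheme,
    all = rep("all", length(ids)),
    mapped = ifelse(chrom == "unmapped", "unmapped", "mapped"),
    introgression = ifelse(chrom == "unmapped", NA_character_,
      ifelse(assignments$introgressed[idx], "introgressed",
        "non_introgressed"
      )
    ),
    allelic_group = ifelse(chrom == "unmapped", NA_character_,
      substr(chrom, 1L, 1L)
    ),
    subgenome = ifelse(chrom == "unmapped", NA_character_,
      substr(chrom, 2L, 2L)
    )
  )
  universe <- switch(scheme,
    all = "all",
    mapped = c("mapped", "unmapped"),
    introgression = c("introgressed", "non_introgressed"),
    allelic_group = as.character(1:7),
    subgenome = c("A", "B", "D")
  )
  out <- lapply(universe, function(lab) {
    pool_codon_counts(counts_by_record[which(labels == lab)])
  })
  setNames(out, universe)
}
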