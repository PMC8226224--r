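# FASTA input for CDS collections. Sequences are carried as plain character
# columns in a data.frame ("cds set"): id, sequence, sample, frame_offset.

#' Read a CDS FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet()`. Record ids (first whitespace
#' token of the header) must be unique within a file. Sequences are
#' uppercased; alphabet is not restricted here — codons with ambiguity
#' codes are dropped at counting time.
#'
#' @param path FASTA file.
#' @param sample Sample label attached to every record (e.g. "recipient",
#'   "hybrid").
#' @param frame_offset 0-based offset of the first in-frame base, applied
#'   to all records (default 0; no ORF-finding is performed).
#' @return A `data.frame` with columns `id`, `sequence`, `sample`,
#'   `frame_offset`.
#' @export
read_cds_fasta <- function(path, sample, frame_offset = 0L) {
  stopifnot(file.exists(path), is.character(sample), length(sample) == 1L)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate record ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  data.frame(
    id = ids,
    sequence = toupper(as.character(set)),
    sample = sample,
    frame_offset = as.integer(frame_offset),
    stringsAsFactors = FALSE
  )
}

#' Write a CDS set to FASTA
#'
#' @param cds A cds-set `data.frame` (`id`, `sequence` columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  set <- Biostrings::DNAStringSet(setNames(cds$sequence, cds$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Codon counts per record of a CDS set
#'
#' @param cds A cds-set `data.frame`.
#' @return Named list (by record id) of `codon_counts`.
#' @export
cds_codon_counts <- function(cds) {
  out <- lapply(seq_len(nrow(cds)), function(i) {
    count_synonymous_codons(
      extract_codons(cds$sequence[i], cds$frame_offset[i])
    )
  })
  names(out) <- cds$id
  out
}

#' Codon lists per record of a CDS set
#'
#' @param cds A cds-set `data.frame`.
#' @return Named list (by record id) of codon character vectors.
#' @export
cds_codon_lists <- function(cds) {
  out <- lapply(seq_len(nrow(cds)), function(i) {
    extract_codons(cds$sequence[i], cds$frame_offset[i])
  })
  names(out) <- cds$id
  out
}
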