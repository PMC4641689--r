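#' Read assembly contigs from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-FASTA of contigs. The identifier is
#' the header up to the first whitespace; the remaining description is
#' dropped. Sequences are uppercased and `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` and `length`.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) abort("duplicate contig ids in FASTA input")
  seqs <- clean_seq(as.character(x))
  bad <- !grepl("^[ACGTN]*$", seqs)
  if (any(bad)) {
    abort(sprintf(
      "contig(s) with characters outside {A,C,G,T,N,U}: %s",
      paste(ids[bad], collapse = ", ")
    ))
  }
  tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq`; an optional `desc`
#'   column is appended to each header after a space (used e.g. for
#'   `circular=true overlap=<k>` tags).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  headers <- as.character(seqs$id)
  if ("desc" %in% names(seqs)) {
    has_desc <- !is.na(seqs$desc) & nzchar(seqs$desc)
    headers[has_desc] <- paste(headers[has_desc], seqs$desc[has_desc])
  }
  x <- Biostrings::BStringSet(as.character(seqs$seq))
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA (multiple sequence alignment)
#'
#' Rows must all have the same gapped length; gaps are `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `seq` (gapped).
#' @export
read_msa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  if (length(unique(nchar(seqs))) > 1L) {
    abort("alignment rows have unequal lengths")
  }
  tibble(id = ids, seq = unname(seqs))
}
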