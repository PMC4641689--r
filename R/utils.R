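# Internal sequence helpers. Coordinates are 0-based, half-open throughout
# the package; 1-based inclusive coordinates appear only in GFF3 output.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
NON_STOP_CODONS <- setdiff(
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0)),
  STOP_CODONS
)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' Vectorised over `seq`; `N` maps to `N`.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GACGAATCTCG")
#' @export
revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

# complement of single characters, vectorised
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# uppercase and map U -> T; applied to every sequence on entry
clean_seq <- function(seq) chartr("U", "T", toupper(seq))

assert_scalar_dna <- function(seq, what = "seq", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("`%s` must be a single non-empty DNA string", what))
  }
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, seq)) {
    abort(sprintf(
      "`%s` contains characters outside {A,C,G,T%s}", what,
      if (allow_n) ",N" else ""
    ))
  }
  invisible(seq)
}

# rotate so that 0-based position `k` becomes the new origin
rotate_seq <- function(seq, k) {
  n <- nchar(seq)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, n), substr(seq, 1L, k))
}

# substring of a circular sequence: 0-based start, wraps past the end
circ_substr <- function(seq, start0, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  start0 <- ((start0 %% n) + n) %% n
  if (start0 + len <= n) {
    substr(seq, start0 + 1L, start0 + len)
  } else {
    paste0(
      substr(seq, start0 + 1L, n),
      substr(seq, 1L, start0 + len - n)
    )
  }
}

# fraction of N characters
n_fraction <- function(seq) {
  stringr::str_count(seq, stringr::fixed("N")) / nchar(seq)
}

# coerce tibble(id, seq) or named character vector to a named character vector
as_named_seqs <- function(x, arg = "seqs") {
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      abort(sprintf("`%s` data frame needs columns `id` and `seq`", arg))
    }
    out <- as.character(x$seq)
    names(out) <- as.character(x$id)
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    abort(sprintf("`%s` must be a data frame with id/seq or a character vector", arg))
  }
  if (anyDuplicated(names(out))) abort(sprintf("duplicate ids in `%s`", arg))
  clean_seq(out)
}
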