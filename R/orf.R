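# Six-frame, circular-aware ORF calling. A circular genome is scanned as a
# tripled linearization: every ORF of length <= L appears as a contiguous
# in-frame run there, and restricting reported starts to the middle copy
# guarantees full upstream context and a single report per circular ORF.

#' Find open reading frames on a (circular) genome
#'
#' Calls maximal ORFs on both strands: a start codon (`ATG`) through the
#' first in-frame stop (`TAA`/`TAG`/`TGA`), with the stop included in the
#' length. Nested starts are suppressed — per (stop, strand) only the
#' longest ORF (the first `ATG` after the previous in-frame stop) is
#' reported, matching common ORF-finder behaviour. When `circular = TRUE`
#' ORFs may wrap the breakpoint (reported once, `start` reduced modulo the
#' genome length, `end` possibly exceeding it) and no ORF may be longer
#' than one full turn.
#'
#' Coordinates are 0-based on the reading strand: for `strand == "-"` the
#' positions refer to the reverse-complemented linearization of the genome
#' (use [orfs_to_gff3()] for plus-strand interval output).
#'
#' In `mode = "stop_stop"` the start-codon requirement is dropped and whole
#' stop-to-stop frames are reported; this recovers start-less ORFs such as
#' papillomavirus E4.
#'
#' @param seq A single genome sequence.
#' @param min_len Minimum ORF length in nt, stop codon included; must be
#'   divisible by 3. Default 300, the conventional cutoff for small
#'   circular virus genome annotation.
#' @param circular Whether the genome is circular.
#' @param mode `"start_stop"` (default) or `"stop_stop"`.
#' @param genome_id Optional id prepended as a `genome_id` column.
#' @return A tibble with columns `start`, `end`, `strand`, `frame`,
#'   `length_nt`, `crosses_breakpoint`, `protein`, sorted by `start`.
#' @export
find_orfs <- function(seq, min_len = 300L, circular = TRUE,
                      mode = c("start_stop", "stop_stop"), genome_id = NULL) {
  mode <- match.arg(mode)
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  L <- nchar(seq)
  if (L < 3L) abort("genome shorter than one codon")
  if (min_len < 6L || min_len %% 3L != 0L) {
    abort("`min_len` must be >= 6 and divisible by 3")
  }
  gc_tab <- Biostrings::GENETIC_CODE
  max_codons <- L %/% 3L

  res <- list()
  for (strand in c("+", "-")) {
    s_lin <- if (strand == "+") seq else revcomp(seq)
    scan <- if (circular) strrep(s_lin, 3L) else s_lin
    nS <- nchar(scan)
    for (f in 0:2) {
      if (nS - f < 6L) next
      cs <- seq.int(f + 1L, nS - 2L, by = 3L) # 1-based codon starts
      cod <- substring(scan, cs, cs + 2L)
      stop_i <- which(cod %in% STOP_CODONS)
      if (!length(stop_i)) next
      prev_stop <- c(0L, stop_i[-length(stop_i)])
      lower <- pmax(prev_stop, stop_i - max_codons) # start index must exceed this
      if (mode == "start_stop") {
        atg_i <- which(cod == "ATG")
        if (!length(atg_i)) next
        k <- findInterval(lower, atg_i) + 1L
        a <- ifelse(k <= length(atg_i), atg_i[pmin(k, length(atg_i))], NA_integer_)
        a[!is.na(a) & a >= stop_i] <- NA_integer_
      } else {
        a <- lower + 1L
        a[a >= stop_i] <- NA_integer_
      }
      ok <- which(!is.na(a))
      if (!length(ok)) next
      a <- a[ok]
      t <- stop_i[ok]
      start0 <- f + (a - 1L) * 3L # 0-based nt start on scan
      len_nt <- (t - a + 1L) * 3L
      if (circular) {
        keep <- start0 >= L & start0 < 2L * L & len_nt >= min_len
      } else {
        keep <- len_nt >= min_len
      }
      if (!any(keep)) next
      a <- a[keep]; t <- t[keep]
      start0 <- start0[keep]; len_nt <- len_nt[keep]
      start_mod <- if (circular) start0 - L else start0
      protein <- vapply(seq_along(a), function(i) {
        aa <- unname(gc_tab[cod[a[i]:(t[i] - 1L)]])
        aa[is.na(aa)] <- "X"
        paste(aa, collapse = "")
      }, character(1))
      res[[length(res) + 1L]] <- tibble(
        start = start_mod,
        end = start_mod + len_nt,
        strand = strand,
        frame = start_mod %% 3L,
        length_nt = len_nt,
        crosses_breakpoint = circular & (start_mod + len_nt > L),
        protein = protein
      )
    }
  }
  out <- if (length(res)) bind_rows(res) else tibble(
    start = integer(), end = integer(), strand = character(),
    frame = integer(), length_nt = integer(),
    crosses_breakpoint = logical(), protein = character()
  )
  out <- distinct(out, .data$start, .data$strand, .keep_all = TRUE)
  out <- arrange(out, .data$start, .data$strand)
  if (!is.null(genome_id)) {
    out <- bind_cols(tibble(genome_id = rep(genome_id, nrow(out))), out)
  }
  out
}

#' Translate DNA to protein
#'
#' Standard genetic code; any codon containing a character other than
#' `A/C/G/T` (e.g. `N`) translates to `X`. A trailing stop is trimmed from
#' the returned string (internal stops, if present, appear as `*`); a
#' trailing partial codon is dropped.
#'
#' @param seq Character vector of DNA sequences.
#' @param frame_offset Reading-frame offset, 0, 1 or 2.
#' @return Character vector of amino-acid strings.
#' @examples
#' translate_dna("ATGNNNGCC") # "MXA"
#' @export
translate_dna <- function(seq, frame_offset = 0L) {
  if (!frame_offset %in% 0:2) abort("`frame_offset` must be 0, 1 or 2")
  gc_tab <- Biostrings::GENETIC_CODE
  vapply(seq, function(x) {
    x <- clean_seq(x)
    assert_scalar_dna(x)
    ncod <- (nchar(x) - frame_offset) %/% 3L
    if (ncod < 1L) return("")
    cs <- frame_offset + 1L + 3L * (seq_len(ncod) - 1L)
    aa <- unname(gc_tab[substring(x, cs, cs + 2L)])
    aa[is.na(aa)] <- "X"
    sub("\\*$", "", paste(aa, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# plus-strand 0-based half-open interval(s) occupied by an ORF row
orf_plus_interval <- function(start, length_nt, strand, L) {
  if (strand == "+") {
    c(start, start + length_nt)
  } else {
    ps <- (L - start - length_nt) %% L
    c(ps, ps + length_nt)
  }
}

#' Write ORF calls as GFF3
#'
#' Emits 1-based inclusive plus-strand coordinates per the GFF3
#' specification, with `Is_circular=true` on the region directive's
#' landmark when the genome is circular. An ORF that wraps the breakpoint
#' is split into two `CDS` lines sharing one `ID`.
#'
#' @param orfs A tibble from [find_orfs()].
#' @param genome_id Landmark (sequence) identifier.
#' @param genome_length Genome length in nt.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @param circular Whether the genome is circular.
#' @return Character vector of GFF3 lines (invisibly when written to file).
#' @export
orfs_to_gff3 <- function(orfs, genome_id, genome_length, path = NULL,
                         circular = TRUE) {
  L <- as.integer(genome_length)
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", genome_id, L),
    sprintf(
      "%s\tcircvirome\tregion\t1\t%d\t.\t+\t.\tID=%s%s",
      genome_id, L, genome_id, if (circular) ";Is_circular=true" else ""
    )
  )
  if (nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      iv <- orf_plus_interval(
        orfs$start[i], orfs$length_nt[i], orfs$strand[i], L
      )
      id <- sprintf("%s_orf%03d", genome_id, i)
      ps <- iv[1] %% L
      pe <- ps + orfs$length_nt[i]
      parts <- if (pe <= L) {
        list(c(ps + 1L, pe))
      } else {
        list(c(ps + 1L, L), c(1L, pe - L))
      }
      # phase 0 on the part holding the start codon (first part for "+",
      # last for "-"); the other part's phase follows from the split length
      for (j in seq_along(parts)) {
        p <- parts[[j]]
        plen_before <- if (orfs$strand[i] == "+") {
          sum(vapply(parts[seq_len(j - 1L)], function(q) q[2] - q[1] + 1L, integer(1)))
        } else {
          sum(vapply(parts[-seq_len(j)], function(q) q[2] - q[1] + 1L, integer(1)))
        }
        phase <- (3L - plen_before %% 3L) %% 3L
        lines <- c(lines, sprintf(
          "%s\tcircvirome\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s%s",
          genome_id, p[1], p[2], orfs$strand[i], phase, id,
          if (isTRUE(orfs$crosses_breakpoint[i])) ";crosses_breakpoint=true" else ""
        ))
      }
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
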