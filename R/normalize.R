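# Circularization of assembler contigs: terminal-redundancy detection,
# trimming, low-complexity truncation, and the canonical representative.

#' Detect assembler terminal redundancy
#'
#' De novo assemblers linearize a circular template into a contig whose 3'
#' end repeats its 5' end exactly. This returns, per contig, the largest
#' overlap length `k` with `min_overlap <= k <= max_overlap_frac * length`
#' such that the first `k` bases equal the last `k` bases, or `NA` when no
#' such `k` exists (the contig is treated as linear).
#'
#' @param seq Character vector of contig sequences (`A,C,G,T,N`).
#' @param min_overlap Minimum overlap accepted as evidence of circularity.
#'   The default of 10 nt bounds the chance of a spurious end match at
#'   roughly `4^-10` per contig.
#' @param max_overlap_frac Largest overlap considered, as a fraction of
#'   contig length (must be <= 0.5 so the two copies cannot overlap).
#' @param unique_ends If `TRUE`, additionally require that the detected
#'   terminal k-mer occurs exactly twice in the contig (once per end);
#'   contigs failing this stricter uniqueness check get `NA`.
#' @return Integer vector of overlap lengths (`NA` where not circular).
#' @examples
#' detect_terminal_overlap("ACGTACGTTTACGTACGT", min_overlap = 4)
#' @export
detect_terminal_overlap <- function(seq, min_overlap = 10L,
                                    max_overlap_frac = 0.5,
                                    unique_ends = FALSE) {
  if (min_overlap < 1L) abort("`min_overlap` must be >= 1")
  if (max_overlap_frac <= 0 || max_overlap_frac > 0.5) {
    abort("`max_overlap_frac` must be in (0, 0.5]")
  }
  vapply(seq, function(x) {
    x <- clean_seq(x)
    assert_scalar_dna(x, "seq")
    n <- nchar(x)
    kmax <- floor(max_overlap_frac * n)
    if (kmax < min_overlap) return(NA_integer_)
    for (k in seq.int(kmax, min_overlap)) {
      if (substr(x, 1L, k) == substr(x, n - k + 1L, n)) {
        if (unique_ends) {
          hits <- stringi::stri_count_fixed(x, substr(x, 1L, k), overlap = TRUE)
          if (hits != 2L) return(NA_integer_)
        }
        return(as.integer(k))
      }
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Trim a terminally redundant contig to one full circle
#'
#' Removes the duplicated 5' copy of the overlap, leaving exactly one turn
#' of the circle (the convention is to drop the first `overlap_len` bases).
#'
#' @param seq A single contig sequence.
#' @param overlap_len Overlap length as returned by
#'   [detect_terminal_overlap()]; must be at least 1 and smaller than the
#'   contig length (an absent overlap means the contig is not circular and
#'   cannot be trimmed).
#' @return The trimmed sequence (length `nchar(seq) - overlap_len`).
#' @export
trim_to_circle <- function(seq, overlap_len) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  if (length(overlap_len) != 1L || is.na(overlap_len) || overlap_len < 1L) {
    abort("`overlap_len` must be a positive integer (absent overlap: not circular)")
  }
  if (overlap_len >= nchar(seq)) {
    abort("`overlap_len` must be smaller than the contig length")
  }
  substr(seq, as.integer(overlap_len) + 1L, nchar(seq))
}

#' Find low-complexity tandem repeats
#'
#' Reports all maximal perfect tandem repeats with repeat-unit length at
#' most `max_period` (1 = homopolymer, 2 = dinucleotide such as `GTGT...`)
#' spanning at least `min_run` bases. Overlapping candidates are resolved
#' greedily by span (longest kept), so the result is non-overlapping and
#' sorted by start.
#'
#' @param seq A single DNA sequence.
#' @param max_period Maximum repeat-unit length (1 or 2).
#' @param min_run Minimum span in nt (default 20, i.e. ten `GT` units).
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `period` and `unit`.
#' @export
find_low_complexity <- function(seq, max_period = 2L, min_run = 20L) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  if (!max_period %in% c(1L, 2L)) abort("`max_period` must be 1 or 2")
  if (min_run < 2L * max_period) abort("`min_run` must be >= 2 * max_period")
  ch <- chars(seq)
  n <- length(ch)
  empty <- tibble(
    start = integer(), end = integer(), period = integer(), unit = character()
  )
  cand <- list()
  for (p in seq_len(max_period)) {
    if (n < 2L * p) next
    eq <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & (r$lengths + p >= min_run))) {
      s0 <- starts[i] - 1L # 0-based
      span <- r$lengths[i] + p
      unit <- substr(seq, s0 + 1L, s0 + p)
      # a dinucleotide run of identical characters is really a homopolymer
      if (p == 2L && substr(unit, 1L, 1L) == substr(unit, 2L, 2L)) next
      cand[[length(cand) + 1L]] <- tibble(
        start = s0, end = s0 + span, period = p, unit = unit
      )
    }
  }
  if (!length(cand)) return(empty)
  tb <- arrange(bind_rows(cand), desc(.data$end - .data$start), .data$start, .data$period)
  kept <- empty
  for (i in seq_len(nrow(tb))) {
    row <- tb[i, ]
    if (!nrow(kept) || all(row$end <= kept$start | row$start >= kept$end)) {
      kept <- bind_rows(kept, row)
    }
  }
  arrange(kept, .data$start)
}

#' Excise low-complexity runs from a contig
#'
#' Removes each run's interval from the sequence. In the pipeline this is
#' applied *before* terminal-overlap detection, since an expanded
#' low-complexity tract can mask the true terminal redundancy.
#'
#' @param seq A single DNA sequence.
#' @param runs A tibble of runs as returned by [find_low_complexity()]
#'   (columns `start`, `end`; 0-based half-open, non-overlapping).
#' @return The sequence with the runs excised.
#' @export
truncate_low_complexity <- function(seq, runs) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  if (is.null(runs) || !nrow(runs)) return(seq)
  stopifnot(all(c("start", "end") %in% names(runs)))
  runs <- arrange(as_tibble(runs), .data$start)
  if (any(runs$start < 0L) || any(runs$end > nchar(seq)) ||
      any(runs$end <= runs$start)) {
    abort("run intervals out of bounds")
  }
  if (nrow(runs) > 1L && any(runs$start[-1L] < runs$end[-nrow(runs)])) {
    abort("run intervals overlap")
  }
  keep <- rep(TRUE, nchar(seq))
  for (i in seq_len(nrow(runs))) {
    keep[(runs$start[i] + 1L):runs$end[i]] <- FALSE
  }
  paste(chars(seq)[keep], collapse = "")
}

# index (1-based) of the lexicographically least rotation of an integer
# code vector; candidate-refinement, deterministic
least_rotation_start <- function(iv) {
  n <- length(iv)
  if (n == 1L) return(1L)
  ext <- c(iv, iv)
  cand <- which(iv == min(iv))
  d <- 0L
  while (length(cand) > 1L && d < n - 1L) {
    d <- d + 1L
    nx <- ext[cand + d]
    cand <- cand[nx == min(nx)]
  }
  cand[1L]
}

#' Canonical representative of a circular sequence
#'
#' Assembler output of a circular template is ambiguous up to rotation and
#' strand. This returns the lexicographically smallest string among all
#' rotations of the sequence and all rotations of its reverse complement,
#' giving every circle a unique, deterministic representative.
#'
#' @param seq Character vector of circular sequences.
#' @return Character vector of canonical representatives.
#' @examples
#' canonical_rotation("GCA") # "AGC"
#' @export
canonical_rotation <- function(seq) {
  vapply(seq, function(x) {
    x <- clean_seq(x)
    assert_scalar_dna(x)
    rc <- revcomp(x)
    r1 <- rotate_seq(x, least_rotation_start(utf8ToInt(x)) - 1L)
    r2 <- rotate_seq(rc, least_rotation_start(utf8ToInt(rc)) - 1L)
    if (identical(r1, min(r1, r2))) r1 else r2
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of DNA sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from both numerator and
#' denominator. An all-`N` sequence is an error.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  for (x in seq) assert_scalar_dna(clean_seq(x))
  s <- Biostrings::DNAStringSet(clean_seq(seq))
  f <- Biostrings::letterFrequency(s, letters = c("G", "C", "A", "T"))
  denom <- rowSums(f)
  if (any(denom == 0)) abort("GC content undefined for all-N sequence")
  unname((f[, "G"] + f[, "C"]) / denom)
}

#' Circularize a set of contigs
#'
#' The per-contig normalization pipeline: truncate low-complexity runs,
#' detect the terminal redundancy, trim to one full circle, and reduce to
#' the canonical rotation-and-strand representative. Contigs with more than
#' `max_n_frac` ambiguous bases are flagged (`high_n`) and not analysed;
#' contigs without a detectable terminal overlap are reported as not
#' circular.
#'
#' @param contigs A tibble with columns `id` and `seq` (e.g. from
#'   [read_contigs()]).
#' @inheritParams detect_terminal_overlap
#' @inheritParams find_low_complexity
#' @param canonicalize Reduce each circle to its canonical representative
#'   (recommended; required for cross-assembly comparisons).
#' @param max_n_frac Maximum tolerated fraction of `N` bases.
#' @return A tibble with one row per contig: `id`, `high_n`, `circular`,
#'   `overlap_len`, `seq` (the canonical circle, `NA` if not circular),
#'   `length`, `gc`, `truncated_bases` and a `truncated_intervals`
#'   list-column of excised low-complexity runs (coordinates on the
#'   original contig).
#' @export
circularize <- function(contigs, min_overlap = 10L, max_overlap_frac = 0.5,
                        unique_ends = FALSE, max_period = 2L, min_run = 20L,
                        canonicalize = TRUE, max_n_frac = 0.05) {
  stopifnot(is.data.frame(contigs), all(c("id", "seq") %in% names(contigs)))
  rows <- purrr::map(seq_len(nrow(contigs)), function(i) {
    id <- as.character(contigs$id[i])
    seq <- clean_seq(as.character(contigs$seq[i]))
    assert_scalar_dna(seq, paste0("contig ", id))
    base <- tibble(
      id = id, high_n = FALSE, circular = FALSE,
      overlap_len = NA_integer_, seq = NA_character_,
      length = NA_integer_, gc = NA_real_, truncated_bases = 0L,
      truncated_intervals = list(tibble(
        start = integer(), end = integer(), period = integer(),
        unit = character()
      ))
    )
    if (n_fraction(seq) > max_n_frac) {
      base$high_n <- TRUE
      return(base)
    }
    runs <- find_low_complexity(seq, max_period = max_period, min_run = min_run)
    seq2 <- truncate_low_complexity(seq, runs)
    base$truncated_bases <- sum(runs$end - runs$start)
    base$truncated_intervals <- list(runs)
    ov <- detect_terminal_overlap(
      seq2, min_overlap = min_overlap,
      max_overlap_frac = max_overlap_frac, unique_ends = unique_ends
    )
    if (is.na(ov)) return(base)
    circ <- trim_to_circle(seq2, ov)
    if (canonicalize) circ <- canonical_rotation(circ)
    base$circular <- TRUE
    base$overlap_len <- ov
    base$seq <- circ
    base$length <- nchar(circ)
    base$gc <- gc_content(circ)
    base
  })
  bind_rows(rows)
}
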