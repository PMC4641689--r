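# Rolling-circle replication origin scan: nonanucleotide motif matching and
# inverted-repeat (hairpin) detection around each match.

#' Find nonanucleotide motif sites on a genome
#'
#' Scans both strands for 9-mers within `max_mismatch` Hamming distance of
#' the canonical rolling-circle origin motif (`TAGTATTAC`; the default
#' tolerance of one mismatch also admits the `TAGTATTAA` variant). On a
#' circular genome the scan wraps the breakpoint and each site is reported
#' once. Minus-strand sites are reported with the 0-based start of the site
#' interval on the plus strand; `motif` is the matched 9-mer as read on the
#' hit strand.
#'
#' @param seq A single genome sequence.
#' @param canonical The canonical 9-nt motif.
#' @param max_mismatch Maximum Hamming distance (<= 3).
#' @param circular Treat the sequence as circular (wrap the breakpoint).
#' @return A tibble with columns `motif`, `offset`, `strand`, `mismatches`,
#'   sorted by `offset`.
#' @export
find_nonamer_sites <- function(seq, canonical = "TAGTATTAC", max_mismatch = 1L,
                               circular = TRUE) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  canonical <- clean_seq(canonical)
  k <- nchar(canonical)
  if (k != 9L) abort("`canonical` must be 9 nt")
  if (max_mismatch < 0L || max_mismatch > 3L) abort("`max_mismatch` must be in 0..3")
  L <- nchar(seq)
  if (L < k) abort("genome shorter than the motif")

  scan_strand <- function(s) {
    ext <- if (circular) paste0(s, substr(s, 1L, k - 1L)) else s
    npos <- if (circular) L else L - k + 1L
    ch <- chars(ext)
    can <- chars(canonical)
    p <- seq_len(npos) # 1-based starts
    mism <- integer(npos)
    for (j in seq_len(k)) {
      mism <- mism + (ch[p + j - 1L] != can[j])
    }
    hit <- which(mism <= max_mismatch)
    if (!length(hit)) {
      return(tibble(
        offset = integer(), motif = character(), mismatches = integer()
      ))
    }
    tibble(
      offset = hit - 1L,
      motif = substring(ext, hit, hit + k - 1L),
      mismatches = mism[hit]
    )
  }

  plus <- scan_strand(seq)
  plus$strand <- if (nrow(plus)) "+" else character(0)
  minus <- scan_strand(revcomp(seq))
  if (nrow(minus)) {
    # map the site interval back onto the plus strand
    minus$offset <- if (circular) {
      (L - minus$offset - k) %% L
    } else {
      L - minus$offset - k
    }
    minus$strand <- "-"
  } else {
    minus$strand <- character(0)
  }
  out <- bind_rows(plus, minus)
  out <- distinct(out, .data$offset, .data$strand, .keep_all = TRUE)
  arrange(
    select(out, "motif", "offset", "strand", "mismatches"),
    .data$offset, .data$strand
  )
}

#' Test whether a motif site sits in the loop of a hairpin
#'
#' Searches for a perfect inverted repeat (the stem: two arms that are exact
#' reverse complements of each other, no wobble pairs or bulges) whose
#' unpaired loop contains the whole nonamer. Among all hairpins with
#' `min_arm <= arm <= max_arm` and loop length at most `max_loop`, the one
#' with the longest arm wins; ties are broken by smaller loop, then by the
#' leftmost loop start. The search is bounded to `window` nt on either side
#' of the motif.
#'
#' @param seq A single genome sequence.
#' @param offset 0-based start of the motif site on the plus strand (as
#'   reported by [find_nonamer_sites()]; hairpins are strand-symmetric, so
#'   plus-strand coordinates serve both strands).
#' @param motif_len Length of the motif (9 for the nonanucleotide).
#' @param min_arm,max_arm Stem-arm length bounds in bp.
#' @param max_loop Maximum loop length in nt.
#' @param window Search radius around the motif in nt.
#' @param circular Wrap coordinates around the breakpoint.
#' @return A one-row tibble with `arm_len`, `loop_start`, `loop_end`,
#'   `loop_len`, `stem5_start`, `stem3_end` (positions mod genome length
#'   when circular), or a zero-row tibble when no qualifying hairpin exists.
#' @export
detect_hairpin <- function(seq, offset, motif_len = 9L, min_arm = 5L,
                           max_arm = 20L, max_loop = 15L, window = 40L,
                           circular = TRUE) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  if (min_arm < 1L || max_arm < min_arm || max_loop < motif_len || window < 1L) {
    abort("invalid hairpin search parameters")
  }
  L <- nchar(seq)
  offset <- as.integer(offset)

  empty <- tibble(
    arm_len = integer(), loop_start = integer(), loop_end = integer(),
    loop_len = integer(), stem5_start = integer(), stem3_end = integer()
  )

  if (circular) {
    w_eff <- min(window, (L - motif_len) %/% 2L)
    left <- offset - w_eff # global 0-based, may be negative
    ctx <- circ_substr(seq, left, motif_len + 2L * w_eff)
    ns <- w_eff # local 0-based motif start
  } else {
    left <- max(0L, offset - window)
    right <- min(L, offset + motif_len + window)
    ctx <- substr(seq, left + 1L, right)
    ns <- offset - left
  }
  ch <- chars(ctx)
  nctx <- length(ch)
  cch <- comp_base(ch)

  best <- NULL
  for (ls in seq.int(max(0L, ns + motif_len - max_loop), ns)) {
    for (le in seq.int(ns + motif_len, min(nctx, ls + max_loop))) {
      # arms flank the half-open loop [ls, le): 1-based chars ls and le+1
      a <- 0L
      while (a < max_arm &&
             ls - a >= 1L && le + a + 1L <= nctx &&
             ch[ls - a] == cch[le + a + 1L]) {
        a <- a + 1L
      }
      if (a < min_arm) next
      cand <- c(a, le - ls, ls)
      if (is.null(best) ||
          cand[1L] > best[1L] ||
          (cand[1L] == best[1L] && cand[2L] < best[2L]) ||
          (cand[1L] == best[1L] && cand[2L] == best[2L] && cand[3L] < best[3L])) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(empty)
  a <- best[1L]; ls <- best[3L]; le <- ls + best[2L]
  g <- function(p) if (circular) ((left + p) %% L + L) %% L else left + p
  tibble(
    arm_len = a,
    loop_start = g(ls), loop_end = g(le), loop_len = le - ls,
    stem5_start = g(ls - a), stem3_end = g(le + a)
  )
}

#' Scan a genome for stem-loop replication origins
#'
#' Composition of [find_nonamer_sites()] and [detect_hairpin()]: every
#' motif site is tested for an enclosing hairpin and only sites embedded in
#' one are returned — the signature used to recognise rolling-circle
#' replication origins of CRESS-DNA viruses.
#'
#' @inheritParams find_nonamer_sites
#' @inheritParams detect_hairpin
#' @return A tibble with one row per stem-loop: `motif`, `offset`, `strand`,
#'   `mismatches`, `arm_len`, `loop_start`, `loop_end`, `loop_len`,
#'   `stem5_start`, `stem3_end`.
#' @export
scan_stemloops <- function(seq, canonical = "TAGTATTAC", max_mismatch = 1L,
                           min_arm = 5L, max_arm = 20L, max_loop = 15L,
                           window = 40L, circular = TRUE) {
  sites <- find_nonamer_sites(
    seq, canonical = canonical,
    max_mismatch = max_mismatch, circular = circular
  )
  hp_cols <- tibble(
    arm_len = integer(), loop_start = integer(), loop_end = integer(),
    loop_len = integer(), stem5_start = integer(), stem3_end = integer()
  )
  if (!nrow(sites)) return(bind_cols(sites, hp_cols[0, ]))
  out <- purrr::map(seq_len(nrow(sites)), function(i) {
    hp <- detect_hairpin(
      seq, sites$offset[i], motif_len = nchar(canonical),
      min_arm = min_arm, max_arm = max_arm, max_loop = max_loop,
      window = window, circular = circular
    )
    if (!nrow(hp)) return(NULL)
    bind_cols(sites[i, ], hp)
  })
  out <- bind_rows(purrr::compact(out))
  if (!nrow(out)) return(bind_cols(sites[0, ], hp_cols))
  arrange(out, .data$offset, .data$strand)
}
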