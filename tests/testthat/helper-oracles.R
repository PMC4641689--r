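# Independent brute-force oracles. These deliberately take the slowest,
# most literal route (per-position walks, full enumeration) so they share
# no code path with the package implementation.

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# largest k with prefix(k) == suffix(k), all k tried explicitly
bf_terminal_overlap <- function(seq, min_overlap, max_overlap_frac = 0.5) {
  n <- nchar(seq)
  found <- NA_integer_
  for (k in seq_len(floor(max_overlap_frac * n))) {
    if (k < min_overlap) next
    if (substr(seq, 1, k) == substr(seq, n - k + 1, n)) found <- k
  }
  found
}

# ORF caller by per-ATG codon walk on the doubled sequence
bf_orfs <- function(seq, min_len = 300L, circular = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc_oracle(seq)
    scan <- if (circular) paste0(s, s) else s
    n <- nchar(scan)
    max_start <- if (circular) L - 1L else n - 3L
    cands <- NULL
    for (p in 0:max_start) {
      if (substr(scan, p + 1L, p + 3L) != "ATG") next
      q <- p + 3L
      repeat {
        if (q + 3L > n || q + 3L - p > L) {
          q <- NA_integer_
          break
        }
        if (substr(scan, q + 1L, q + 3L) %in% stops) break
        q <- q + 3L
      }
      if (is.na(q)) next
      len <- q + 3L - p
      if (len < min_len) next
      cands <- rbind(cands, c(start = p, stop_key = q %% L, len = len))
    }
    if (is.null(cands)) next
    # longest ORF per stop codon
    keep <- unlist(lapply(
      split(seq_len(nrow(cands)), cands[, "stop_key"]),
      function(ix) ix[which.max(cands[ix, "len"])]
    ))
    cands <- cands[keep, , drop = FALSE]
    res[[strand]] <- data.frame(
      strand = strand,
      start = as.integer(cands[, "start"] %% L),
      length_nt = as.integer(cands[, "len"])
    )
  }
  if (!length(res)) {
    return(data.frame(strand = character(), start = integer(),
                      length_nt = integer()))
  }
  out <- unique(do.call(rbind, res))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best hairpin around a motif site by full enumeration of (loop, arm) pairs
bf_hairpin <- function(seq, offset, motif_len = 9L, min_arm = 5L,
                       max_arm = 20L, max_loop = 15L, window = 40L,
                       circular = TRUE) {
  L <- nchar(seq)
  w_eff <- if (circular) min(window, (L - motif_len) %/% 2L) else window
  getseq <- function(from, to) { # 0-based half-open, may be out of range
    if (to <= from) return("")
    if (circular) {
      idx <- (seq.int(from, to - 1L) %% L + L) %% L + 1L
      paste(strsplit(seq, "")[[1]][idx], collapse = "")
    } else {
      if (from < 0L || to > L) return(NA_character_)
      substr(seq, from + 1L, to)
    }
  }
  best <- NULL
  for (ls in seq.int(offset + motif_len - max_loop, offset)) {
    for (le in seq.int(offset + motif_len, ls + max_loop)) {
      for (a in seq.int(min_arm, max_arm)) {
        if (ls - a < offset - w_eff) next
        if (le + a > offset + motif_len + w_eff) next
        arm5 <- getseq(ls - a, ls)
        arm3 <- getseq(le, le + a)
        if (is.na(arm5) || is.na(arm3)) next
        if (arm5 != rc_oracle(arm3)) next
        cand <- c(arm = a, loop = le - ls, ls = ls)
        if (is.null(best) ||
            cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] < best[2]) ||
            (cand[1] == best[1] && cand[2] == best[2] && cand[3] < best[3])) {
          best <- cand
        }
      }
    }
  }
  best # c(arm, loop, ls) or NULL
}

# optimal global alignment score by exhaustive enumeration of all
# alignments (move sequences), affine gaps: a gap of length g costs
# open + g * ext
bf_align_score <- function(a, b, match = 1, mismatch = -2,
                           open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A)
  nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i == na && j == nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < na && j < nb) {
      s <- if (A[i + 1] == B[j + 1]) match else mismatch
      rec(i + 1, j + 1, "M", sc + s)
    }
    if (i < na) rec(i + 1, j, "X", sc - ext - if (prev == "X") 0 else open)
    if (j < nb) rec(i, j + 1, "Y", sc - ext - if (prev == "Y") 0 else open)
  }
  rec(0L, 0L, "", 0)
  best
}

# multiset signature of an ORF table that is invariant under rotation and
# strand flip of the genome
orf_signature <- function(orfs) {
  sig <- paste(orfs$length_nt, orfs$crosses_breakpoint * 0 + nchar(orfs$protein),
               orfs$protein, sep = ":")
  sort(sig)
}

stemloop_signature <- function(hits) {
  sort(paste(hits$motif, hits$arm_len, hits$loop_len, sep = ":"))
}
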