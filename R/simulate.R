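# Synthetic contig generator with a machine-readable truth table. Genomes
# are built as circular character sequences with planted features (stem-loop
# origins, ORFs, low-complexity runs); a sanitation pass removes chance
# features from the background so that the truth table is exhaustive, and
# contigs are emitted through the same terminal-redundancy process an
# assembler produces.

#' Construct a synthetic circular genome scaffold
#'
#' An i.i.d. random circle of the requested length and GC content, with an
#' (initially empty) feature table used for collision checking and truth
#' recording by the `plant_*` functions.
#'
#' @param length Genome length in nt (>= 100).
#' @param gc Target GC fraction, strictly inside (0, 1).
#' @return A `sim_genome`: list with `seq`, `length` and a `features`
#'   tibble (`type`, `start`, `end`, `strand`, `info`); `start`/`end` are
#'   the occupied block including guard bases, 0-based half-open, `end`
#'   possibly exceeding `length` to indicate wrapping.
#' @export
sim_genome <- function(length, gc = 0.5) {
  structure(
    list(
      seq = random_circular_genome(length, gc),
      length = as.integer(length),
      features = tibble(
        type = character(), start = integer(), end = integer(),
        strand = character(), info = list()
      )
    ),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "<sim_genome> %d nt, GC %.3f, %d planted feature(s)\n",
    x$length, gc_content(x$seq), nrow(x$features)
  ))
  invisible(x)
}

#' Random circular genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc` (G and C, and A and T,
#' equiprobable). Deterministic given the RNG state; seed via `set.seed()`
#' or [withr::with_seed()].
#'
#' @inheritParams sim_genome
#' @return A single DNA string.
#' @export
random_circular_genome <- function(length, gc = 0.5) {
  if (length < 100L) abort("`length` must be >= 100")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) abort("`gc` must be strictly inside (0, 1)")
  paste(
    sample(DNA_BASES, length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""
  )
}

# positions (0-based, mod L) covered by a block [start, end)
block_positions <- function(start, end, L) {
  ((seq.int(start, end - 1L)) %% L + L) %% L
}

occupied_positions <- function(g) {
  if (!nrow(g$features)) return(integer())
  sort(unique(unlist(purrr::map2(
    g$features$start, g$features$end, block_positions, L = g$length
  ))))
}

check_collision <- function(g, start, end, what) {
  pos <- block_positions(start, end, g$length)
  if (length(pos) != length(unique(pos))) {
    abort(sprintf("%s does not fit on the genome without self-overlap", what))
  }
  if (length(intersect(pos, occupied_positions(g)))) {
    abort(sprintf("%s overlaps a previously planted feature", what))
  }
  invisible(pos)
}

# overwrite genome characters at 0-based positions (mod L)
write_circular <- function(seq, start0, replacement) {
  L <- nchar(seq)
  ch <- chars(seq)
  idx <- (seq.int(start0, start0 + nchar(replacement) - 1L) %% L + L) %% L + 1L
  ch[idx] <- chars(replacement)
  paste(ch, collapse = "")
}

char_at <- function(seq, pos0) {
  L <- nchar(seq)
  p <- (pos0 %% L + L) %% L
  substr(seq, p + 1L, p + 1L)
}

#' Plant a stem-loop replication origin
#'
#' Writes `5'-arm + loop + revcomp(arm)-3'` at `offset`, with the nonamer
#' motif centred in the loop. The bases immediately flanking the stem are
#' set non-complementary so the planted arm length is exactly the maximal
#' one, and when the loop is padded its two edge bases are kept
#' non-complementary so the planted loop cannot shrink — the scanner
#' recovers exactly the planted geometry.
#'
#' @param g A `sim_genome`.
#' @param offset 0-based position of the 5' arm start.
#' @param arm_len Stem arm length in bp.
#' @param loop_len Loop length in nt (>= motif length).
#' @param nonamer The 9-nt motif to embed.
#' @return The updated `sim_genome` (truth recorded in `features`).
#' @export
plant_stemloop <- function(g, offset, arm_len = 11L, loop_len = 11L,
                           nonamer = "TAGTATTAA") {
  stopifnot(inherits(g, "sim_genome"))
  nonamer <- clean_seq(nonamer)
  k <- nchar(nonamer)
  if (arm_len < 1L) abort("`arm_len` must be >= 1")
  if (loop_len < k) abort("`loop_len` must be >= the motif length")
  span <- 2L * arm_len + loop_len
  if (span + 2L > g$length) abort("stem-loop does not fit on the genome")
  offset <- as.integer(offset)
  check_collision(g, offset - 1L, offset + span + 1L, "stem-loop")

  pad_left <- (loop_len - k) %/% 2L
  pad_right <- loop_len - k - pad_left
  pl <- if (pad_left) paste(sample(DNA_BASES, pad_left, TRUE), collapse = "") else ""
  pr <- if (pad_right) paste(sample(DNA_BASES, pad_right, TRUE), collapse = "") else ""
  loop <- paste0(pl, nonamer, pr)
  # keep the loop edges unpaired so the loop cannot shrink
  if (pad_left > 0L && pad_right > 0L) {
    first <- substr(loop, 1L, 1L)
    last <- substr(loop, loop_len, loop_len)
    if (first == comp_base(last)) {
      repl <- sample(setdiff(DNA_BASES, comp_base(last)), 1L)
      loop <- paste0(repl, substr(loop, 2L, loop_len))
    }
  }
  arm5 <- paste(sample(DNA_BASES, arm_len, TRUE), collapse = "")
  region <- paste0(arm5, loop, revcomp(arm5))
  g$seq <- write_circular(g$seq, offset, region)
  # guard bases outside the stem must not pair with each other
  gr <- sample(DNA_BASES, 1L)
  gl <- sample(setdiff(DNA_BASES, comp_base(gr)), 1L)
  g$seq <- write_circular(g$seq, offset - 1L, gl)
  g$seq <- write_circular(g$seq, offset + span, gr)
  g$features <- bind_rows(g$features, tibble(
    type = "stemloop", start = offset - 1L, end = offset + span + 1L,
    strand = "+",
    info = list(list(
      arm_len = as.integer(arm_len), loop_len = as.integer(loop_len),
      nonamer = nonamer,
      nonamer_offset = (offset + arm_len + nchar(pl)) %% g$length,
      loop_start = (offset + arm_len) %% g$length
    ))
  ))
  g
}

#' Plant an open reading frame
#'
#' Writes `ATG`, random non-stop internal codons, and a stop codon on the
#' requested strand; a guard stop codon is written immediately upstream (in
#' the reading direction) so the planted `ATG` is always the first start
#' after the previous in-frame stop and the ORF is recovered at exactly the
#' planted coordinates. The ORF may wrap the circular origin.
#'
#' @param g A `sim_genome`.
#' @param start 0-based plus-strand position of the leftmost base of the
#'   ORF interval `[start, start + length_nt)` (mod genome length).
#' @param length_nt ORF length in nt including the stop codon; divisible
#'   by 3, >= 9.
#' @param strand `"+"` or `"-"` (reading direction).
#' @return The updated `sim_genome`.
#' @export
plant_orf <- function(g, start, length_nt, strand = c("+", "-")) {
  stopifnot(inherits(g, "sim_genome"))
  strand <- match.arg(strand)
  length_nt <- as.integer(length_nt)
  if (length_nt %% 3L != 0L) abort("`length_nt` must be divisible by 3")
  if (length_nt < 9L) abort("`length_nt` must be >= 9")
  if (length_nt + 3L >= g$length) abort("ORF does not fit on the genome")
  start <- as.integer(start)
  block <- if (strand == "+") c(start - 3L, start + length_nt) else
    c(start, start + length_nt + 3L)
  check_collision(g, block[1], block[2], "ORF")
  cassette <- paste0(
    "TAA", # guard stop upstream of the start codon
    "ATG",
    paste(sample(NON_STOP_CODONS, length_nt / 3L - 2L, TRUE), collapse = ""),
    sample(STOP_CODONS, 1L)
  )
  if (strand == "+") {
    g$seq <- write_circular(g$seq, start - 3L, cassette)
  } else {
    g$seq <- write_circular(g$seq, start, revcomp(cassette))
  }
  info_rec <- list(
    plus_start = start %% g$length, length_nt = length_nt, strand = strand
  )
  g$features <- bind_rows(g$features, tibble(
    type = "orf", start = block[1], end = block[2], strand = strand,
    info = list(info_rec)
  ))
  g
}

# rewrite the internal codons of a planted ORF with fresh random non-stop
# codons (used by the sanitizer when a chance feature falls inside an ORF)
resample_orf_internals <- function(g, feature_idx) {
  info <- g$features$info[[feature_idx]]
  len <- info$length_nt
  inner <- paste(sample(NON_STOP_CODONS, len / 3L - 2L, TRUE), collapse = "")
  if (info$strand == "+") {
    g$seq <- write_circular(g$seq, info$plus_start + 3L, inner)
  } else {
    # internal codons sit between stop (left) and ATG (right) on the plus strand
    g$seq <- write_circular(g$seq, info$plus_start + 3L, revcomp(inner))
  }
  g
}

#' Plant a low-complexity tandem repeat
#'
#' Writes `n_units` copies of a short repeat unit (default `GT`), with the
#' immediately flanking bases chosen so the planted run is exactly maximal.
#'
#' @param g A `sim_genome`.
#' @param offset 0-based start position.
#' @param unit Repeat unit (1 or 2 nt).
#' @param n_units Number of unit copies.
#' @return The updated `sim_genome`.
#' @export
plant_lc_run <- function(g, offset, unit = "GT", n_units = 15L) {
  stopifnot(inherits(g, "sim_genome"))
  unit <- clean_seq(unit)
  p <- nchar(unit)
  if (!p %in% c(1L, 2L)) abort("`unit` must be 1 or 2 nt")
  span <- p * as.integer(n_units)
  offset <- as.integer(offset)
  check_collision(g, offset - 1L, offset + span + 1L, "low-complexity run")
  run <- strrep(unit, n_units)
  g$seq <- write_circular(g$seq, offset, run)
  # break period-p continuation on both sides
  left_bad <- char_at(g$seq, offset + p - 1L) # char that would extend leftwards
  g$seq <- write_circular(g$seq, offset - 1L,
                          sample(setdiff(DNA_BASES, left_bad), 1L))
  right_bad <- char_at(g$seq, offset + span - p)
  g$seq <- write_circular(g$seq, offset + span,
                          sample(setdiff(DNA_BASES, right_bad), 1L))
  g$features <- bind_rows(g$features, tibble(
    type = "lc_run", start = offset - 1L, end = offset + span + 1L,
    strand = "+",
    info = list(list(unit = unit, n_units = as.integer(n_units), span = span))
  ))
  g
}

# expected find_orfs rows for the planted ORFs (strand + reading-strand start)
planted_orf_keys <- function(g) {
  idx <- which(g$features$type == "orf")
  if (!length(idx)) {
    return(tibble(strand = character(), start = integer(), length_nt = integer()))
  }
  bind_rows(purrr::map(idx, function(i) {
    info <- g$features$info[[i]]
    st <- if (info$strand == "+") info$plus_start %% g$length else
      (g$length - info$plus_start - info$length_nt) %% g$length
    tibble(strand = info$strand, start = as.integer(st),
           length_nt = as.integer(info$length_nt))
  }))
}

# plus-strand positions of an ORF reported by find_orfs
orf_report_positions <- function(start, length_nt, strand, L) {
  iv <- orf_plus_interval(start, length_nt, strand, L)
  block_positions(iv[1], iv[2], L)
}

#' Remove chance features from a synthetic genome's background
#'
#' Random background sequence inevitably contains spurious long ORFs and
#' near-matches to the origin nonamer. This pass repeatedly rescans the
#' genome and (i) destroys every ORF at or above `orf_min_len` that was not
#' planted, by writing an in-frame stop codon at an unoccupied position
#' inside it, and (ii) destroys every unplanted nonamer site (within
#' `max_mismatch` of `canonical`, either strand) by mutating one unoccupied
#' base. When a chance feature lies entirely inside a planted ORF, that
#' ORF's internal codons are resampled instead. After this pass the truth
#' table is exhaustive: the detection modules find the planted features and
#' nothing else.
#'
#' @param g A `sim_genome`.
#' @param orf_min_len Spurious-ORF length threshold (nt).
#' @param canonical,max_mismatch Nonamer scan parameters.
#' @param max_iter Safety bound on rescan iterations.
#' @return The sanitised `sim_genome`.
#' @export
sanitize_background <- function(g, orf_min_len = 300L,
                                canonical = "TAGTATTAC", max_mismatch = 1L,
                                max_iter = 100L) {
  stopifnot(inherits(g, "sim_genome"))
  L <- g$length
  for (iter in seq_len(max_iter)) {
    occ <- occupied_positions(g)
    changed <- FALSE
    debug_san <- isTRUE(getOption("circvirome.debug_sanitize"))

    orfs <- find_orfs(g$seq, min_len = orf_min_len, circular = TRUE)
    keys <- planted_orf_keys(g)
    if (nrow(orfs)) {
      spurious <- anti_join(orfs, keys, by = c("strand", "start", "length_nt"))
    } else {
      spurious <- orfs
    }
    if (nrow(spurious)) {
      if (debug_san) {
        message(sprintf("sanitize iter %d: %d spurious ORF(s): %s", iter,
          nrow(spurious),
          paste(spurious$strand, spurious$start, spurious$length_nt,
                collapse = " | ")))
      }
      for (r in seq_len(nrow(spurious))) {
        o <- spurious[r, ]
        fixed <- FALSE
        n_codons <- o$length_nt / 3L
        # all internal codons whose bases are untouched by planted features,
        # as plus-strand triple starts; the codon written is chosen at
        # random so that interacting chance ORFs cannot cycle
        cand <- integer()
        for (j in seq_len(max(0L, n_codons - 2L))) { # internal codons only
          trip <- if (o$strand == "+") {
            (o$start + 3L * j + 0:2) %% L
          } else {
            # codon j of the minus-strand reading, as plus-strand positions
            (L - o$start - 3L * j - 3L + 0:2) %% L
          }
          if (!length(intersect(trip, occ))) cand <- c(cand, trip[1L])
        }
        if (length(cand)) {
          stopc <- sample(STOP_CODONS, 1L)
          p <- if (length(cand) == 1L) cand else sample(cand, 1L)
          g$seq <- write_circular(
            g$seq, p, if (o$strand == "+") stopc else revcomp(stopc)
          )
          fixed <- TRUE
        }
        if (!fixed) {
          pos <- orf_report_positions(o$start, o$length_nt, o$strand, L)
          host <- which(g$features$type == "orf" & purrr::map_lgl(
            seq_len(nrow(g$features)),
            function(i) length(intersect(
              block_positions(g$features$start[i], g$features$end[i], L), pos
            )) > 0
          ))
          if (!length(host)) {
            abort("cannot sanitize: spurious ORF has no mutable position")
          }
          g <- resample_orf_internals(g, host[1L])
        }
      }
      next
    }

    sites <- find_nonamer_sites(
      g$seq, canonical = canonical, max_mismatch = max_mismatch, circular = TRUE
    )
    sl_idx <- which(g$features$type == "stemloop")
    sl_pos <- if (length(sl_idx)) {
      unique(unlist(purrr::map(sl_idx, function(i) {
        block_positions(g$features$start[i], g$features$end[i], L)
      })))
    } else {
      integer()
    }
    if (nrow(sites)) {
      if (debug_san) {
        message(sprintf("sanitize iter %d: %d nonamer site(s): %s", iter,
          nrow(sites),
          paste(sites$strand, sites$offset, sites$mismatches, collapse = " | ")))
      }
      can <- chars(clean_seq(canonical))
      for (i in seq_len(nrow(sites))) {
        pos <- (sites$offset[i] + 0:8) %% L
        if (length(intersect(pos, sl_pos))) next # planted origin
        # the plus-strand base the canonical motif expects at site position p
        expected_at <- function(p) {
          i0 <- match(p, pos) - 1L # 0-based position within the site
          if (sites$strand[i] == "+") can[i0 + 1L] else comp_base(can[9L - i0])
        }
        free <- setdiff(pos, occ)
        # only editing a currently-matching position raises the mismatch
        # count; push the site strictly past the tolerance
        matching_free <- free[vapply(
          free, function(p) char_at(g$seq, p) == expected_at(p), logical(1)
        )]
        need <- max_mismatch + 1L - sites$mismatches[i]
        if (length(matching_free) >= need) {
          for (p in matching_free[seq_len(need)]) {
            g$seq <- write_circular(
              g$seq, p, sample(setdiff(DNA_BASES, expected_at(p)), 1L)
            )
          }
        } else {
          host <- which(g$features$type == "orf" & purrr::map_lgl(
            seq_len(nrow(g$features)),
            function(k) length(intersect(
              block_positions(g$features$start[k], g$features$end[k], L), pos
            )) > 0
          ))
          if (!length(host)) abort("cannot sanitize: nonamer site not mutable")
          g <- resample_orf_internals(g, host[1L])
        }
        changed <- TRUE
      }
      if (changed) next
    }
    return(g)
  }
  abort("sanitize_background did not converge")
}

#' Linearize a circular genome the way an assembler does
#'
#' Rotates the circle to start at `breakpoint` and appends its first
#' `overlap_len` bases again at the end, reproducing the identical-ends
#' terminal redundancy of assembled circular templates. `overlap_len = 0`
#' gives a plain rotation (a linear-looking contig).
#'
#' @param seq A circular genome sequence.
#' @param breakpoint 0-based rotation point, `0 <= breakpoint < length`.
#' @param overlap_len Duplicated end length, `0 <= overlap_len < length`.
#' @return The linearized contig (length `nchar(seq) + overlap_len`).
#' @export
linearize_with_overlap <- function(seq, breakpoint, overlap_len) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  L <- nchar(seq)
  if (breakpoint < 0L || breakpoint >= L) abort("`breakpoint` must be in [0, length)")
  if (overlap_len < 0L || overlap_len >= L) abort("`overlap_len` must be in [0, length)")
  rot <- rotate_seq(seq, breakpoint)
  if (overlap_len == 0L) return(rot)
  paste0(rot, substr(rot, 1L, overlap_len))
}

#' Mutate a sequence with point substitutions and optional indels
#'
#' Each position is substituted with probability `divergence` (uniformly
#' over the three alternative bases, so a drawn site always changes);
#' insertions and deletions each occur at rate `indel_rate / 2` per
#' position, with lengths 1-3 (geometric, truncated). The substitution-
#' dominated model matches nucleotide-level identity analyses; the default
#' `indel_rate = 0` keeps divergence exactly countable.
#'
#' @param seq A single sequence.
#' @param divergence Per-site substitution probability, `<= 0.5`.
#' @param indel_rate Per-site indel probability (default 0).
#' @return A list: `seq` (mutated), `n_substitutions`, `n_insertions`,
#'   `n_deletions`, `substituted_sites` (0-based positions on the input).
#' @export
mutate_seq <- function(seq, divergence, indel_rate = 0) {
  seq <- clean_seq(seq)
  assert_scalar_dna(seq)
  if (divergence < 0 || divergence > 0.5) abort("`divergence` must be in [0, 0.5]")
  if (indel_rate < 0 || indel_rate > 0.5) abort("`indel_rate` must be in [0, 0.5]")
  ch <- chars(seq)
  n <- length(ch)
  sub_idx <- which(runif(n) < divergence)
  for (i in sub_idx) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  n_ins <- 0L
  n_del <- 0L
  if (indel_rate > 0) {
    del_idx <- which(runif(n) < indel_rate / 2)
    ins_idx <- which(runif(n) < indel_rate / 2)
    pieces <- as.list(ch)
    for (i in del_idx) {
      len <- min(3L, rgeom(1L, 0.5) + 1L, n - i + 1L)
      for (j in seq.int(i, i + len - 1L)) pieces[[j]] <- ""
      n_del <- n_del + len
    }
    for (i in ins_idx) {
      len <- min(3L, rgeom(1L, 0.5) + 1L)
      pieces[[i]] <- paste0(
        pieces[[i]], paste(sample(DNA_BASES, len, TRUE), collapse = "")
      )
      n_ins <- n_ins + len
    }
    out <- paste(unlist(pieces), collapse = "")
  } else {
    out <- paste(ch, collapse = "")
  }
  list(
    seq = out,
    n_substitutions = length(sub_idx),
    n_insertions = n_ins,
    n_deletions = n_del,
    substituted_sites = sub_idx - 1L
  )
}

#' Specification for a synthetic contig dataset
#'
#' Defaults emulate the composition of a circular-DNA-enriched rodent
#' faecal assembly: a few ~7.7 kb papillomavirus-like circles carrying
#' seven ORFs, CRESS-like ~1.9 kb circles with a stem-loop origin and two
#' ORFs, short ~850 nt stem-loop circles with 1-2 ORFs (defective/
#' multicomponent-like), and linear background contigs.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_papilloma,n_cress,n_short,n_linear Contig counts per class.
#' @param papilloma_range,cress_range,short_range,linear_range Length
#'   ranges (nt) per class.
#' @param gc Target GC fraction.
#' @param overlap_range Terminal-redundancy length range (nt) for circular
#'   classes.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L,
                     n_papilloma = 4L, n_cress = 4L, n_short = 6L,
                     n_linear = 6L,
                     papilloma_range = c(7200L, 8300L),
                     cress_range = c(1700L, 3000L),
                     short_range = c(780L, 950L),
                     linear_range = c(500L, 3000L),
                     gc = 0.5,
                     overlap_range = c(20L, 60L)) {
  counts <- c(n_papilloma, n_cress, n_short, n_linear)
  if (any(counts < 0L)) abort("class counts must be >= 0")
  for (r in list(papilloma_range, cress_range, short_range, linear_range,
                 overlap_range)) {
    if (length(r) != 2L || r[2] < r[1]) abort("ranges must be c(lo, hi) with hi >= lo")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_papilloma = n_papilloma, n_cress = n_cress,
      n_short = n_short, n_linear = n_linear,
      papilloma_range = papilloma_range, cress_range = cress_range,
      short_range = short_range, linear_range = linear_range,
      gc = gc, overlap_range = overlap_range
    ),
    class = "sim_spec"
  )
}

sample_range <- function(r) sample(seq.int(r[1], r[2]), 1L)

# one genome of a given class; returns list(g = sim_genome or NULL,
# seq = circle/linear sequence, truth columns)
build_class_genome <- function(class, spec) {
  if (class == "linear") {
    len <- sample_range(spec$linear_range)
    return(list(
      g = NULL, seq = random_circular_genome(len, spec$gc),
      true_length = len, has_stemloop = FALSE, n_orfs = NA_integer_
    ))
  }
  if (class == "papilloma") {
    L <- sample_range(spec$papilloma_range)
    g <- sim_genome(L, spec$gc)
    lens <- c(1500L, 1050L, 450L, 300L, 501L, 1401L, 1200L)
    strands <- c("+", "+", "+", "+", "-", "+", "+")
    gap <- 3L + 24L + (L - sum(lens) - 7L * 27L) %/% 7L
    pos <- 3L
    for (i in seq_along(lens)) {
      g <- plant_orf(g, pos, lens[i], strands[i])
      pos <- pos + lens[i] + gap
    }
    n_orfs <- 7L
    has_sl <- FALSE
  } else if (class == "cress") {
    L <- sample_range(spec$cress_range)
    g <- sim_genome(L, spec$gc)
    g <- plant_stemloop(g, 50L, arm_len = 11L, loop_len = 11L,
                        nonamer = "TAGTATTAA")
    orf1 <- 3L * ((L %/% 3L) * 3L %/% 10L) # ~30% of L, multiple of 3
    orf1 <- max(303L, 3L * (orf1 %/% 3L))
    orf2 <- max(303L, 3L * ((L %/% 4L) %/% 3L))
    g <- plant_orf(g, 130L, orf1, "+")
    g <- plant_orf(g, 130L + orf1 + 30L, orf2, "-")
    n_orfs <- 2L
    has_sl <- TRUE
  } else { # short
    L <- sample_range(spec$short_range)
    g <- sim_genome(L, spec$gc)
    g <- plant_stemloop(g, 30L, arm_len = 11L, loop_len = 11L,
                        nonamer = "TAGTATTAA")
    n_orfs <- sample(1:2, 1L)
    pos <- 100L
    for (i in seq_len(n_orfs)) {
      g <- plant_orf(g, pos, 303L, "+")
      pos <- pos + 303L + 30L
    }
    has_sl <- TRUE
  }
  g <- sanitize_background(g)
  list(
    g = g, seq = g$seq, true_length = g$length,
    has_stemloop = has_sl, n_orfs = n_orfs
  )
}

class_category <- c(
  papilloma = "papillomavirus_sized",
  cress = "cress_sized",
  short = "short_circular_defective_or_multicomponent",
  linear = "not_circular"
)

#' Generate a synthetic contig dataset with its truth table
#'
#' Builds one genome per requested contig (see [sim_spec()]), sanitises
#' chance background features, linearizes each circular genome at a random
#' breakpoint with a random terminal redundancy, and shuffles the output
#' order. A single root seed drives everything: per-contig RNG substreams
#' are derived up front, so results are fully reproducible and insertion
#' order never changes downstream draws.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `sim_dataset`: `contigs` (tibble `id`, `seq`,
#'   `length`) and `truth` (tibble `contig_id`, `class`, `category`,
#'   `true_length`, `breakpoint`, `overlap_len`, `has_stemloop`,
#'   `stemloop_offset`, `stemloop_arm`, `stemloop_loop`, `nonamer`,
#'   `n_orfs`, plus an `orfs` list-column of planted ORF keys).
#' @export
simulate_contigs <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  classes <- rep(
    c("papilloma", "cress", "short", "linear"),
    times = c(spec$n_papilloma, spec$n_cress, spec$n_short, spec$n_linear)
  )
  n <- length(classes)
  if (!n) {
    return(structure(list(
      contigs = tibble(id = character(), seq = character(), length = integer()),
      truth = tibble()
    ), class = "sim_dataset"))
  }
  records <- withr::with_seed(spec$seed, {
    subseeds <- sample.int(2147483646L, n + 1L)
    recs <- purrr::map(seq_len(n), function(i) {
      withr::with_seed(subseeds[i], {
        built <- build_class_genome(classes[i], spec)
        if (classes[i] == "linear") {
          contig <- built$seq
          bp <- NA_integer_
          ov <- NA_integer_
        } else {
          bp <- sample(0:(built$true_length - 1L), 1L)
          ov <- sample_range(spec$overlap_range)
          contig <- linearize_with_overlap(built$seq, bp, ov)
        }
        sl <- if (built$has_stemloop) {
          g <- built$g
          i_sl <- which(g$features$type == "stemloop")[1L]
          g$features$info[[i_sl]]
        } else {
          NULL
        }
        list(
          class = classes[i], contig = contig, circle = built$seq,
          true_length = built$true_length, breakpoint = bp, overlap_len = ov,
          has_stemloop = built$has_stemloop,
          stemloop_offset = if (is.null(sl)) NA_integer_ else sl$nonamer_offset,
          stemloop_arm = if (is.null(sl)) NA_integer_ else sl$arm_len,
          stemloop_loop = if (is.null(sl)) NA_integer_ else sl$loop_len,
          nonamer = if (is.null(sl)) NA_character_ else sl$nonamer,
          n_orfs = built$n_orfs,
          orfs = if (is.null(built$g)) {
            tibble(strand = character(), start = integer(),
                   length_nt = integer())
          } else {
            planted_orf_keys(built$g)
          }
        )
      })
    })
    withr::with_seed(subseeds[n + 1L], recs[sample(n)])
  })
  ids <- sprintf("contig_%03d", seq_len(n))
  contigs <- tibble(
    id = ids,
    seq = purrr::map_chr(records, "contig"),
    length = nchar(purrr::map_chr(records, "contig"))
  )
  truth <- tibble(
    contig_id = ids,
    class = purrr::map_chr(records, "class"),
    category = unname(class_category[purrr::map_chr(records, "class")]),
    true_length = purrr::map_int(records, "true_length"),
    breakpoint = purrr::map_int(records, "breakpoint"),
    overlap_len = purrr::map_int(records, "overlap_len"),
    has_stemloop = purrr::map_lgl(records, "has_stemloop"),
    stemloop_offset = purrr::map_int(records, "stemloop_offset"),
    stemloop_arm = purrr::map_int(records, "stemloop_arm"),
    stemloop_loop = purrr::map_int(records, "stemloop_loop"),
    nonamer = purrr::map_chr(records, "nonamer"),
    n_orfs = purrr::map_int(records, "n_orfs"),
    orfs = purrr::map(records, "orfs"),
    circle = purrr::map_chr(records, function(r) {
      if (r$class == "linear") NA_character_ else r$circle
    })
  )
  structure(list(contigs = contigs, truth = truth), class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits `contigs.fasta` and `truth.tsv` (the planted-ORF list column is
#' serialised as `strand:start:length` triples separated by `;`, and the
#' full circle sequence is omitted).
#'
#' @param ds A `sim_dataset` from [simulate_contigs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(ds$contigs, file.path(dir, "contigs.fasta"))
  flat <- ds$truth
  flat$orfs <- purrr::map_chr(flat$orfs, function(o) {
    if (!nrow(o)) return("")
    paste(sprintf("%s:%d:%d", o$strand, o$start, o$length_nt), collapse = ";")
  })
  flat$circle <- NULL
  readr::write_tsv(flat, file.path(dir, "truth.tsv"))
  invisible(dir)
}
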