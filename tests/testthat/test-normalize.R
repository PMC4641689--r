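# Circularization: terminal redundancy, low-complexity runs, canonical form.

test_that("terminal overlap detection finds the largest identical end", {
  expect_identical(detect_terminal_overlap("ACGTACGTTTACGTACGT", min_overlap = 4L), 8L)
  expect_identical(detect_terminal_overlap("AAAACCCCGGGG", min_overlap = 4L), NA_integer_)
  # an 850-nt circle linearized with a 40-nt duplicated end
  set.seed(101)
  circ <- random_dna(850)
  contig <- linearize_with_overlap(circ, breakpoint = 123L, overlap_len = 40L)
  expect_identical(nchar(contig), 890L)
  expect_identical(detect_terminal_overlap(contig), 40L)
  expect_error(detect_terminal_overlap(""), "non-empty")
  expect_error(detect_terminal_overlap("ACGTXQ"), "outside")
})

test_that("terminal overlap matches the all-k brute-force oracle", {
  set.seed(102)
  for (i in 1:30) {
    L <- sample(60:1800, 1)
    seq <- if (i %% 2 == 0) {
      linearize_with_overlap(random_dna(L), sample(0:(L - 1), 1),
                             sample(10:min(59, L - 1), 1))
    } else {
      random_dna(L)
    }
    expect_identical(
      detect_terminal_overlap(seq, min_overlap = 10L),
      bf_terminal_overlap(seq, min_overlap = 10L)
    )
  }
  # low min_overlap on short random strings exercises chance matches
  set.seed(103)
  for (i in 1:40) {
    seq <- random_dna(sample(20:60, 1), gc = 0.5)
    expect_identical(
      detect_terminal_overlap(seq, min_overlap = 2L),
      bf_terminal_overlap(seq, min_overlap = 2L)
    )
  }
})

test_that("trimming removes the duplicated 5' end and conserves residues", {
  expect_identical(trim_to_circle("ACGTACGTTTACGTACGT", 8L), "TTACGTACGT")
  expect_error(trim_to_circle("ACGTACGT", 0L), "not circular")
  expect_error(trim_to_circle("ACGT", 4L), "smaller than")
  set.seed(104)
  circ <- random_dna(850)
  contig <- linearize_with_overlap(circ, 10L, 40L)
  trimmed <- trim_to_circle(contig, detect_terminal_overlap(contig))
  expect_identical(nchar(trimmed) + 40L, nchar(contig))
  expect_identical(nchar(trimmed), 850L)
})

test_that("low-complexity runs are found and excised", {
  runs <- find_low_complexity(paste0("AAA", strrep("GT", 15), "CCC"), 2L, 20L)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$period, 2L)
  expect_identical(runs$unit, "GT")
  expect_identical(runs$end - runs$start, 30L)

  expect_identical(nrow(find_low_complexity(strrep("ACGT", 3), 2L, 4L)), 0L)

  runs1 <- find_low_complexity(strrep("A", 25), 2L, 20L)
  expect_identical(runs1$period, 1L)
  expect_identical(runs1$unit, "A")
  expect_identical(runs1$end - runs1$start, 25L)

  set.seed(105)
  base <- random_dna(200)
  # insert where the neighbours cannot extend the dinucleotide run
  ch <- strsplit(base, "")[[1]]
  p <- which(ch[1:199] != "T" & ch[2:200] != "G")
  p <- p[p >= 50][1]
  with_run <- paste0(substr(base, 1, p), strrep("GT", 15), substr(base, p + 1, 200))
  runs2 <- find_low_complexity(with_run)
  out <- truncate_low_complexity(with_run, runs2)
  expect_identical(nchar(out), nchar(with_run) - 30L)
  expect_identical(out, base)

  expect_identical(truncate_low_complexity(base, runs2[0, ]), base)

  two <- paste0(substr(base, 1, 50), strrep("A", 20), substr(base, 51, 120),
                strrep("CT", 12), substr(base, 121, 200))
  runs3 <- find_low_complexity(two)
  expect_identical(sum(runs3$end - runs3$start), 44L)
  expect_identical(nchar(truncate_low_complexity(two, runs3)), nchar(two) - 44L)

  bad <- tibble::tibble(start = c(0L, 5L), end = c(10L, 15L))
  expect_error(truncate_low_complexity(base, bad), "overlap")
})

test_that("canonical rotation is a unique rotation-and-strand representative", {
  expect_identical(canonical_rotation("GCA"), "AGC")
  set.seed(106)
  for (i in 1:100) {
    circ <- random_dna(sample(20:200, 1))
    canon <- canonical_rotation(circ)
    # idempotent
    expect_identical(canonical_rotation(canon), canon)
    # rotation invariant
    r <- sample(0:(nchar(circ) - 1), 1)
    rot <- paste0(substr(circ, r + 1, nchar(circ)), substr(circ, 1, r))
    expect_identical(canonical_rotation(rot), canon)
    # strand invariant
    expect_identical(canonical_rotation(rc_oracle(circ)), canon)
  }
})

test_that("linearize -> trim -> canonical round-trip is exact for all breakpoints", {
  set.seed(107)
  for (i in 1:5) {
    L <- sample(40:60, 1)
    circ <- random_dna(L)
    canon <- canonical_rotation(circ)
    for (b in 0:(L - 1)) {
      contig <- linearize_with_overlap(circ, b, 12L)
      ov <- detect_terminal_overlap(contig, min_overlap = 10L)
      expect_false(is.na(ov))
      expect_identical(canonical_rotation(trim_to_circle(contig, ov)), canon)
    }
  }
})

test_that("GC content follows the N-exclusion rule", {
  expect_identical(gc_content("GGCC"), 1)
  expect_identical(gc_content("ATGC"), 0.5)
  expect_identical(gc_content("ATNGC"), 0.5)
  expect_error(gc_content("NNNN"), "all-N")
})

test_that("circularize() assembles the per-contig normalization table", {
  set.seed(108)
  circ <- random_dna(600)
  good <- linearize_with_overlap(circ, 77L, 30L)
  lin <- random_dna(400)
  high_n <- paste0(strrep("N", 60), random_dna(340))
  tbl <- tibble::tibble(
    id = c("c1", "c2", "c3"),
    seq = c(good, lin, high_n)
  )
  out <- circularize(tbl)
  expect_identical(out$id, c("c1", "c2", "c3"))
  expect_identical(out$circular, c(TRUE, FALSE, FALSE))
  expect_identical(out$high_n, c(FALSE, FALSE, TRUE))
  expect_identical(out$overlap_len[1], 30L)
  expect_identical(out$length[1], 600L)
  expect_identical(out$seq[1], canonical_rotation(circ))
  expect_true(is.na(out$seq[2]))
})

test_that("low-complexity truncation precedes overlap detection in the pipeline", {
  # a GT expansion inserted inside the duplicated end region masks the
  # terminal redundancy until it is excised
  set.seed(109)
  circ <- random_dna(500)
  contig <- linearize_with_overlap(circ, 0L, 40L)
  ch <- strsplit(contig, "")[[1]]
  p <- which(ch[1:539] != "T" & ch[2:540] != "G") # non-extending insert point
  p <- p[p >= 200][1]
  contaminated <- paste0(substr(contig, 1, p), strrep("GT", 15),
                         substr(contig, p + 1, 540))
  out <- circularize(tibble::tibble(id = "x", seq = contaminated))
  expect_true(out$circular)
  expect_identical(out$truncated_bases, 30L)
  expect_identical(out$length, 500L)
  expect_identical(out$seq, canonical_rotation(circ))
})
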