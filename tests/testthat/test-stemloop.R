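# Nonanucleotide scanning and inverted-repeat hairpin detection.

ORIGIN_33MER <- "CGAGATTCGTCCTTAGTATTAAGACGAATCTCG"

test_that("the printed origin context yields one nonamer hit in a perfect hairpin", {
  sites <- find_nonamer_sites(ORIGIN_33MER, circular = FALSE)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$motif, "TAGTATTAA")
  expect_identical(sites$offset, 13L)
  expect_identical(sites$strand, "+")
  expect_identical(sites$mismatches, 1L)
  # the single mismatch to TAGTATTAC sits at the 9th motif position
  diffs <- which(strsplit("TAGTATTAA", "")[[1]] != strsplit("TAGTATTAC", "")[[1]])
  expect_identical(diffs, 9L)

  hp <- detect_hairpin(ORIGIN_33MER, 13L, circular = FALSE)
  expect_identical(hp$arm_len, 11L)
  expect_identical(hp$loop_len, 11L)
  expect_identical(hp$loop_start, 11L)
  expect_identical(hp$loop_end, 22L)
  # the loop contains the whole nonamer
  expect_true(hp$loop_start <= 13L && hp$loop_end >= 22L)
  # arms are exact reverse complements
  arm5 <- substr(ORIGIN_33MER, hp$stem5_start + 1, hp$loop_start)
  arm3 <- substr(ORIGIN_33MER, hp$loop_end + 1, hp$stem3_end)
  expect_identical(arm5, rc_oracle(arm3))

  # and the full scan agrees with the exhaustive inverted-repeat oracle
  bf <- bf_hairpin(ORIGIN_33MER, 13L, circular = FALSE)
  expect_identical(unname(bf), c(11L, 11L, 11L))
})

test_that("nonamer scan handles mismatch budget, both strands, and wrapping", {
  expect_identical(nrow(find_nonamer_sites(strrep("A", 50))), 0L)
  expect_error(find_nonamer_sites("ACGTACG"), "shorter")

  set.seed(201)
  base <- random_dna(300)
  g <- circvirome:::write_circular(base, 100L, "TAGTATTAC")
  sites <- find_nonamer_sites(g)
  plus <- sites[sites$strand == "+" & sites$mismatches == 0, ]
  expect_true(100L %in% plus$offset)

  # a minus-strand site: plant the reverse complement of the motif
  g2 <- circvirome:::write_circular(base, 200L, rc_oracle("TAGTATTAC"))
  sites2 <- find_nonamer_sites(g2)
  minus <- sites2[sites2$strand == "-" & sites2$mismatches == 0, ]
  expect_true(200L %in% minus$offset)

  # wrapping the breakpoint: same motif, rotated so it spans position 0
  rot <- circvirome:::rotate_seq(g, 104L) # motif now at L - 4
  sites3 <- find_nonamer_sites(rot)
  expect_true((300L - 4L) %in% sites3$offset[sites3$mismatches == 0])
})

test_that("a nonamer without complementary flanks has no hairpin", {
  # flanks of pure A on one side and pure C on the other can never pair
  seq <- paste0(strrep("A", 40), "TAGTATTAC", strrep("C", 40))
  expect_null(bf_hairpin(seq, 40L, circular = FALSE)) # negative by oracle
  expect_identical(nrow(detect_hairpin(seq, 40L, circular = FALSE)), 0L)
  expect_identical(nrow(scan_stemloops(seq, circular = FALSE)), 0L)
})

test_that("planted hairpins are recovered at exactly the planted geometry", {
  set.seed(202)
  for (arm in c(5L, 7L, 11L)) {
    loop <- if (arm == 7L) 12L else 11L
    g <- sim_genome(400L)
    g <- plant_stemloop(g, 150L, arm_len = arm, loop_len = loop,
                        nonamer = "TAGTATTAA")
    hits <- scan_stemloops(g$seq)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$arm_len, arm)
    expect_identical(hits$loop_len, loop)
    expect_identical(hits$motif, "TAGTATTAA")
  }
  # two non-overlapping origins give two hits
  set.seed(203)
  g2 <- sim_genome(500L)
  g2 <- plant_stemloop(g2, 100L, 7L, 11L)
  g2 <- plant_stemloop(g2, 300L, 9L, 11L)
  expect_identical(nrow(scan_stemloops(g2$seq)), 2L)
})

test_that("hairpin detection matches the exhaustive oracle on small genomes", {
  set.seed(204)
  n_checked <- 0L
  for (i in 1:40) {
    L <- sample(60:200, 1)
    g <- random_dna(L)
    # plant a motif; half the time also a hairpin around one
    off <- sample(30:(L - 40), 1)
    g <- circvirome:::write_circular(g, off, "TAGTATTAC")
    if (i %% 2 == 0) {
      arm <- sample(5:9, 1)
      arm5 <- random_dna(arm)
      g <- circvirome:::write_circular(g, off - arm - 1L, paste0(arm5, "C"))
      g <- circvirome:::write_circular(g, off + 9L, paste0("A", rc_oracle(arm5)))
    }
    sites <- find_nonamer_sites(g)
    for (k in seq_len(nrow(sites))) {
      hp <- detect_hairpin(g, sites$offset[k])
      bf <- bf_hairpin(g, sites$offset[k])
      if (is.null(bf)) {
        expect_identical(nrow(hp), 0L)
      } else {
        n_checked <- n_checked + 1L
        expect_identical(hp$arm_len, as.integer(bf[["arm"]]))
        expect_identical(hp$loop_len, as.integer(bf[["loop"]]))
        expect_identical(hp$loop_start, as.integer(bf[["ls"]] %% L))
      }
    }
  }
  expect_gt(n_checked, 5L) # the positive branch was actually exercised
})

test_that("stem-loop calls are rotation invariant, including across the breakpoint", {
  set.seed(205)
  g <- sim_genome(1890L)
  g <- plant_stemloop(g, 50L, 11L, 11L, "TAGTATTAA")
  g <- sanitize_background(g)
  ref <- scan_stemloops(g$seq)
  expect_identical(nrow(ref), 1L)
  L <- 1890L
  # rotations, including one placing the nonamer at position L - 4
  nonamer_at <- ref$offset
  for (r in c(17L, 555L, 1000L, (nonamer_at + 4L) %% L)) {
    rot <- circvirome:::rotate_seq(g$seq, r)
    hits <- scan_stemloops(rot)
    expect_identical(nrow(hits), 1L)
    expect_identical(stemloop_signature(hits), stemloop_signature(ref))
    expect_identical(hits$offset, (ref$offset - r) %% L)
  }
})

test_that("hits respond monotonically to the scan parameters", {
  set.seed(206)
  for (i in 1:8) {
    g <- sim_genome(300L)
    g <- plant_stemloop(g, 120L, sample(5:9, 1), 11L)
    for (arm_lo in c(5L, 7L, 9L, 12L)) {
      n_lo <- nrow(scan_stemloops(g$seq, min_arm = arm_lo))
      n_hi <- nrow(scan_stemloops(g$seq, min_arm = arm_lo + 2L))
      expect_lte(n_hi, n_lo) # raising min_arm never adds hits
    }
    n_m0 <- nrow(find_nonamer_sites(g$seq, max_mismatch = 0L))
    n_m1 <- nrow(find_nonamer_sites(g$seq, max_mismatch = 1L))
    n_m2 <- nrow(find_nonamer_sites(g$seq, max_mismatch = 2L))
    expect_lte(n_m0, n_m1) # raising the budget never removes sites
    expect_lte(n_m1, n_m2)
  }
})
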