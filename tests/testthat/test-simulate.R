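# The synthetic-contig generator and its truth table.

test_that("random genomes hit the requested length and GC content", {
  set.seed(501)
  g <- random_circular_genome(7707L, 0.5)
  expect_identical(nchar(g), 7707L)
  expect_lt(abs(gc_content(g) - 0.5), 0.02)
  g2 <- withr::with_seed(99L, random_circular_genome(500L))
  g3 <- withr::with_seed(99L, random_circular_genome(500L))
  expect_identical(g2, g3)
  expect_error(random_circular_genome(500L, 0), "inside")
  expect_error(random_circular_genome(50L), ">= 100")
})

test_that("the printed origin region planted verbatim is recovered as arm 11 / loop 11", {
  set.seed(502)
  g <- sim_genome(400L)
  # write the full 33-mer and non-pairing guard bases around it
  g$seq <- circvirome:::write_circular(
    g$seq, 100L, "ACGAGATTCGTCCTTAGTATTAAGACGAATCTCGA"
  )
  hits <- scan_stemloops(g$seq)
  hit <- hits[hits$offset == 114L, ]
  expect_identical(hit$motif, "TAGTATTAA")
  expect_identical(hit$arm_len, 11L)
  expect_identical(hit$loop_len, 11L)
})

test_that("planting collides, validates, and wraps correctly", {
  set.seed(503)
  g <- sim_genome(600L)
  g <- plant_orf(g, 100L, 300L, "+")
  expect_error(plant_orf(g, 250L, 300L, "+"), "overlaps")
  expect_error(plant_orf(g, 450L, 301L, "+"), "divisible")
  expect_error(plant_stemloop(g, 150L, 11L, 11L), "overlaps")
  g <- plant_stemloop(g, 450L, 7L, 12L)
  expect_identical(nrow(g$features), 2L)
  # wrapped ORF: interval crosses position 0
  g2 <- sim_genome(600L)
  g2 <- plant_orf(g2, 500L, 300L, "-")
  key <- circvirome:::planted_orf_keys(g2)
  found <- find_orfs(sanitize_background(g2)$seq, 300L)
  expect_identical(found$start, key$start)
  expect_identical(found$strand, "-")
  expect_true(found$crosses_breakpoint)
})

test_that("linearization adds exactly the requested terminal redundancy", {
  set.seed(504)
  circ <- random_dna(850)
  contig <- linearize_with_overlap(circ, 200L, 40L)
  expect_identical(nchar(contig), 890L)
  expect_identical(substr(contig, 1, 40), substr(contig, 851, 890))
  # overlap 0 is a plain rotation
  rot <- linearize_with_overlap(circ, 200L, 0L)
  expect_identical(nchar(rot), 850L)
  expect_identical(canonical_rotation(rot), canonical_rotation(circ))
  expect_error(linearize_with_overlap(circ, 850L, 10L), "breakpoint")
  expect_error(linearize_with_overlap(circ, 0L, 850L), "overlap_len")
  # round-trip through the circularizer
  out <- circularize(tibble::tibble(id = "x", seq = contig))
  expect_identical(out$seq, canonical_rotation(circ))
})

test_that("the mutation model produces countable, reproducible changes", {
  set.seed(505)
  x <- random_dna(1500)
  expect_identical(mutate_seq(x, 0)$seq, x)
  m <- mutate_seq(x, 0.18)
  # realized substitutions within the Binomial(1500, 0.18) 99% interval
  expect_gt(m$n_substitutions, qbinom(0.005, 1500, 0.18))
  expect_lt(m$n_substitutions, qbinom(0.995, 1500, 0.18))
  # every recorded site actually changed
  ch_in <- strsplit(x, "")[[1]]
  ch_out <- strsplit(m$seq, "")[[1]]
  expect_true(all(ch_in[m$substituted_sites + 1] != ch_out[m$substituted_sites + 1]))
  expect_identical(sum(ch_in != ch_out), m$n_substitutions)
  # seed reproducibility
  m1 <- withr::with_seed(7L, mutate_seq(x, 0.05, indel_rate = 0.01))
  m2 <- withr::with_seed(7L, mutate_seq(x, 0.05, indel_rate = 0.01))
  expect_identical(m1, m2)
  expect_identical(nchar(m1$seq), 1500L + m1$n_insertions - m1$n_deletions)
})

test_that("a dataset is deterministic with a complete truth table", {
  spec <- sim_spec(seed = 7L)
  ds <- simulate_contigs(spec)
  expect_identical(nrow(ds$contigs), 20L)
  expect_identical(nrow(ds$truth), 20L)
  expect_identical(ds$contigs$id, ds$truth$contig_id)
  counts <- table(ds$truth$class)
  expect_identical(as.integer(counts[c("papilloma", "cress", "short", "linear")]),
                   c(4L, 4L, 6L, 6L))
  ds2 <- simulate_contigs(sim_spec(seed = 7L))
  expect_identical(ds, ds2)
  # a different seed keeps the schema and class counts
  ds3 <- simulate_contigs(sim_spec(seed = 8L))
  expect_identical(names(ds3$truth), names(ds$truth))
  expect_identical(table(ds3$truth$class), table(ds$truth$class))
  expect_false(identical(ds3$contigs$seq, ds$contigs$seq))
})

test_that("every planted feature is recovered by the matching module", {
  ds <- simulate_contigs(sim_spec(seed = 3L))
  circles <- ds$truth[ds$truth$class != "linear", ]
  for (i in seq_len(nrow(circles))) {
    tr <- circles[i, ]
    contig <- ds$contigs$seq[ds$contigs$id == tr$contig_id]
    # terminal redundancy
    expect_identical(detect_terminal_overlap(contig), tr$overlap_len)
    circ <- trim_to_circle(contig, tr$overlap_len)
    expect_identical(canonical_rotation(circ), canonical_rotation(tr$circle))
    # stem-loop
    hits <- scan_stemloops(circ)
    if (tr$has_stemloop) {
      expect_identical(nrow(hits), 1L)
      expect_identical(hits$arm_len, tr$stemloop_arm)
      expect_identical(hits$loop_len, tr$stemloop_loop)
      expect_identical(hits$motif, tr$nonamer)
    } else {
      expect_identical(nrow(hits), 0L)
    }
    # ORFs on the original circle match the planted keys exactly
    found <- find_orfs(tr$circle, 300L)
    expect_identical(
      dplyr::arrange(as.data.frame(found[, c("strand", "start", "length_nt")]),
                     start, strand),
      dplyr::arrange(as.data.frame(tr$orfs[[1]]), start, strand),
      ignore_attr = TRUE
    )
  }
})

test_that("written datasets round-trip through FASTA", {
  ds <- simulate_contigs(sim_spec(seed = 2L, n_papilloma = 0L, n_cress = 1L,
                                  n_short = 1L, n_linear = 1L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "contigs.fasta")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_contigs(file.path(dir, "contigs.fasta"))
  expect_identical(back$id, ds$contigs$id)
  expect_identical(back$seq, ds$contigs$seq)
})
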