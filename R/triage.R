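# End-to-end candidate triage: circularize -> stem-loop scan -> ORF call ->
# per-contig evidence table with a size/structure category.

TRIAGE_CATEGORIES <- c(
  "papillomavirus_sized", "cress_sized",
  "short_circular_defective_or_multicomponent",
  "circular_unclassified", "not_circular"
)

#' Triage assembly contigs for circular DNA virus candidates
#'
#' Runs the full evidence pipeline on each contig: low-complexity
#' truncation, terminal-redundancy detection and trimming, canonical
#' rotation, stem-loop origin scan, and circular ORF calling; then assigns
#' one category per contig from the evidence:
#'
#' * `not_circular` — no terminal redundancy (also used, with `high_n =
#'   TRUE`, for contigs exceeding `max_n_frac` ambiguous bases, which are
#'   reported but not analysed);
#' * `papillomavirus_sized` — trimmed length within `pv_size` and at least
#'   `pv_min_orfs` ORFs (papillomavirus genomes are ~8 kb with seven
#'   canonical ORFs);
#' * `cress_sized` — a stem-loop origin and length within `cress_size`
#'   (CRESS-DNA virus genomes run ~1.7-3 kb);
#' * `short_circular_defective_or_multicomponent` — a stem-loop origin but
#'   shorter than `short_max` nt (sub-genomic circles, e.g. ~850 nt, that
#'   carry replication signals but are likely defective molecules or
#'   components of multipartite viruses);
#' * `circular_unclassified` — circular but none of the above.
#'
#' Size windows are evidence-based margins around the magnitudes typical of
#' each genome class, not taxonomic assignments, and are all configurable.
#'
#' @param contigs A tibble with columns `id` and `seq` (from
#'   [read_contigs()] or [simulate_contigs()]).
#' @inheritParams circularize
#' @inheritParams scan_stemloops
#' @param orf_min_len Minimum ORF length (nt, stop included) counted as
#'   evidence.
#' @param pv_size Length window (nt) for `papillomavirus_sized`.
#' @param pv_min_orfs Minimum ORF count for `papillomavirus_sized`.
#' @param cress_size Length window (nt) for `cress_sized`.
#' @param short_max Upper length bound (nt) for the short-circle category.
#' @return A tibble with one row per input contig: `contig_id`, `circular`,
#'   `overlap_len`, `trimmed_len`, `gc`, `n_orfs`, `has_stemloop`,
#'   `nonamer_motif`, `category`, `high_n`.
#' @export
triage <- function(contigs,
                   min_overlap = 10L, max_overlap_frac = 0.5,
                   unique_ends = FALSE, max_period = 2L, min_run = 20L,
                   max_n_frac = 0.05,
                   canonical = "TAGTATTAC", max_mismatch = 1L,
                   min_arm = 5L, max_arm = 20L, max_loop = 15L, window = 40L,
                   orf_min_len = 300L,
                   pv_size = c(6800L, 8500L), pv_min_orfs = 6L,
                   cress_size = c(1200L, 3200L), short_max = 1200L) {
  stopifnot(is.data.frame(contigs), all(c("id", "seq") %in% names(contigs)))
  empty <- tibble(
    contig_id = character(), circular = logical(),
    overlap_len = integer(), trimmed_len = integer(), gc = numeric(),
    n_orfs = integer(), has_stemloop = logical(),
    nonamer_motif = character(), category = character(), high_n = logical()
  )
  if (!nrow(contigs)) return(empty)
  norm <- circularize(
    contigs, min_overlap = min_overlap, max_overlap_frac = max_overlap_frac,
    unique_ends = unique_ends, max_period = max_period, min_run = min_run,
    canonicalize = TRUE, max_n_frac = max_n_frac
  )
  rows <- purrr::map(seq_len(nrow(norm)), function(i) {
    out <- tibble(
      contig_id = norm$id[i], circular = isTRUE(norm$circular[i]),
      overlap_len = norm$overlap_len[i], trimmed_len = norm$length[i],
      gc = norm$gc[i], n_orfs = NA_integer_, has_stemloop = NA,
      nonamer_motif = NA_character_, category = "not_circular",
      high_n = norm$high_n[i]
    )
    if (!isTRUE(norm$circular[i])) return(out)
    circ <- norm$seq[i]
    L <- nchar(circ)
    sl <- scan_stemloops(
      circ, canonical = canonical, max_mismatch = max_mismatch,
      min_arm = min_arm, max_arm = max_arm, max_loop = max_loop,
      window = window, circular = TRUE
    )
    orfs <- find_orfs(circ, min_len = orf_min_len, circular = TRUE)
    out$n_orfs <- nrow(orfs)
    out$has_stemloop <- nrow(sl) > 0
    out$nonamer_motif <- if (nrow(sl)) sl$motif[1] else NA_character_
    out$category <- if (L >= pv_size[1] && L <= pv_size[2] &&
                        nrow(orfs) >= pv_min_orfs) {
      "papillomavirus_sized"
    } else if (nrow(sl) > 0 && L >= cress_size[1] && L <= cress_size[2]) {
      "cress_sized"
    } else if (nrow(sl) > 0 && L < short_max) {
      "short_circular_defective_or_multicomponent"
    } else {
      "circular_unclassified"
    }
    out
  })
  bind_rows(rows)
}
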