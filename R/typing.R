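# Sliding-window identity along a multiple alignment, and the
# papillomavirus L1 type/subtype/variant demarcation decision.

#' Sliding-window identity along a multiple alignment
#'
#' For each window position (0, `step`, `2*step`, ...) the identity is the
#' percentage of window columns at which *all* rows agree; a gap character
#' counts as an ordinary character, so a column where one row is gapped and
#' another is not disagrees. The final partial window is reported with its
#' actual width.
#'
#' @param msa A tibble with columns `id` and `seq` (gapped, equal lengths;
#'   e.g. from [read_msa()]) or a character vector of at least two rows.
#' @param window Window width in alignment columns (default 400).
#' @param step Step between window starts in columns (default 50).
#' @return A tibble with columns `window_start` (0-based), `width` and
#'   `identity_pct`.
#' @export
sliding_window_identity <- function(msa, window = 400L, step = 50L) {
  v <- as_named_seqs(msa, "msa")
  if (length(v) < 2L) abort("alignment needs at least two rows")
  len <- unique(nchar(v))
  if (length(len) != 1L) abort("alignment rows have unequal lengths")
  if (len == 0L) abort("empty alignment")
  if (window < 1L || window > len) abort("`window` must be in 1..alignment length")
  if (step < 1L) abort("`step` must be >= 1")
  mat <- do.call(rbind, strsplit(toupper(v), "", fixed = TRUE))
  same <- rep(TRUE, len)
  for (r in seq.int(2L, nrow(mat))) {
    same <- same & (mat[r, ] == mat[1L, ])
  }
  cum <- c(0, cumsum(same))
  starts <- seq.int(0L, len - 1L, by = step)
  width <- pmin(window, len - starts)
  tibble(
    window_start = starts,
    width = as.integer(width),
    identity_pct = 100 * (cum[starts + width + 1L] - cum[starts + 1L]) / width
  )
}

demarcation_category <- function(divergence_pct) {
  dplyr::case_when(
    divergence_pct > 10 ~ "new_type",
    divergence_pct < 2 ~ "variant",
    TRUE ~ "subtype"
  )
}

#' Papillomavirus L1 demarcation call
#'
#' Aligns a query L1 nucleotide sequence to every reference L1, takes the
#' reference of maximum identity, and applies the standard papillomavirus
#' demarcation rule on the divergence `d = 100 - identity_pct`: a new
#' *type* if `d > 10`, a new *subtype* if `2 <= d <= 10`, and a *variant*
#' if `d < 2`. The thresholds apply to the L1 gene; the function does not
#' verify that its inputs are L1 sequences — that is the caller's
#' responsibility.
#'
#' @param query A single L1 nucleotide sequence.
#' @param refs Reference L1 sequences: a tibble with `id`/`seq` columns or
#'   a named character vector (non-empty).
#' @param query_id Identifier for the query.
#' @param ... Passed to [global_align()] (scoring parameters).
#' @return A `demarcation_call` object. [glance()] returns the one-row
#'   decision (`query_id`, `closest_ref_id`, `identity_pct`,
#'   `divergence_pct`, `category`); [tidy()] returns the per-reference
#'   identity table.
#' @export
classify_papillomavirus <- function(query, refs, query_id = "query", ...) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    abort("`query` must be a single non-empty sequence")
  }
  rv <- as_named_seqs(refs, "refs")
  if (!length(rv)) abort("`refs` must be non-empty")
  per_ref <- purrr::map(seq_along(rv), function(i) {
    al <- global_align(query, rv[[i]], a_id = query_id, b_id = names(rv)[i],
                       alphabet = "dna", ...)
    tibble(
      ref_id = names(rv)[i],
      identity_pct = al$identity_pct,
      divergence_pct = 100 - al$identity_pct,
      score = al$score
    )
  })
  per_ref <- bind_rows(per_ref)
  best <- per_ref[which.max(per_ref$identity_pct), ] # first at ties
  call <- tibble(
    query_id = query_id,
    closest_ref_id = best$ref_id,
    identity_pct = best$identity_pct,
    divergence_pct = best$divergence_pct,
    category = demarcation_category(best$divergence_pct)
  )
  structure(list(call = call, per_ref = per_ref), class = "demarcation_call")
}

#' @exportS3Method generics::glance
glance.demarcation_call <- function(x, ...) x$call

#' @exportS3Method generics::tidy
tidy.demarcation_call <- function(x, ...) x$per_ref

#' @export
print.demarcation_call <- function(x, ...) {
  cat(sprintf(
    "<demarcation_call> %s: closest reference %s, identity %.2f%% (divergence %.2f%%) -> %s\n",
    x$call$query_id, x$call$closest_ref_id, x$call$identity_pct,
    x$call$divergence_pct, x$call$category
  ))
  invisible(x)
}
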