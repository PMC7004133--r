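#' Filter structural variants by size
#'
#' Keeps variants with `min_size <= size <= max_size` (defaults 20 bp and
#' 25 kb, the standard contig-alignment variant window).
#'
#' @param records SV tibble with a `size` column (bp).
#' @param min_size,max_size Inclusive size bounds.
#' @return The retained records.
#' @export
filter_sv <- function(records, min_size = 20L, max_size = 25000L) {
  stopifnot(all(records$size >= 0))
  records |> filter(.data$size >= min_size, .data$size <= max_size)
}

# Fraction of [start, end] covered by the union of TE intervals on the same
# sequence (merged footprint: no double counting).
te_span_coverage <- function(sequence_id, start, end, te) {
  te <- te[te$sequence_id == sequence_id, , drop = FALSE]
  if (nrow(te) == 0L) return(0)
  q <- IRanges::IRanges(start, end)
  s <- IRanges::reduce(IRanges::IRanges(te$start, te$end))
  ov <- IRanges::intersect(s, q)
  sum(IRanges::width(ov)) / IRanges::width(q)
}

#' Flag TE-associated structural variants
#'
#' A variant is TE-associated when at least 50% of its span is covered by the
#' merged TE footprint of the relevant genome: insertions and repeat/tandem
#' expansions are tested against genome A's annotation over their A-side
#' span (`ref_*` columns), deletions and repeat/tandem contractions against
#' genome B's annotation over their B-side span (`alt_*` columns). Variants
#' of unrecognised type pass through with `te_associated = NA`.
#'
#' @param records SV tibble: `variant_id`, `type`, `ref_sequence_id`,
#'   `ref_start`, `ref_end`, `alt_sequence_id`, `alt_start`, `alt_end`,
#'   `size`.
#' @param te_a,te_b TE annotations (`sequence_id`, `start`, `end`) of genomes
#'   A and B.
#' @param min_span_fraction Coverage threshold (default 0.5, inclusive).
#' @return `records` with `te_coverage` and `te_associated` columns.
#' @export
sv_te_associate <- function(records, te_a, te_b, min_span_fraction = 0.5) {
  a_types <- c("insertion", "repeat_expansion", "tandem_expansion")
  b_types <- c("deletion", "repeat_contraction", "tandem_contraction")
  cov <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    ty <- records$type[i]
    if (ty %in% a_types) {
      sid <- records$ref_sequence_id[i]
      if (is.na(sid)) {
        abort("variant with missing sequence id", class = "ltrdyn_input_error")
      }
      cov[i] <- te_span_coverage(sid, records$ref_start[i], records$ref_end[i], te_a)
    } else if (ty %in% b_types) {
      cov[i] <- te_span_coverage(records$alt_sequence_id[i],
                                 records$alt_start[i], records$alt_end[i], te_b)
    }
  }
  records |>
    mutate(te_coverage = cov,
           te_associated = if_else(is.na(cov), NA,
                                   cov >= min_span_fraction))
}

#' Summary of TE association by variant type
#'
#' @param records Output of [sv_te_associate()].
#' @return Tibble per `type`: variant count, total Mb, TE-associated count
#'   and percentage.
#' @export
sv_te_summary <- function(records) {
  records |>
    group_by(.data$type) |>
    summarise(n = n(),
              total_mb = sum(.data$size) / 1e6,
              n_te_associated = sum(.data$te_associated, na.rm = TRUE),
              pct_te_associated = 100 * mean(.data$te_associated, na.rm = TRUE),
              .groups = "drop")
}
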