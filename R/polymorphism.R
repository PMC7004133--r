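#' Filter cohort deletion calls
#'
#' Keeps calls with at least `min_support` supporting reads in their cultivar
#' and no overlap with any assembly-gap (`N`) region expanded by `pad` bp on
#' each side.
#'
#' @param calls Deletion-call tibble: `cultivar_id`, `sequence_id`, `start`,
#'   `end`, `support_reads` (1-based inclusive spans).
#' @param n_regions Tibble of N-regions: `sequence_id`, `start`, `end`.
#' @param min_support Minimum supporting reads per cultivar (default 20).
#' @param pad N-region padding in bp (default 1000).
#' @return The retained calls.
#' @export
filter_deletions <- function(calls, n_regions, min_support = 20L, pad = 1000L) {
  calls <- calls |> filter(.data$support_reads >= min_support)
  if (nrow(calls) == 0L || is.null(n_regions) || nrow(n_regions) == 0L) return(calls)
  bad <- logical(nrow(calls))
  for (sid in unique(calls$sequence_id)) {
    ci <- which(calls$sequence_id == sid)
    nr <- n_regions |> filter(.data$sequence_id == sid)
    if (nrow(nr) == 0L) next
    q <- IRanges::IRanges(calls$start[ci], calls$end[ci])
    s <- IRanges::IRanges(pmax(1L, nr$start - pad), nr$end + pad)
    bad[ci] <- IRanges::overlapsAny(q, s)
  }
  calls[!bad, ]
}

#' One-way 80% overlap between a deletion and a TE
#'
#' A deletion and a TE overlap (in the polymorphism sense) when at least 80%
#' of at least one of the two intervals is covered by the other. Vectorised
#' over its arguments; spans are 1-based inclusive and must share a sequence.
#'
#' @param del_start,del_end Deletion span(s).
#' @param te_start,te_end TE span(s).
#' @param min_fraction One-way overlap fraction (default 0.8, inclusive).
#' @return Logical vector.
#' @export
deletion_te_overlap <- function(del_start, del_end, te_start, te_end,
                                min_fraction = 0.8) {
  ov <- pmax(0L, pmin(del_end, te_end) - pmax(del_start, te_start) + 1L)
  len_del <- del_end - del_start + 1L
  len_te <- te_end - te_start + 1L
  ov >= min_fraction * len_del | ov >= min_fraction * len_te
}

#' Classify reference insertions as fixed or polymorphic in a cohort
#'
#' An insertion is polymorphic iff at least one cultivar carries a filtered
#' deletion call overlapping it under the one-way 80% rule; the cultivars
#' with such evidence are listed in `absent_in`. Presence is inferred only
#' from the absence of a deletion call.
#'
#' @param insertions Element tibble (`element_id`, `sequence_id`, `start`,
#'   `end`).
#' @param filtered_calls Calls surviving [filter_deletions()] (must carry
#'   `call_id`).
#' @param cohort Character vector of cultivar ids (must be non-empty).
#' @return Tibble: `element_id`, `status` (`fixed`/`polymorphic`),
#'   `n_absent`, plus list-columns `absent_in` and `evidence` (call ids).
#' @export
classify_fixed_polymorphic <- function(insertions, filtered_calls, cohort) {
  if (length(cohort) == 0L) {
    abort("cohort must contain at least one cultivar", class = "ltrdyn_input_error")
  }
  calls <- filtered_calls |> filter(.data$cultivar_id %in% cohort)
  rows <- map(seq_len(nrow(insertions)), function(i) {
    el <- insertions[i, ]
    cand <- calls |> filter(.data$sequence_id == el$sequence_id)
    hit <- cand |>
      filter(deletion_te_overlap(.data$start, .data$end, el$start, el$end))
    absent <- sort(unique(hit$cultivar_id))
    tibble(element_id = el$element_id,
           status = if (length(absent) > 0L) "polymorphic" else "fixed",
           n_absent = length(absent),
           absent_in = list(absent),
           evidence = list(hit$call_id))
  })
  list_rbind(rows)
}

#' Deletion size-class and TE-overlap summary
#'
#' Deduplicates calls to unique events (identical `sequence_id`/`start`/`end`
#' across cultivars, optionally merged within `merge_slop` bp), bins them
#' into the size classes 1-50, 51-500, 501-10000 and 10001-50000 bp, and
#' reports per class the unique-event count and the count and percentage of
#' events overlapping a TE under the one-way 80% rule. Events above 50 kb
#' are reported in a separate `>50000` row.
#'
#' @param filtered_calls Filtered deletion calls.
#' @param te_annotation TE span tibble (`sequence_id`, `start`, `end`).
#' @param merge_slop Coordinate tolerance when deduplicating events
#'   (default 0: exact span identity).
#' @return List with `size_classes` (per-class tibble) and `per_cultivar`
#'   (call counts per cultivar).
#' @export
size_class_summary <- function(filtered_calls, te_annotation, merge_slop = 0L) {
  breaks <- c(1L, 51L, 501L, 10001L, 50001L)
  labels <- c("1-50", "51-500", "501-10000", "10001-50000")
  events <- filtered_calls |> distinct(.data$sequence_id, .data$start, .data$end)
  if (merge_slop > 0L && nrow(events) > 1L) {
    events <- events |>
      arrange(.data$sequence_id, .data$start, .data$end) |>
      group_by(.data$sequence_id) |>
      mutate(new_grp = c(TRUE, diff(.data$start) > merge_slop |
                           abs(diff(.data$end)) > merge_slop),
             grp = cumsum(.data$new_grp)) |>
      group_by(.data$sequence_id, .data$grp) |>
      summarise(start = .data$start[1], end = .data$end[1], .groups = "drop") |>
      select(-"grp")
  }
  events <- events |>
    mutate(length = .data$end - .data$start + 1L,
           size_class = as.character(cut(.data$length, c(breaks - 1L, Inf),
                                         labels = c(labels, ">50000"))),
           te_overlap = map_lgl(row_number(), function(i) {
             te <- te_annotation |>
               filter(.data$sequence_id == events$sequence_id[i])
             any(deletion_te_overlap(events$start[i], events$end[i],
                                     te$start, te$end))
           }))
  size_classes <- tibble(size_class = c(labels, ">50000")) |>
    left_join(events |>
                group_by(.data$size_class) |>
                summarise(n_events = n(), n_te_overlap = sum(.data$te_overlap),
                          .groups = "drop"),
              by = "size_class") |>
    mutate(n_events = coalesce(.data$n_events, 0L),
           n_te_overlap = coalesce(.data$n_te_overlap, 0L),
           pct_te_overlap = if_else(.data$n_events > 0,
                                    100 * .data$n_te_overlap / .data$n_events,
                                    NA_real_))
  per_cultivar <- filtered_calls |> count(.data$cultivar_id, name = "n_calls")
  list(size_classes = size_classes, per_cultivar = per_cultivar,
       n_unique_events = nrow(events))
}
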