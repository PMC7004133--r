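#' Insertion-dating configuration
#'
#' The two LTRs of an element are identical at insertion and each accumulates
#' substitutions independently afterwards, so their K2P distance K estimates
#' `2 r T` and the insertion age is `T = K / (2 r)`. The rate is per year, so
#' the generation time is carried as metadata only and does not enter the
#' formula.
#'
#' @param substitution_rate Substitutions per site per year (default 1e-8).
#' @param generation_time Years per generation (default 10; metadata).
#' @param bin_width Histogram bin width in Mya.
#' @param min_compared_sites Minimum gap-free columns for a usable estimate;
#'   below this the K2P sampling noise (about `1/sqrt(n)`) drowns the signal.
#' @return A list of class `dating_config`.
#' @export
dating_config <- function(substitution_rate = 1e-8, generation_time = 10,
                          bin_width = 1.0, min_compared_sites = 50L) {
  stopifnot(substitution_rate > 0)
  structure(list(substitution_rate = substitution_rate,
                 generation_time = generation_time,
                 bin_width = bin_width,
                 min_compared_sites = as.integer(min_compared_sites)),
            class = "dating_config")
}

#' Date LTR elements from the divergence of their two LTRs
#'
#' For each element the 5' and 3' LTR sequences are extracted, globally
#' aligned, and their Kimura two-parameter distance converted to an insertion
#' age `T = K / (2 r)`. Elements whose alignment is K2P-saturated are flagged
#' `saturated`; those with fewer usable columns than
#' `cfg$min_compared_sites` are flagged `too_short`; neither receives an age.
#'
#' @param elements Element tibble with `ltr5_start/ltr5_end/ltr3_start/
#'   ltr3_end` and `sequence_id` columns.
#' @param genome Genome the elements live on.
#' @param cfg A [dating_config()].
#' @param params Alignment parameters for the LTR pair.
#' @return Tibble: `element_id`, `P`, `Q`, `K`, `compared_sites`, `age_mya`,
#'   `status` (`dated`, `saturated`, `too_short`).
#' @export
date_elements <- function(elements, genome, cfg = dating_config(),
                          params = align_params()) {
  genome <- as_genome(genome)
  rows <- map(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    ltr5 <- extract_seq(genome, el$sequence_id, el$ltr5_start, el$ltr5_end)
    ltr3 <- extract_seq(genome, el$sequence_id, el$ltr3_start, el$ltr3_end)
    aln <- align_global(ltr5, ltr3, params = params)
    res <- tryCatch(k2p_distance(aln), ltrdyn_saturation_error = function(e) "saturated",
                    ltrdyn_input_error = function(e) "too_short")
    if (is.character(res)) {
      return(tibble(element_id = el$element_id, P = NA_real_, Q = NA_real_,
                    K = NA_real_, compared_sites = NA_integer_,
                    age_mya = NA_real_, status = res))
    }
    status <- if (res$compared_sites < cfg$min_compared_sites) "too_short" else "dated"
    tibble(element_id = el$element_id, P = res$P, Q = res$Q, K = res$K,
           compared_sites = res$compared_sites,
           age_mya = if (status == "dated")
             res$K / (2 * cfg$substitution_rate) / 1e6 else NA_real_,
           status = status)
  })
  list_rbind(rows)
}

#' Histogram of insertion ages
#'
#' Bins dated ages into `[i b, (i+1) b)` Mya bins and reports, as attributes
#' `recent_count` and `recent_fraction`, the number and fraction of dated
#' elements at most `recent_mya` (default 5) million years old.
#'
#' @param ages Tibble from [date_elements()] (rows with `status != "dated"`
#'   are ignored).
#' @param bin_width Bin width in Mya.
#' @param recent_mya Cutoff defining "recent" insertions.
#' @return Tibble `bin_start`, `bin_end`, `count`, `fraction`; empty for no
#'   dated input.
#' @export
age_histogram <- function(ages, bin_width = 1.0, recent_mya = 5) {
  a <- ages |> filter(.data$status == "dated") |> pull("age_mya")
  if (length(a) == 0L) {
    out <- tibble(bin_start = numeric(0), bin_end = numeric(0),
                  count = integer(0), fraction = numeric(0))
    attr(out, "recent_count") <- 0L
    attr(out, "recent_fraction") <- NA_real_
    return(out)
  }
  idx <- floor(a / bin_width)
  tab <- table(idx)
  out <- tibble(bin_start = as.numeric(names(tab)) * bin_width,
                count = as.integer(tab)) |>
    mutate(bin_end = .data$bin_start + bin_width,
           fraction = .data$count / length(a)) |>
    select("bin_start", "bin_end", "count", "fraction") |>
    arrange(.data$bin_start)
  attr(out, "recent_count") <- sum(a <= recent_mya)
  attr(out, "recent_fraction") <- mean(a <= recent_mya)
  out
}
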