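#' Orthologous-locus search parameters
#'
#' @param flank_len Flank length extracted on each side of an element (bp).
#' @param max_locus_distance Maximum inner-edge distance between the two
#'   mapped flanks for a concordant locus (bp).
#' @param min_identity,min_coverage Orthology thresholds for the element vs
#'   inter-flank alignment (the 80/80 rule).
#' @param empty_site_max Maximum inter-flank span still read as an empty
#'   site (element absent); an empty orthologous site should span little more
#'   than the target-site duplication, with slack for small indels.
#' @param ambiguity_ratio Best flank hit must score at least this factor
#'   above the second best to count as unambiguous.
#' @param flank_min_identity,flank_min_coverage Per-flank hit thresholds.
#' @param max_flank_hits Flanks with more hits than this are considered
#'   repeat-dense and the element is reported unmapped rather than forced.
#' @param map Flank-mapping parameters ([map_params()]).
#' @return A list of class `ortho_params`.
#' @export
ortho_params <- function(flank_len = 500L, max_locus_distance = 25000L,
                         min_identity = 0.8, min_coverage = 0.8,
                         empty_site_max = 100L, ambiguity_ratio = 1.2,
                         flank_min_identity = 0.75, flank_min_coverage = 0.5,
                         max_flank_hits = 5L, map = map_params()) {
  structure(list(flank_len = as.integer(flank_len),
                 max_locus_distance = as.integer(max_locus_distance),
                 min_identity = min_identity, min_coverage = min_coverage,
                 empty_site_max = as.integer(empty_site_max),
                 ambiguity_ratio = ambiguity_ratio,
                 flank_min_identity = flank_min_identity,
                 flank_min_coverage = flank_min_coverage,
                 max_flank_hits = as.integer(max_flank_hits),
                 map = map),
            class = "ortho_params")
}

#' Extract the flanking sequences of an element
#'
#' Returns up to `flank_len` bases on each side of the element span,
#' truncated at sequence ends (with a truncation flag). An element flush
#' against both ends of its sequence has no flanks and raises an error.
#'
#' @param element One-row element tibble (`sequence_id`, `start`, `end`).
#' @param genome Genome the element lives on.
#' @param flank_len Flank length (bp).
#' @return List `left`, `right` (character; possibly empty strings),
#'   `left_truncated`, `right_truncated`.
#' @export
extract_flanks <- function(element, genome, flank_len = 500L) {
  genome <- as_genome(genome)
  stopifnot(nrow(element) == 1L)
  len <- length(genome[[element$sequence_id]])
  ls <- max(1L, element$start - flank_len)
  le <- element$start - 1L
  rs <- element$end + 1L
  re <- min(len, element$end + flank_len)
  left <- if (le >= ls) extract_seq(genome, element$sequence_id, ls, le) else ""
  right <- if (re >= rs) extract_seq(genome, element$sequence_id, rs, re) else ""
  if (nchar(left) == 0L && nchar(right) == 0L) {
    abort("element spans its entire sequence: no flanks available",
          class = "ltrdyn_flank_error")
  }
  list(left = left, right = right,
       left_truncated = nchar(left) < flank_len,
       right_truncated = nchar(right) < flank_len)
}

# Pick the unambiguous best hit of one flank, or explain why there is none.
# Returns list(status = "ok"|"unmapped"|"ambiguous", hit = tibble row or NULL)
best_unambiguous_hit <- function(hits, params) {
  hits <- hits |> filter(.data$identity >= params$flank_min_identity,
                         .data$coverage >= params$flank_min_coverage)
  if (nrow(hits) == 0L) return(list(status = "unmapped", hit = NULL))
  if (nrow(hits) > params$max_flank_hits) return(list(status = "ambiguous", hit = NULL))
  if (nrow(hits) >= 2L &&
      hits$score[1] < params$ambiguity_ratio * hits$score[2]) {
    return(list(status = "ambiguous", hit = NULL))
  }
  list(status = "ok", hit = hits[1L, ])
}

#' Locate the orthologous locus of an element in another genome
#'
#' Maps the two flanks onto the other genome. The locus is `concordant` when
#' both flanks map unambiguously to the same sequence and strand, in
#' preserved left/right order after strand normalisation, with an inner-edge
#' distance below `params$max_locus_distance`; otherwise `discordant` (both
#' flanks mapped but the geometry fails) or `unmapped` (a flank has no
#' unambiguous hit or is repeat-dense).
#'
#' @param left,right Flank sequences (from [extract_flanks()]).
#' @param other_genome The genome searched, or a prebuilt
#'   `genome_kmer_index` of it.
#' @param params An [ortho_params()].
#' @return List: `locus_status`, and for concordant loci
#'   `target_sequence_id`, `target_start`, `target_end` (the inter-flank
#'   interval, width possibly 0), `strand`.
#' @export
find_ortholog_locus <- function(left, right, other_genome, params = ortho_params()) {
  if (nchar(left) < params$map$k || nchar(right) < params$map$k) {
    return(list(locus_status = "unmapped"))
  }
  lh <- best_unambiguous_hit(map_flank(left, other_genome, params$map), params)
  rh <- best_unambiguous_hit(map_flank(right, other_genome, params$map), params)
  if (lh$status != "ok" || rh$status != "ok") {
    return(list(locus_status = "unmapped"))
  }
  L <- lh$hit; R <- rh$hit
  if (L$target_sequence_id != R$target_sequence_id || L$strand != R$strand) {
    return(list(locus_status = "discordant"))
  }
  if (L$strand == "+") {
    inner <- R$start - L$end - 1L
    ts <- L$end + 1L; te <- R$start - 1L
  } else {
    # on the minus strand the left flank lies downstream in target coordinates
    inner <- L$start - R$end - 1L
    ts <- R$end + 1L; te <- L$start - 1L
  }
  if (inner >= params$max_locus_distance) return(list(locus_status = "discordant"))
  if (inner < -2L * params$flank_len) return(list(locus_status = "discordant"))
  list(locus_status = "concordant",
       target_sequence_id = L$target_sequence_id,
       target_start = ts, target_end = te, strand = L$strand)
}

#' Classify one insertion against its orthologous locus
#'
#' For a concordant locus, the target inter-flank region is globally aligned
#' to the element sequence: identity and coverage at or above the 80/80
#' thresholds give `conserved`; otherwise an inter-flank span at most
#' `empty_site_max` bp reads as an empty site (`specific`), and anything
#' longer that fails the alignment is `partially_deleted_or_rearranged`.
#' Non-concordant loci are `unresolved`.
#'
#' @param element One-row element tibble.
#' @param locus Result of [find_ortholog_locus()].
#' @param genome Genome of the element.
#' @param other_genome The other genome.
#' @param params An [ortho_params()].
#' @return One-row tibble: `element_id`, `locus_status`, `category`,
#'   `target_sequence_id`, `target_start`, `target_end`,
#'   `internal_identity`, `internal_coverage`.
#' @export
classify_insertion <- function(element, locus, genome, other_genome,
                               params = ortho_params()) {
  base <- tibble(element_id = element$element_id,
                 locus_status = locus$locus_status,
                 category = "unresolved",
                 target_sequence_id = NA_character_,
                 target_start = NA_integer_, target_end = NA_integer_,
                 internal_identity = NA_real_, internal_coverage = NA_real_)
  if (locus$locus_status != "concordant") return(base)
  base$target_sequence_id <- locus$target_sequence_id
  width <- locus$target_end - locus$target_start + 1L
  base$target_start <- locus$target_start
  base$target_end <- locus$target_end
  if (width <= params$empty_site_max) {
    base$category <- "specific"
    return(base)
  }
  og <- if (inherits(other_genome, "genome_kmer_index")) other_genome$genome else as_genome(other_genome)
  target_seq <- extract_seq(og, locus$target_sequence_id,
                            locus$target_start, locus$target_end)
  if (locus$strand == "-") target_seq <- reverse_complement(target_seq)
  el_seq <- extract_seq(genome, element$sequence_id, element$start, element$end)
  aln <- align_global(el_seq, target_seq)
  ic <- identity_coverage(aln)
  base$internal_identity <- ic[["identity"]]
  base$internal_coverage <- ic[["coverage"]]
  if (ic[["identity"]] >= params$min_identity && ic[["coverage"]] >= params$min_coverage) {
    base$category <- "conserved"
  } else {
    base$category <- "partially_deleted_or_rearranged"
  }
  base
}

#' Classify every insertion of one genome against the other
#'
#' Drives [extract_flanks()], [find_ortholog_locus()] and
#' [classify_insertion()] over an element table, reusing one k-mer index of
#' the target genome.
#'
#' @param elements Element tibble on `genome`.
#' @param genome,other_genome The two genomes.
#' @param params An [ortho_params()].
#' @return Tibble with one [classify_insertion()] row per element.
#' @export
classify_orthologs <- function(elements, genome, other_genome,
                               params = ortho_params()) {
  genome <- as_genome(genome)
  idx <- if (inherits(other_genome, "genome_kmer_index")) other_genome
         else genome_kmer_index(as_genome(other_genome), k = params$map$k)
  rows <- map(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    fl <- tryCatch(extract_flanks(el, genome, params$flank_len),
                   ltrdyn_flank_error = function(e) NULL)
    if (is.null(fl)) {
      return(tibble(element_id = el$element_id, locus_status = "unmapped",
                    category = "unresolved", target_sequence_id = NA_character_,
                    target_start = NA_integer_, target_end = NA_integer_,
                    internal_identity = NA_real_, internal_coverage = NA_real_))
    }
    locus <- find_ortholog_locus(fl$left, fl$right, idx, params)
    classify_insertion(el, locus, genome, idx, params)
  })
  list_rbind(rows)
}

#' Age structure of orthology categories
#'
#' Joins orthology calls with insertion ages and summarises each category
#' against the speciation time: element count, dated count, median age, and
#' fractions younger/older than `speciation_mya` (absent when a category has
#' no dated member). Specific insertions are expected younger than the
#' split and conserved ones older.
#'
#' @param calls Orthology calls ([classify_orthologs()]).
#' @param ages Ages tibble ([date_elements()]).
#' @param speciation_mya Species split time (default 5.88 Mya).
#' @return A list of class `ortho_report` with `by_category` and the joined
#'   per-element table `detail`.
#' @export
age_by_category <- function(calls, ages, speciation_mya = 5.88) {
  detail <- calls |>
    left_join(ages |> select("element_id", "age_mya", status_dating = "status"),
              by = "element_id")
  by_cat <- detail |>
    group_by(category = .data$category) |>
    summarise(n = n(),
              n_dated = sum(!is.na(.data$age_mya)),
              median_age_mya = stats::median(.data$age_mya, na.rm = TRUE),
              fraction_younger = if (sum(!is.na(.data$age_mya)) > 0)
                mean(.data$age_mya[!is.na(.data$age_mya)] < speciation_mya)
              else NA_real_,
              fraction_older = if (sum(!is.na(.data$age_mya)) > 0)
                mean(.data$age_mya[!is.na(.data$age_mya)] >= speciation_mya)
              else NA_real_,
              .groups = "drop")
  structure(list(by_category = by_cat, detail = detail,
                 speciation_mya = speciation_mya),
            class = "ortho_report")
}

#' @export
print.ortho_report <- function(x, ...) {
  cat("<ortho_report> speciation", x$speciation_mya, "Mya\n")
  print(x$by_category)
  invisible(x)
}

#' Per-category summary of an orthology report
#' @param x An `ortho_report`.
#' @param ... Unused.
#' @export
tidy.ortho_report <- function(x, ...) x$by_category

#' One-row summary of an orthology report
#' @param x An `ortho_report`.
#' @param ... Unused.
#' @export
glance.ortho_report <- function(x, ...) {
  d <- x$detail
  tibble(n_elements = nrow(d),
         n_concordant = sum(d$locus_status == "concordant"),
         n_conserved = sum(d$category == "conserved"),
         n_specific = sum(d$category == "specific"),
         n_partial = sum(d$category == "partially_deleted_or_rearranged"),
         n_unresolved = sum(d$category == "unresolved"),
         speciation_mya = x$speciation_mya)
}
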