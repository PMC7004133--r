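#' Parameters for structural LTR candidate detection
#'
#' Defaults mirror the spirit of classical structural detectors: terminal
#' repeats of 100-3000 bp at >= 85% identity bounding an element of 1-15 kb.
#'
#' @param k Seed length for the k-mer self-match scan.
#' @param min_ltr,max_ltr Allowed LTR length range (bp).
#' @param min_element,max_element Allowed element length range (bp).
#' @param min_ltr_identity Minimum identity between the two terminal repeats.
#' @param min_seed_pairs Minimum self-matching seed pairs per candidate.
#' @param pad Window padding around the seeded repeat before refinement.
#' @param tsd_length Target-site duplication length checked around candidates.
#' @param max_kmer_occurrences Seed k-mers occurring more often than this in
#'   the sequence are skipped (guards against repeat-driven blowup; raise it
#'   for genomes carrying very high-copy young families).
#' @param require_tsd Require target-site-duplication evidence (an exact
#'   `tsd_length`-mer repeated at the candidate boundaries, allowing a few bp
#'   of boundary fuzz) for a candidate to be reported; LTR insertions create
#'   a TSD, and requiring it suppresses spurious pairings between the
#'   repeats of neighbouring copies.
#' @return A list of class `ltr_detect_params`.
#' @export
ltr_detect_params <- function(k = 13L, min_ltr = 100L, max_ltr = 3000L,
                              min_element = 1000L, max_element = 15000L,
                              min_ltr_identity = 0.85, min_seed_pairs = 4L,
                              pad = 100L, tsd_length = 5L,
                              max_kmer_occurrences = 40L,
                              require_tsd = TRUE) {
  structure(list(k = as.integer(k), min_ltr = as.integer(min_ltr),
                 max_ltr = as.integer(max_ltr),
                 min_element = as.integer(min_element),
                 max_element = as.integer(max_element),
                 min_ltr_identity = min_ltr_identity,
                 min_seed_pairs = as.integer(min_seed_pairs),
                 pad = as.integer(pad), tsd_length = as.integer(tsd_length),
                 max_kmer_occurrences = as.integer(max_kmer_occurrences),
                 require_tsd = isTRUE(require_tsd)),
            class = "ltr_detect_params")
}

empty_elements_tbl <- function() {
  tibble(element_id = character(0), sequence_id = character(0),
         start = integer(0), end = integer(0),
         ltr5_start = integer(0), ltr5_end = integer(0),
         internal_start = integer(0), internal_end = integer(0),
         ltr3_start = integer(0), ltr3_end = integer(0),
         ltr_identity = numeric(0), tsd = character(0),
         seed_pairs = integer(0))
}

#' Detect candidate LTR retrotransposons by terminal-repeat structure
#'
#' A simplified structural detector: exact k-mer self-matches at a spacing
#' compatible with the configured LTR/element length ranges seed candidate
#' repeat pairs, which are refined by local alignment of the two repeat
#' windows. Candidates are ranked by target-site-duplication evidence and
#' alignment score and greedily accepted without overlap, which suppresses
#' spurious pairings between the repeats of neighbouring same-family copies.
#' Exact parity with any particular published detector is not claimed.
#'
#' @param genome Genome ([as_genome()] forms).
#' @param params An [ltr_detect_params()] object.
#' @return Tibble of candidate elements with 1-based inclusive spans:
#'   `element_id`, `sequence_id`, `start`, `end`, `ltr5_*`, `internal_*`,
#'   `ltr3_*`, `ltr_identity`, `tsd` (the duplicated target-site sequence,
#'   `NA` when none was found), `seed_pairs`.
#' @export
detect_ltr_candidates <- function(genome, params = ltr_detect_params()) {
  genome <- as_genome(genome)
  out <- list()
  for (sid in names(genome)) {
    seq_chr <- as.character(genome[[sid]])
    v <- dna_to_int(seq_chr)
    cand <- ltr_candidates_one(v, seq_chr, sid, params)
    if (nrow(cand) > 0L) out[[length(out) + 1L]] <- cand
  }
  if (length(out) == 0L) return(empty_elements_tbl())
  res <- bind_rows(out)
  res$element_id <- sprintf("LTRcand%04d", seq_len(nrow(res)))
  res |> select(all_of(names(empty_elements_tbl())))
}

ltr_candidates_one <- function(v, seq_chr, sid, params) {
  n <- length(v)
  if (n < params$min_element) return(empty_elements_tbl())
  kt <- kmer_table(v, k = params$k)
  if (length(kt$code) == 0L) return(empty_elements_tbl())
  # pairs of identical k-mers at LTR-compatible spacing
  o <- order(kt$code)
  code <- kt$code[o]; pos <- kt$pos[o]
  runs <- rle(code)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  multi <- which(runs$lengths >= 2L & runs$lengths <= params$max_kmer_occurrences)
  d_min <- max(params$min_element - params$max_ltr, params$min_ltr)
  d_max <- params$max_element - params$min_ltr
  p1 <- integer(0); p2 <- integer(0)
  for (ri in multi) {
    ps <- sort(pos[starts[ri]:ends[ri]])
    cmb <- utils::combn(ps, 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    ok <- d >= d_min & d <= d_max
    p1 <- c(p1, cmb[1L, ok]); p2 <- c(p2, cmb[2L, ok])
  }
  if (length(p1) == 0L) return(empty_elements_tbl())
  pairs <- tibble(p1 = p1, d = p2 - p1) |> arrange(.data$d, .data$p1)
  # a group must stay within one terminal repeat: same diagonal (d) and
  # seeds no further apart than a plausible within-LTR gap
  brk <- c(TRUE, diff(pairs$d) > 30L | abs(diff(pairs$p1)) > 400L)
  pairs$grp <- cumsum(brk)
  grps <- pairs |>
    group_by(.data$grp) |>
    summarise(n_seeds = n(), p1_min = min(.data$p1), p1_max = max(.data$p1),
              d = .data$d[1], .groups = "drop") |>
    filter(.data$n_seeds >= params$min_seed_pairs,
           .data$p1_max - .data$p1_min <= params$max_ltr)
  if (nrow(grps) == 0L) return(empty_elements_tbl())

  cands <- list()
  for (gi in seq_len(nrow(grps))) {
    g <- grps[gi, ]
    w5s <- max(1L, g$p1_min - params$pad)
    w5e <- min(n, g$p1_max + params$k - 1L + params$pad)
    w3s <- max(1L, g$p1_min + g$d - params$pad)
    w3e <- min(n, g$p1_max + g$d + params$k - 1L + params$pad)
    if (w5e - w5s + 1L < params$k || w3e - w3s + 1L < params$k) next
    win5 <- substr(seq_chr, w5s, w5e)
    win3 <- substr(seq_chr, w3s, w3e)
    ap <- align_params()
    pa <- Biostrings::pairwiseAlignment(
      pattern = win5, subject = win3, type = "local",
      substitutionMatrix = submat_acgtn(ap),
      gapOpening = ap$gap_open, gapExtension = ap$gap_extend)
    ltr5_s <- w5s + Biostrings::start(Biostrings::pattern(pa)) - 1L
    ltr5_e <- w5s + Biostrings::end(Biostrings::pattern(pa)) - 1L
    ltr3_s <- w3s + Biostrings::start(Biostrings::subject(pa)) - 1L
    ltr3_e <- w3s + Biostrings::end(Biostrings::subject(pa)) - 1L
    ltr_len5 <- ltr5_e - ltr5_s + 1L
    ltr_len3 <- ltr3_e - ltr3_s + 1L
    if (ltr_len5 < params$min_ltr || ltr_len5 > params$max_ltr) next
    if (ltr_len3 < params$min_ltr || ltr_len3 > params$max_ltr) next
    el_len <- ltr3_e - ltr5_s + 1L
    if (el_len < params$min_element || el_len > params$max_element) next
    if (ltr3_s <= ltr5_e) next
    aq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    at <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    # the local alignment occasionally drifts past the repeat ends on chance
    # matches; trim each end back to a clean core under a stricter score
    m <- aq == at & aq != "-" & at != "-" & aq != "N"
    colsc <- ifelse(m, 1, -3)
    lo <- which.min(c(0, cumsum(colsc)))          # columns trimmed on the left
    hi_rev <- which.min(c(0, cumsum(rev(colsc))))  # and on the right
    trim_l <- lo - 1L
    trim_r <- hi_rev - 1L
    ncol <- length(colsc)
    if (trim_l + trim_r >= ncol) next
    keep <- seq2(trim_l + 1L, ncol - trim_r)
    ltr5_s <- ltr5_s + sum(aq[seq2(1L, trim_l)] != "-")
    ltr3_s <- ltr3_s + sum(at[seq2(1L, trim_l)] != "-")
    ltr5_e <- ltr5_e - sum(aq[seq2(ncol - trim_r + 1L, ncol)] != "-")
    ltr3_e <- ltr3_e - sum(at[seq2(ncol - trim_r + 1L, ncol)] != "-")
    aq <- aq[keep]; at <- at[keep]
    ltr_len5 <- ltr5_e - ltr5_s + 1L
    ltr_len3 <- ltr3_e - ltr3_s + 1L
    if (ltr_len5 < params$min_ltr || ltr_len3 < params$min_ltr) next
    both <- aq != "-" & at != "-" & aq != "N" & at != "N"
    ident <- if (sum(both) == 0L) 0 else sum(aq[both] == at[both]) / sum(both)
    if (ident < params$min_ltr_identity) next
    # target-site duplication evidence: the alignment boundaries carry a few
    # bp of fuzz, so scan joint boundary offsets for an exact TSD match and
    # let a found TSD anchor the element boundaries
    tl <- params$tsd_length
    tsd <- NA_character_
    offs <- expand.grid(ds = -10:10, de = -10:10)
    offs <- offs[order(abs(offs$ds) + abs(offs$de)), ]
    for (oi in seq_len(nrow(offs))) {
      s0 <- ltr5_s + offs$ds[oi]
      e0 <- ltr3_e + offs$de[oi]
      if (s0 <= tl || e0 + tl > n) next
      left <- v[(s0 - tl):(s0 - 1L)]
      right <- v[(e0 + 1L):(e0 + tl)]
      if (!anyNA(c(left, right)) && all(left == right)) {
        tsd <- int_to_dna(left)
        ltr5_s <- s0
        ltr3_e <- e0
        break
      }
    }
    if (params$require_tsd && is.na(tsd)) next
    cands[[length(cands) + 1L]] <- tibble(
      sequence_id = sid, start = ltr5_s, end = ltr3_e,
      ltr5_start = ltr5_s, ltr5_end = ltr5_e,
      internal_start = ltr5_e + 1L, internal_end = ltr3_s - 1L,
      ltr3_start = ltr3_s, ltr3_end = ltr3_e,
      ltr_identity = ident, tsd = tsd, seed_pairs = g$n_seeds,
      aln_score = Biostrings::score(pa))
  }
  if (length(cands) == 0L) return(empty_elements_tbl())
  cands <- bind_rows(cands) |>
    arrange(desc(!is.na(.data$tsd)), desc(.data$ltr_identity), desc(.data$aln_score))
  # greedy non-overlapping acceptance
  accepted <- logical(nrow(cands))
  acc_start <- integer(0); acc_end <- integer(0)
  for (i in seq_len(nrow(cands))) {
    if (length(acc_start) == 0L ||
        all(cands$end[i] < acc_start | cands$start[i] > acc_end)) {
      accepted[i] <- TRUE
      acc_start <- c(acc_start, cands$start[i])
      acc_end <- c(acc_end, cands$end[i])
    }
  }
  cands <- cands[accepted, ] |> arrange(.data$start)
  cands$element_id <- sprintf("tmp%04d", seq_len(nrow(cands)))
  cands |> select(all_of(names(empty_elements_tbl())))
}

# Fraction of positions lying in a perfect tandem run: position i is tandem
# under period p if v[i] == v[i - p] within a run of length >= min_run, for
# any p <= max_period. Dependency-free stand-in for a tandem-repeat finder.
tandem_fraction <- function(x, max_period = 12L, min_run = 24L) {
  v <- if (is.character(x)) dna_to_int(x) else x
  n <- length(v)
  if (n < min_run) return(0)
  marked <- logical(n)
  for (p in seq_len(min(max_period, n - 1L))) {
    eq <- !is.na(v[(p + 1L):n]) & !is.na(v[1L:(n - p)]) & v[(p + 1L):n] == v[1L:(n - p)]
    r <- rle(eq)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    long <- which(r$values & r$lengths >= (min_run - p))
    for (j in long) {
      # mark the whole repeated stretch including the leading period
      marked[(s[j]):(e[j] + p)] <- TRUE
    }
  }
  mean(marked)
}

gap_fraction <- function(x) {
  v <- if (is.character(x)) dna_to_int(x) else x
  mean(is.na(v))
}

# Count 80/80-style genomic loci matching the full element sequence, by
# colinear exact-seed evidence: a locus qualifies when enough seeds agree on
# one diagonal band and the matched query positions span >= 80% of the query.
count_genomic_hits <- function(query, idx, min_span_frac = 0.8, min_seeds = 10L) {
  kt <- kmer_table(query, k = idx$k)
  if (length(kt$code) == 0L) return(0L)
  qlen <- nchar(query)
  total <- 0L
  for (sid in names(idx$index)) {
    hits <- seed_matches(kt$code, kt$pos, idx$index[[sid]])
    if (nrow(hits) == 0L) next
    hits <- cluster_seeds(hits, diag_tol = 200L, gap_tol = qlen)
    loci <- hits |>
      group_by(.data$locus) |>
      summarise(n_seeds = n(),
                span = max(.data$qpos) - min(.data$qpos) + idx$k,
                .groups = "drop") |>
      filter(.data$n_seeds >= min_seeds, .data$span >= min_span_frac * qlen)
    total <- total + nrow(loci)
  }
  total
}

#' Structural and coding filters for candidate LTR elements
#'
#' Applies the retention rules for coding LTR retrotransposons: an element is
#' rejected if it has no internal protein-domain hit (`non_coding`), more
#' than 10% assembly-gap (`N`) content (`gap_fraction`), more than 50% tandem
#' repeats (`tandem_fraction`), or exactly one 80/80 match on its own genome,
#' i.e. itself (`single_hit`). The first failing rule, in that order, is
#' recorded per rejected element.
#'
#' @param elements Element tibble (as from [detect_ltr_candidates()] or a
#'   simulator annotation).
#' @param genome The genome the elements live on.
#' @param domain_hits Tibble of domain hits keyed by `element_id` (columns
#'   `element_id`, `domain`, `start`, `end`, `strand`; element-relative
#'   coordinates).
#' @param max_gap_fraction,max_tandem_fraction,min_genomic_hits Rule
#'   thresholds.
#' @return The input tibble with logical `kept` and character `reject_reason`
#'   (`NA` for kept elements) columns appended.
#' @export
filter_elements <- function(elements, genome, domain_hits,
                            max_gap_fraction = 0.10,
                            max_tandem_fraction = 0.50,
                            min_genomic_hits = 2L) {
  genome <- as_genome(genome)
  unknown <- setdiff(unique(domain_hits$element_id), elements$element_id)
  if (length(unknown) > 0L) {
    abort(paste0("domain hits reference unknown element ids: ",
                 paste(utils::head(unknown, 3), collapse = ", ")),
          class = "ltrdyn_input_error")
  }
  if (nrow(elements) == 0L) {
    return(elements |> mutate(kept = logical(0), reject_reason = character(0)))
  }
  coding <- elements$element_id %in% domain_hits$element_id
  seqs <- map_chr(seq_len(nrow(elements)), function(i) {
    extract_seq(genome, elements$sequence_id[i], elements$start[i], elements$end[i])
  })
  gapf <- map_dbl(seqs, gap_fraction)
  tanf <- map_dbl(seqs, tandem_fraction)
  reason <- rep(NA_character_, nrow(elements))
  reason[!coding] <- "non_coding"
  reason[is.na(reason) & gapf > max_gap_fraction] <- "gap_fraction"
  reason[is.na(reason) & tanf > max_tandem_fraction] <- "tandem_fraction"
  # genomic-copy check only for elements still unrejected (it is the costly one)
  todo <- which(is.na(reason))
  if (length(todo) > 0L) {
    idx <- genome_kmer_index(genome, k = 13L, stride = 3L)
    nhits <- map_int(todo, function(i) count_genomic_hits(seqs[i], idx))
    reason[todo[nhits < min_genomic_hits]] <- "single_hit"
  }
  elements |>
    mutate(gap_fraction = gapf, tandem_fraction = tanf,
           kept = is.na(reason), reject_reason = reason)
}

#' Classify elements into Copia and Gypsy superfamilies by domain order
#'
#' With both an integrase (INT) and a reverse transcriptase (RT) hit present,
#' INT upstream of RT on the coding strand gives Copia and RT upstream of INT
#' gives Gypsy; anything else is unclassified. An element is `complete` iff
#' all five domains GAG, PR, INT, RT, RH are present, otherwise `incomplete`.
#' The element's coding strand is the majority strand of its domain hits;
#' minus-strand hits are mirrored before ordering, so classification is
#' strand-invariant.
#'
#' @param elements Element tibble.
#' @param domain_hits Domain-hit tibble (element-relative coordinates).
#' @return `elements` with `superfamily` and `completeness` columns.
#' @export
classify_superfamily <- function(elements, domain_hits) {
  all_doms <- c("GAG", "PR", "INT", "RT", "RH")
  cls <- domain_hits |>
    group_by(.data$element_id) |>
    summarise(strand_maj = if (mean(.data$strand == "-") > 0.5) "-" else "+",
              n_domains = n_distinct(.data$domain),
              complete = all(all_doms %in% .data$domain),
              int_pos = if (any(.data$domain == "INT"))
                min(.data$start[.data$domain == "INT"]) else NA_integer_,
              rt_pos = if (any(.data$domain == "RT"))
                min(.data$start[.data$domain == "RT"]) else NA_integer_,
              .groups = "drop") |>
    mutate(int_first = if_else(.data$strand_maj == "+",
                               .data$int_pos < .data$rt_pos,
                               .data$int_pos > .data$rt_pos),
           superfamily = case_when(
             is.na(.data$int_pos) | is.na(.data$rt_pos) ~ "unclassified",
             .data$int_first ~ "Copia",
             TRUE ~ "Gypsy"),
           completeness = if_else(.data$complete, "complete", "incomplete"))
  elements |>
    select(-any_of(c("superfamily", "completeness"))) |>
    left_join(cls |> select("element_id", "superfamily", "completeness"),
              by = "element_id") |>
    mutate(superfamily = coalesce(.data$superfamily, "unclassified"),
           completeness = coalesce(.data$completeness, "incomplete"))
}

#' Retain only full-length MITE copies
#'
#' Keeps copies whose length lies within consensus length plus or minus 20%
#' (closed interval on both boundaries).
#'
#' @param copies Tibble with at least `consensus_length` and `copy_length`
#'   columns (or `start`/`end` from which `copy_length` is derived).
#' @param tolerance Relative length tolerance (default 0.2).
#' @return The subset of full-length copies.
#' @export
mite_full_length_filter <- function(copies, tolerance = 0.2) {
  if (!"copy_length" %in% names(copies)) {
    copies <- copies |> mutate(copy_length = .data$end - .data$start + 1L)
  }
  stopifnot(all(copies$consensus_length > 0))
  copies |>
    filter(.data$copy_length >= (1 - tolerance) * .data$consensus_length,
           .data$copy_length <= (1 + tolerance) * .data$consensus_length)
}
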