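#' Alignment scoring parameters
#'
#' Needle/BLASTn-like defaults: match +2, mismatch -3, affine gap penalties
#' (open 5, extend 2, both applied as positive costs). `N` scores 0 against
#' everything so assembly gaps neither reward nor punish the optimal path.
#'
#' @param match Match score.
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening cost (positive).
#' @param gap_extend Gap extension cost per residue (positive).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# Substitution matrix over {A,C,G,T,N}; N is neutral (0) against everything.
submat_acgtn <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

new_pairwise_alignment <- function(aligned_query, aligned_target, score,
                                   query_id = NA_character_, target_id = NA_character_,
                                   query_span, target_span,
                                   query_length, target_length) {
  stopifnot(nchar(aligned_query) == nchar(aligned_target))
  structure(list(query_id = query_id, target_id = target_id,
                 aligned_query = aligned_query, aligned_target = aligned_target,
                 score = score, query_span = query_span, target_span = target_span,
                 query_length = query_length, target_length = target_length),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  ic <- identity_coverage(x)
  cat(sprintf("<pairwise_alignment> score %.1f, identity %.3f, coverage %.3f\n",
              x$score, ic[["identity"]], ic[["coverage"]]))
  w <- nchar(x$aligned_query)
  show <- min(w, 60L)
  cat(substr(x$aligned_query, 1, show), if (w > show) "...", "\n", sep = "")
  cat(substr(x$aligned_target, 1, show), if (w > show) "...", "\n", sep = "")
  invisible(x)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment of two nucleotide sequences, as used for
#' LTR-pair dating, 80/80 family comparisons and orthologous-locus
#' verification. Delegates the dynamic program to
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Sequences (character scalars over `A,C,G,T,N`).
#' @param params An [align_params()] object.
#' @param query_id,target_id Optional identifiers carried into the result.
#' @return A `pairwise_alignment` object with gapped sequences, score and
#'   1-based inclusive spans on each input.
#' @export
align_global <- function(a, b, params = align_params(),
                         query_id = NA_character_, target_id = NA_character_) {
  if (!is.character(a) || !is.character(b) || nchar(a) == 0L || nchar(b) == 0L) {
    abort("both sequences must be non-empty character scalars",
          class = "ltrdyn_input_error")
  }
  a <- toupper(a); b <- toupper(b)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = submat_acgtn(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  new_pairwise_alignment(
    aligned_query = as.character(Biostrings::alignedPattern(pa)),
    aligned_target = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    query_id = query_id, target_id = target_id,
    query_span = c(1L, nchar(a)), target_span = c(1L, nchar(b)),
    query_length = nchar(a), target_length = nchar(b))
}

# Character matrices of the two gapped rows, shared by the column counters.
aln_columns <- function(aln) {
  q <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  t <- strsplit(aln$aligned_target, "", fixed = TRUE)[[1L]]
  list(q = q, t = t)
}

#' Identity and coverage of an alignment
#'
#' Identity is matches over aligned residue pairs (columns where both rows
#' carry a non-`N` residue). Coverage is the number of aligned residue-pair
#' columns over the full length of the longer input sequence, so that an
#' "aligned over 80% of their length" test is conservative when lengths
#' differ.
#'
#' @param aln A `pairwise_alignment`.
#' @return Named numeric vector `c(identity =, coverage =)`.
#' @export
identity_coverage <- function(aln) {
  cols <- aln_columns(aln)
  both <- cols$q != "-" & cols$t != "-"
  usable <- both & cols$q != "N" & cols$t != "N"
  n_usable <- sum(usable)
  identity <- if (n_usable == 0L) 0 else sum(cols$q[usable] == cols$t[usable]) / n_usable
  denom <- max(aln$query_length, aln$target_length)
  c(identity = identity, coverage = sum(both) / denom)
}

#' Kimura two-parameter distance of an aligned pair
#'
#' Counts the transition proportion P and transversion proportion Q over
#' gap-free, non-`N` columns and applies the closed form
#' \deqn{K = -\tfrac12 \ln\big((1-2P-Q)\sqrt{1-2Q}\big).}
#' The correction is undefined (saturated) when `1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`; a classed error `ltrdyn_saturation_error` is raised there.
#'
#' @param aln A `pairwise_alignment`, or a character vector of length 2 holding
#'   two equal-length gapped sequences.
#' @return A one-row tibble with `P`, `Q`, `K` and `compared_sites`.
#' @export
k2p_distance <- function(aln) {
  if (is.character(aln) && length(aln) == 2L) {
    if (nchar(aln[1]) != nchar(aln[2])) {
      abort("gapped sequences must have equal length", class = "ltrdyn_input_error")
    }
    aln <- new_pairwise_alignment(toupper(aln[1]), toupper(aln[2]), score = NA_real_,
                                  query_span = c(1L, 0L), target_span = c(1L, 0L),
                                  query_length = nchar(aln[1]), target_length = nchar(aln[2]))
  }
  cols <- aln_columns(aln)
  q <- cols$q; t <- cols$t
  usable <- q %in% .BASES & t %in% .BASES
  n <- sum(usable)
  if (n == 0L) {
    abort("no gap-free, unambiguous columns to compare", class = "ltrdyn_input_error")
  }
  qi <- match(q[usable], .BASES)
  ti <- match(t[usable], .BASES)
  diff <- qi != ti
  ts <- diff & (.TS_PARTNER[qi] == ti)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf("K2P distance saturated (P = %.3f, Q = %.3f)", P, Q),
          class = "ltrdyn_saturation_error")
  }
  K <- -0.5 * log(w1 * sqrt(w2))
  tibble(P = P, Q = Q, K = K, compared_sites = n)
}

#' Flank-mapping parameters
#'
#' Controls the exact k-mer seed and affine extension used by [map_flank()].
#' The E-value cutoff of a database search is replaced by a deterministic,
#' database-free score floor plus an identity pre-filter.
#'
#' @param k Seed length (exact match).
#' @param min_score Minimum alignment score to report a hit.
#' @param min_identity Minimum identity of a reported hit.
#' @param min_seeds Minimum seeds per candidate locus before extension
#'   (automatically 1 for queries shorter than 40 bp).
#' @param diag_tol Diagonal tolerance when clustering seeds into loci.
#' @param pad Window padding around the seeded locus before extension.
#' @param align An [align_params()] object for the extension.
#' @return A list of class `map_params`.
#' @export
map_params <- function(k = 13L, min_score = 50, min_identity = 0.75,
                       min_seeds = 2L, diag_tol = 60L, pad = 100L,
                       align = align_params()) {
  structure(list(k = as.integer(k), min_score = min_score,
                 min_identity = min_identity, min_seeds = as.integer(min_seeds),
                 diag_tol = as.integer(diag_tol), pad = as.integer(pad),
                 align = align),
            class = "map_params")
}

# A reusable exact k-mer index of a genome: per sequence, sorted codes with
# positions. Building it once amortizes mapping many queries.
genome_kmer_index <- function(genome, k = 13L, stride = 1L) {
  genome <- as_genome(genome)
  idx <- lapply(seq_along(genome), function(i) {
    kt <- kmer_table(as.character(genome[[i]]), k = k, stride = stride)
    o <- order(kt$code)
    list(code = kt$code[o], pos = kt$pos[o])
  })
  names(idx) <- names(genome)
  structure(list(index = idx, k = as.integer(k), stride = as.integer(stride),
                 genome = genome),
            class = "genome_kmer_index")
}

# All exact seed matches of query k-mers in one indexed sequence.
# Returns tibble(qpos, tpos).
seed_matches <- function(qcodes, qpos, idx_seq) {
  code <- idx_seq$code
  lo <- findInterval(qcodes - 1L, code) + 1L
  hi <- findInterval(qcodes, code)
  nhit <- hi - lo + 1L
  keep <- which(nhit > 0L)
  if (length(keep) == 0L) return(tibble(qpos = integer(0), tpos = integer(0)))
  reps <- nhit[keep]
  qp <- rep(qpos[keep], reps)
  tp <- idx_seq$pos[unlist(lapply(keep, function(i) lo[i]:hi[i]), use.names = FALSE)]
  tibble(qpos = qp, tpos = tp)
}

# Cluster seed matches into candidate loci by diagonal and position.
cluster_seeds <- function(hits, diag_tol, gap_tol) {
  hits <- hits |> mutate(diag = .data$tpos - .data$qpos) |> arrange(.data$diag, .data$tpos)
  brk <- c(TRUE, diff(hits$diag) > diag_tol | abs(diff(hits$tpos)) > gap_tol)
  hits$locus <- cumsum(brk)
  hits
}

#' Map a short query sequence onto a genome
#'
#' Seed-and-extend local mapping: exact `k`-mer seeds locate candidate loci on
#' both strands, then the full query is aligned to the padded locus window
#' (global in the query, local in the target). This is the primitive behind
#' orthologous-locus detection via 500-bp flanks.
#'
#' @param query Query sequence (character scalar).
#' @param genome Genome ([as_genome()] forms) or a prebuilt index from
#'   `genome_kmer_index()`.
#' @param params A [map_params()] object.
#' @return A tibble of hits sorted by score (descending):
#'   `target_sequence_id`, `start`, `end` (1-based inclusive), `strand`,
#'   `identity`, `coverage`, `score`.
#' @export
map_flank <- function(query, genome, params = map_params()) {
  if (inherits(genome, "genome_kmer_index")) {
    idx <- genome
  } else {
    genome <- as_genome(genome)
    if (sum(Biostrings::width(genome)) == 0L) {
      abort("genome is empty", class = "ltrdyn_input_error")
    }
    idx <- genome_kmer_index(genome, k = params$k)
  }
  query <- toupper(query)
  qlen <- nchar(query)
  if (qlen < params$k) {
    abort("query shorter than seed length", class = "ltrdyn_input_error")
  }
  min_seeds <- if (qlen < 40L) 1L else params$min_seeds
  strands <- list(`+` = query, `-` = reverse_complement(query))
  out <- vector("list", 0L)
  for (strand in names(strands)) {
    qs <- strands[[strand]]
    kt <- kmer_table(qs, k = idx$k)
    if (length(kt$code) == 0L) next
    for (sid in names(idx$index)) {
      hits <- seed_matches(kt$code, kt$pos, idx$index[[sid]])
      if (nrow(hits) == 0L) next
      hits <- cluster_seeds(hits, params$diag_tol, gap_tol = qlen + 200L)
      tseq_len <- length(idx$genome[[sid]])
      for (loc in split(hits, hits$locus)) {
        if (nrow(loc) < min_seeds) next
        wstart <- max(1L, min(loc$tpos) - (min(loc$qpos) - 1L) - params$pad)
        wend <- min(tseq_len, max(loc$tpos) + idx$k - 1L + (qlen - max(loc$qpos)) + params$pad)
        window <- extract_seq(idx$genome, sid, wstart, wend)
        pa <- Biostrings::pairwiseAlignment(
          pattern = qs, subject = window, type = "global-local",
          substitutionMatrix = submat_acgtn(params$align),
          gapOpening = params$align$gap_open, gapExtension = params$align$gap_extend)
        sc <- Biostrings::score(pa)
        if (sc < params$min_score) next
        aq <- as.character(Biostrings::alignedPattern(pa))
        at <- as.character(Biostrings::alignedSubject(pa))
        tstart <- wstart + Biostrings::start(Biostrings::subject(pa)) - 1L
        tend <- wstart + Biostrings::end(Biostrings::subject(pa)) - 1L
        aln <- new_pairwise_alignment(aq, at, sc,
                                      query_span = c(1L, qlen),
                                      target_span = c(tstart, tend),
                                      query_length = qlen,
                                      target_length = qlen)
        # coverage here is the aligned fraction of the query, not of the window
        cols <- aln_columns(aln)
        both <- cols$q != "-" & cols$t != "-"
        usable <- both & cols$q != "N" & cols$t != "N"
        ident <- if (sum(usable) == 0L) 0 else sum(cols$q[usable] == cols$t[usable]) / sum(usable)
        if (ident < params$min_identity) next
        if (strand == "-") {
          # report coordinates of the forward-strand locus
          out[[length(out) + 1L]] <- tibble(
            target_sequence_id = sid, start = tstart, end = tend, strand = "-",
            identity = ident, coverage = sum(both) / qlen, score = sc)
        } else {
          out[[length(out) + 1L]] <- tibble(
            target_sequence_id = sid, start = tstart, end = tend, strand = "+",
            identity = ident, coverage = sum(both) / qlen, score = sc)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(target_sequence_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0), identity = numeric(0),
                  coverage = numeric(0), score = numeric(0)))
  }
  bind_rows(out) |>
    distinct(.data$target_sequence_id, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) |>
    arrange(desc(.data$score))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.pairwise_alignment <- function(x, ...) {
  ic <- identity_coverage(x)
  tibble(score = x$score, identity = ic[["identity"]], coverage = ic[["coverage"]],
         columns = nchar(x$aligned_query))
}

#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(query_id = x$query_id, target_id = x$target_id,
         aligned_query = x$aligned_query, aligned_target = x$aligned_target,
         score = x$score,
         query_start = x$query_span[1], query_end = x$query_span[2],
         target_start = x$target_span[1], target_end = x$target_span[2])
}
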