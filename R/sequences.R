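#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int map_chr map_lgl pmap imap list_rbind
NULL

# Internal integer coding of nucleotides: A=1, C=2, G=3, T=4, N/other = NA.
# Transition partners (A<->G, C<->T) and the two transversion targets per base
# are fixed lookup tables used by both the simulator and the K2P counter.
.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(3L, 4L, 1L, 2L)
.TV1 <- c(2L, 1L, 2L, 1L)
.TV2 <- c(4L, 3L, 4L, 3L)

dna_to_int <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  stopifnot(length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  match(chars, .BASES)
}

int_to_dna <- function(v) {
  out <- .BASES[v]
  out[is.na(v)] <- "N"
  paste(out, collapse = "")
}

#' Coerce a genome to a named DNAStringSet
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector of sequences,
#' or a path to a FASTA file. Used by every function that takes a genome.
#'
#' @param genome Genome in any of the accepted forms.
#' @return A named [Biostrings::DNAStringSet].
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (is.null(names(genome))) abort("genome sequences must be named")
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome sequences must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("cannot interpret `genome`: give a DNAStringSet, named character vector, or FASTA path")
}

# Integer codes of all k-mers of `x` (character sequence or integer vector),
# base-4 polynomial code; NA where the window touches an ambiguous base.
# k <= 15 keeps the code within the integer range.
kmer_codes <- function(x, k = 13L) {
  v <- if (is.character(x)) dna_to_int(x) else x
  n <- length(v)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- (v[seq_len(m)] - 1L)
  for (j in 1L:(k - 1L)) {
    code <- code * 4L + (v[seq_len(m) + j] - 1L)
  }
  code
}

# Positions (1-based) and codes of non-NA k-mers, optionally strided.
kmer_table <- function(x, k = 13L, stride = 1L) {
  code <- kmer_codes(x, k)
  pos <- seq_along(code)
  if (stride > 1L) {
    keep <- seq(1L, length(code), by = stride)
    code <- code[keep]
    pos <- pos[keep]
  }
  ok <- !is.na(code)
  list(pos = pos[ok], code = code[ok])
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Extract subsequence [start, end] 1-based inclusive from a DNAStringSet entry.
extract_seq <- function(genome, sequence_id, start, end) {
  genome <- as_genome(genome)
  if (!sequence_id %in% names(genome)) {
    abort(paste0("sequence '", sequence_id, "' not found in genome"))
  }
  len <- length(genome[[sequence_id]])
  if (start < 1L || end > len || start > end) {
    abort(sprintf("span [%d, %d] out of bounds for sequence '%s' (length %d)",
                  start, end, sequence_id, len), class = "ltrdyn_input_error")
  }
  as.character(Biostrings::subseq(genome[[sequence_id]], start, end))
}
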