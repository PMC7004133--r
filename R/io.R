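#' Write a genome to FASTA
#'
#' @param genome Genome ([as_genome()] forms).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 60L)
  invisible(path)
}

#' Write an element table as GFF3
#'
#' Each element becomes one `LTR_retrotransposon` parent feature with two
#' `long_terminal_repeat` children. Coordinates are 1-based inclusive, as in
#' the element tibbles themselves.
#'
#' @param elements Element tibble.
#' @param path Output path.
#' @param source Source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path, source = "ltrdyn") {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    attrs <- paste0("ID=", el$element_id)
    if ("superfamily" %in% names(elements) && !is.na(el$superfamily)) {
      attrs <- paste0(attrs, ";superfamily=", el$superfamily)
    }
    if ("completeness" %in% names(elements) && !is.na(el$completeness)) {
      attrs <- paste0(attrs, ";completeness=", el$completeness)
    }
    lines <- c(lines,
      paste(el$sequence_id, source, "LTR_retrotransposon", el$start, el$end,
            ".", "+", ".", attrs, sep = "\t"),
      paste(el$sequence_id, source, "long_terminal_repeat", el$ltr5_start,
            el$ltr5_end, ".", "+", ".",
            paste0("ID=", el$element_id, "_ltr5;Parent=", el$element_id), sep = "\t"),
      paste(el$sequence_id, source, "long_terminal_repeat", el$ltr3_start,
            el$ltr3_end, ".", "+", ".",
            paste0("ID=", el$element_id, "_ltr3;Parent=", el$element_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an element table from GFF3
#'
#' Inverse of [write_elements_gff3()]: reconstructs the element tibble from
#' `LTR_retrotransposon` parents and their `long_terminal_repeat` children.
#'
#' @param path GFF3 path.
#' @return Element tibble.
#' @export
read_elements_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  parents <- df |> filter(.data$type == "LTR_retrotransposon")
  kids <- df |> filter(.data$type == "long_terminal_repeat")
  kid_parent <- map_chr(kids$Parent, function(p) as.character(p)[1])
  out <- map(seq_len(nrow(parents)), function(i) {
    p <- parents[i, ]
    k <- kids[kid_parent == p$ID, ] |> arrange(.data$start)
    if (nrow(k) != 2L) {
      abort(paste0("element ", p$ID, " does not have exactly two LTR children"))
    }
    tibble(element_id = p$ID, sequence_id = as.character(p$seqnames),
           start = p$start, end = p$end,
           ltr5_start = k$start[1], ltr5_end = k$end[1],
           internal_start = k$end[1] + 1L, internal_end = k$start[2] - 1L,
           ltr3_start = k$start[2], ltr3_end = k$end[2],
           superfamily = if ("superfamily" %in% names(p)) p$superfamily else NA_character_,
           completeness = if ("completeness" %in% names(p)) p$completeness else NA_character_)
  })
  list_rbind(out)
}

#' Write deletion calls of one cultivar as a minimal VCF
#'
#' Emits VCF 4.2 records with `SVTYPE=DEL`, `END` and `SUPPORT` INFO keys.
#'
#' @param calls Calls of a single cultivar (`sequence_id`, `start`, `end`,
#'   `support_reads`).
#' @param path Output path.
#' @param sample_id Sample name written in the header.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(calls, path, sample_id = "sample") {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
              "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
              "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
              paste0("##sample=", sample_id),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls) > 0L) {
    ids <- if ("call_id" %in% names(calls)) calls$call_id else sprintf("DEL%05d", seq_len(nrow(calls)))
    recs <- paste(calls$sequence_id, calls$start, ids, "N", "<DEL>", ".", "PASS",
                  sprintf("SVTYPE=DEL;END=%d;SUPPORT=%d", calls$end, calls$support_reads),
                  sep = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read deletion calls from a VCF
#'
#' Reads `SVTYPE=DEL` records, taking the span from POS and the `END` INFO
#' key and supporting reads from `support_key`.
#'
#' @param path VCF path.
#' @param cultivar_id Cultivar id to attach to the calls.
#' @param support_key INFO key holding supporting-read counts.
#' @return Deletion-call tibble.
#' @export
read_deletion_vcf <- function(path, cultivar_id = NA_character_,
                              support_key = "SUPPORT") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  m <- vcfR::getFIX(v)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  fix <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    return(tibble(call_id = character(0), cultivar_id = character(0),
                  sequence_id = character(0), start = integer(0),
                  end = integer(0), support_reads = integer(0)))
  }
  info <- vcfR::extract.info(v, element = "SVTYPE")
  ends <- as.integer(vcfR::extract.info(v, element = "END"))
  supp <- as.integer(vcfR::extract.info(v, element = support_key))
  keep <- !is.na(info) & info == "DEL"
  tibble(call_id = fix$ID[keep], cultivar_id = cultivar_id,
         sequence_id = fix$CHROM[keep],
         start = as.integer(fix$POS[keep]), end = ends[keep],
         support_reads = supp[keep])
}

#' Read a contig-alignment structural-variant table
#'
#' Parses the tab-separated variant table emitted by Assemblytics-style
#' pipelines (`reference`, `ref_start`, `ref_stop`, `ID`, `size`, `strand`,
#' `type`, `ref_gap_size`, `query_gap_size`, `query_coordinates`, `method`).
#' Types are lower-cased (`Insertion` becomes `insertion`, etc.) and the
#' query coordinate string `seq:start-stop:strand` is split into `alt_*`
#' columns.
#'
#' @param path TSV path.
#' @return SV tibble suitable for [filter_sv()] / [sv_te_associate()].
#' @export
read_assemblytics <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df) <- sub("^#", "", names(df))
  qc <- stringr::str_match(df$query_coordinates, "^([^:]+):(\\d+)-(\\d+)(?::([+-]))?$")
  tibble(variant_id = as.character(df$ID),
         type = tolower(df$type),
         ref_sequence_id = as.character(df$reference),
         ref_start = as.integer(df$ref_start),
         ref_end = as.integer(df$ref_stop),
         alt_sequence_id = qc[, 2],
         alt_start = as.integer(qc[, 3]),
         alt_end = as.integer(qc[, 4]),
         size = as.integer(df$size))
}

#' Write a simulated genome pair to disk
#'
#' Emits FASTA genomes, GFF3 annotations, domain-hit and truth tables plus
#' N-region tables into `dir`.
#'
#' @param sim An `ltr_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome_a = file.path(dir, "genome_A.fa"),
    genome_b = file.path(dir, "genome_B.fa"),
    elements_a = file.path(dir, "elements_A.gff3"),
    elements_b = file.path(dir, "elements_B.gff3"),
    domains_a = file.path(dir, "domains_A.tsv"),
    domains_b = file.path(dir, "domains_B.tsv"),
    truth = file.path(dir, "truth.tsv"),
    n_regions_a = file.path(dir, "n_regions_A.tsv"),
    n_regions_b = file.path(dir, "n_regions_B.tsv"))
  write_genome_fasta(sim$genome_a, paths["genome_a"])
  write_genome_fasta(sim$genome_b, paths["genome_b"])
  write_elements_gff3(sim$elements_a, paths["elements_a"])
  write_elements_gff3(sim$elements_b, paths["elements_b"])
  readr::write_tsv(sim$domains_a, paths["domains_a"])
  readr::write_tsv(sim$domains_b, paths["domains_b"])
  readr::write_tsv(sim$truth, paths["truth"])
  readr::write_tsv(sim$n_regions_a, paths["n_regions_a"])
  readr::write_tsv(sim$n_regions_b, paths["n_regions_b"])
  invisible(paths)
}

#' Write cohort deletion calls as per-cultivar VCFs
#'
#' @param cohort An `ltr_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return Paths of the written VCFs, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- map_chr(cohort$cohort, function(cv) {
    p <- file.path(dir, paste0(cv, ".deletions.vcf"))
    write_deletion_vcf(cohort$calls |> filter(.data$cultivar_id == cv), p,
                       sample_id = cv)
    p
  })
  readr::write_tsv(cohort$presence, file.path(dir, "presence.tsv"))
  invisible(paths)
}
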