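#' Simulation configuration for a diverged genome pair
#'
#' Defines the study conditions emulated by [simulate_genome_pair()]: two
#' genomes descended from a common ancestor that split `split_mya` million
#' years ago (default 5.88), carrying LTR retrotransposon insertions whose two
#' LTRs were identical at insertion time and have since diverged under a
#' Kimura two-parameter substitution process with total rate
#' `substitution_rate` per site per year and transition/transversion rate
#' ratio `kappa`. Insertions older than the split are planted in the common
#' ancestor (and may later be partially deleted in one lineage); younger ones
#' are lineage specific.
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param genome_length Ancestral background length in bp.
#' @param gc_content Background GC fraction.
#' @param n_families Number of LTR retrotransposon families.
#' @param ltr_length,internal_length Consensus LTR and internal lengths (bp).
#' @param split_mya Species split time, million years.
#' @param substitution_rate Substitutions per site per year.
#' @param kappa Transition/transversion rate ratio.
#' @param fate_counts Named counts per insertion fate: `conserved`,
#'   `specific_A`, `specific_B`, `partial_A_in_B`, `partial_B_in_A`.
#' @param age_range_shared Age range (Mya) for insertions predating the split.
#' @param age_range_specific Age range (Mya) for lineage-specific insertions.
#' @param tsd_length Target-site duplication length planted at every insertion.
#' @param min_spacing Minimum background distance between insertion sites (bp).
#' @param n_region_count,n_region_length Number and length range of planted
#'   assembly-gap (`N`) regions.
#' @param indel_rate Per-site probability of a small background indel event
#'   applied independently to each lineage after the split (0 disables; keeps
#'   every simulated coordinate exactly mappable).
#' @param generation_time Years per generation; carried as metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       gc_content = 0.38,
                       n_families = 6L,
                       ltr_length = 500L,
                       internal_length = 2000L,
                       split_mya = 5.88,
                       substitution_rate = 1e-8,
                       kappa = 2,
                       fate_counts = c(conserved = 50L, specific_A = 50L,
                                       specific_B = 50L, partial_A_in_B = 25L,
                                       partial_B_in_A = 25L),
                       age_range_shared = c(6.5, 12),
                       age_range_specific = c(0.3, 5.5),
                       tsd_length = 5L,
                       min_spacing = 1500L,
                       n_region_count = 4L,
                       n_region_length = c(500L, 1500L),
                       indel_rate = 0,
                       generation_time = 10) {
  fates <- c("conserved", "specific_A", "specific_B", "partial_A_in_B", "partial_B_in_A")
  missing_fates <- setdiff(fates, names(fate_counts))
  fate_counts[missing_fates] <- 0L
  fate_counts <- fate_counts[fates]
  stopifnot(all(fate_counts >= 0), gc_content > 0, gc_content < 1,
            substitution_rate > 0, kappa > 0, split_mya > 0)
  if (age_range_shared[1] < split_mya) {
    abort("age_range_shared must lie above split_mya")
  }
  if (age_range_specific[2] > split_mya) {
    abort("age_range_specific must lie below split_mya")
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_families = as.integer(n_families),
                 ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 split_mya = split_mya, substitution_rate = substitution_rate,
                 kappa = kappa, fate_counts = fate_counts,
                 age_range_shared = age_range_shared,
                 age_range_specific = age_range_specific,
                 tsd_length = as.integer(tsd_length),
                 min_spacing = as.integer(min_spacing),
                 n_region_count = as.integer(n_region_count),
                 n_region_length = as.integer(n_region_length),
                 indel_rate = indel_rate,
                 generation_time = generation_time),
            class = "sim_config")
}

# Random integer-coded sequence at the given GC content.
random_int_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

# Evolve an integer-coded sequence for `years` under K80 with total
# substitution rate `rate` and ts/tv rate ratio `kappa`, using the exact
# finite-time transition probabilities so that successive applications
# compose exactly (Markov property). NA (N) sites are left untouched.
mutate_k2p <- function(v, years, rate, kappa) {
  if (years <= 0) return(v)
  beta <- rate / (kappa + 2)
  alpha <- kappa * beta
  t1 <- exp(-4 * beta * years)
  t2 <- exp(-2 * (alpha + beta) * years)
  p_ts <- 0.25 + 0.25 * t1 - 0.5 * t2
  p_tv_each <- 0.25 - 0.25 * t1
  n <- length(v)
  u <- stats::runif(n)
  out <- v
  ok <- !is.na(v)
  sel <- ok & u < p_ts
  out[sel] <- .TS_PARTNER[v[sel]]
  sel <- ok & u >= p_ts & u < p_ts + p_tv_each
  out[sel] <- .TV1[v[sel]]
  sel <- ok & u >= p_ts + p_tv_each & u < p_ts + 2 * p_tv_each
  out[sel] <- .TV2[v[sel]]
  out
}

# Small random indels: each site nucleates an event with probability `rate`;
# half are deletions, half insertions, lengths 1 + Geom(0.5) capped at 10.
apply_indels <- function(v, rate) {
  if (rate <= 0) return(v)
  n <- length(v)
  sites <- which(stats::runif(n) < rate)
  if (length(sites) == 0L) return(v)
  lens <- pmin(1L + stats::rgeom(length(sites), 0.5), 10L)
  is_del <- stats::runif(length(sites)) < 0.5
  pieces <- list()
  prev <- 1L
  for (i in seq_along(sites)) {
    s <- sites[i]
    if (s < prev) next
    if (is_del[i]) {
      pieces[[length(pieces) + 1L]] <- v[seq2(prev, s - 1L)]
      prev <- min(n + 1L, s + lens[i])
    } else {
      pieces[[length(pieces) + 1L]] <- v[seq2(prev, s)]
      pieces[[length(pieces) + 1L]] <- random_int_seq(lens[i], 0.5)
      prev <- s + 1L
    }
  }
  pieces[[length(pieces) + 1L]] <- v[seq2(prev, n)]
  unlist(pieces, use.names = FALSE)
}

seq2 <- function(from, to) {
  if (to < from) integer(0) else from:to
}

#' Simulate a diverged genome pair with planted, dated TE insertions
#'
#' Builds an ancestral background sequence, plants LTR retrotransposon
#' insertions of known age, family and fate, evolves the two lineages
#' independently for `split_mya` million years, and emits both genomes with
#' per-genome element annotations, domain-hit tables and a ground-truth
#' ledger. Insertions older than the split share their pre-split mutations in
#' both genomes; each LTR of each copy accumulates substitutions
#' independently so the expected inter-LTR K2P distance is `2 r T` for a
#' copy of age `T` years.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ltr_sim`: `genome_a`, `genome_b`
#'   (DNAStringSet, sequences `chr1`), `elements_a`, `elements_b` (annotation
#'   tibbles), `domains_a`, `domains_b` (domain-hit tibbles), `truth`
#'   (per-insertion ledger), `n_regions_a/b`, `consensi`, `config`.
#' @export
simulate_genome_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_ins <- sum(cfg$fate_counts)
  el_len <- 2L * cfg$ltr_length + cfg$internal_length
  needed <- n_ins * (cfg$min_spacing + el_len) + 2L * 2000L
  if (needed > cfg$genome_length + n_ins * el_len) {
    abort(sprintf("genome_length %d too small for %d insertions at spacing %d",
                  cfg$genome_length, n_ins, cfg$min_spacing),
          class = "ltrdyn_config_error")
  }

  split_years <- cfg$split_mya * 1e6
  r <- cfg$substitution_rate

  ## ancestral background with N regions
  bg <- random_int_seq(cfg$genome_length, cfg$gc_content)
  n_regions <- tibble(start = integer(0), end = integer(0))
  if (cfg$n_region_count > 0L) {
    nlen <- sample(seq(cfg$n_region_length[1], cfg$n_region_length[2]),
                   cfg$n_region_count, replace = TRUE)
    nstart <- sort(sample(seq(5000L, cfg$genome_length - 5000L - max(nlen)),
                          cfg$n_region_count))
    # keep N regions well apart
    while (any(diff(nstart) < 10000L)) {
      nstart <- sort(sample(seq(5000L, cfg$genome_length - 5000L - max(nlen)),
                            cfg$n_region_count))
    }
    for (i in seq_len(cfg$n_region_count)) {
      bg[nstart[i]:(nstart[i] + nlen[i] - 1L)] <- NA_integer_
    }
    n_regions <- tibble(start = nstart, end = nstart + nlen - 1L)
  }

  ## family consensi: alternate Copia / Gypsy domain orders
  doms_copia <- c("GAG", "PR", "INT", "RT", "RH")
  doms_gypsy <- c("GAG", "PR", "RT", "RH", "INT")
  consensi <- lapply(seq_len(cfg$n_families), function(f) {
    sf <- if (f %% 2L == 1L) "Copia" else "Gypsy"
    ord <- if (sf == "Copia") doms_copia else doms_gypsy
    dlen <- max(60L, min(300L, (cfg$internal_length - 100L) %/% 6L))
    gap <- (cfg$internal_length - 5L * dlen) %/% 6L
    starts <- gap + (seq_len(5L) - 1L) * (dlen + gap) + 1L
    list(family_id = sprintf("FAM%02d", f), superfamily = sf,
         ltr = random_int_seq(cfg$ltr_length, cfg$gc_content),
         internal = random_int_seq(cfg$internal_length, cfg$gc_content),
         domains = tibble(domain = ord, start = starts, end = starts + dlen - 1L,
                          strand = "+"))
  })
  names(consensi) <- map_chr(consensi, "family_id")

  ## insertion sites in ancestral coordinates, away from N regions and edges
  forbidden <- n_regions |> mutate(start = .data$start - 2500L, end = .data$end + 2500L)
  ok_site <- function(p) {
    if (nrow(forbidden) > 0L && any(p >= forbidden$start & p <= forbidden$end)) return(FALSE)
    TRUE
  }
  sites <- integer(0)
  cand <- sample(seq(2000L, cfg$genome_length - 2000L), min(cfg$genome_length, n_ins * 50L),
                 replace = FALSE)
  for (p in cand) {
    if (length(sites) == n_ins) break
    if (!ok_site(p)) next
    if (length(sites) > 0L && any(abs(sites - p) < cfg$min_spacing + cfg$tsd_length)) next
    sites <- c(sites, p)
  }
  if (length(sites) < n_ins) {
    abort("could not place all insertions; increase genome_length or lower min_spacing",
          class = "ltrdyn_config_error")
  }
  sites <- sort(sites)

  fates <- sample(rep(names(cfg$fate_counts), cfg$fate_counts))
  fams <- sample(names(consensi), n_ins, replace = TRUE)
  shared <- fates %in% c("conserved", "partial_A_in_B", "partial_B_in_A")
  ages <- ifelse(shared,
                 stats::runif(n_ins, cfg$age_range_shared[1], cfg$age_range_shared[2]),
                 stats::runif(n_ins, cfg$age_range_specific[1], cfg$age_range_specific[2]))

  ## per-insertion element copies for each genome
  # returns list(ltr5, internal, ltr3) integer vectors or NULL if absent
  build_copies <- function(i) {
    cons <- consensi[[fams[i]]]
    age_years <- ages[i] * 1e6
    if (shared[i]) {
      pre <- age_years - split_years
      s5 <- mutate_k2p(cons$ltr, pre, r, cfg$kappa)
      s3 <- mutate_k2p(cons$ltr, pre, r, cfg$kappa)
      si <- mutate_k2p(cons$internal, pre, r, cfg$kappa)
      a <- list(ltr5 = mutate_k2p(s5, split_years, r, cfg$kappa),
                internal = mutate_k2p(si, split_years, r, cfg$kappa),
                ltr3 = mutate_k2p(s3, split_years, r, cfg$kappa))
      b <- list(ltr5 = mutate_k2p(s5, split_years, r, cfg$kappa),
                internal = mutate_k2p(si, split_years, r, cfg$kappa),
                ltr3 = mutate_k2p(s3, split_years, r, cfg$kappa))
      list(A = a, B = b)
    } else {
      copy <- list(ltr5 = mutate_k2p(cons$ltr, age_years, r, cfg$kappa),
                   internal = mutate_k2p(cons$internal, age_years, r, cfg$kappa),
                   ltr3 = mutate_k2p(cons$ltr, age_years, r, cfg$kappa))
      if (fates[i] == "specific_A") list(A = copy, B = NULL) else list(A = NULL, B = copy)
    }
  }
  copies <- lapply(seq_len(n_ins), build_copies)

  ## partial deletions: remove a central chunk from the copy in the genome
  ## where the element is degraded
  partial_keep <- stats::runif(n_ins, 0.15, 0.25)  # fraction kept on each end
  for (i in seq_len(n_ins)) {
    if (fates[i] == "partial_A_in_B" && !is.null(copies[[i]]$B)) {
      copies[[i]]$B <- degrade_copy(copies[[i]]$B, partial_keep[i])
    } else if (fates[i] == "partial_B_in_A" && !is.null(copies[[i]]$A)) {
      copies[[i]]$A <- degrade_copy(copies[[i]]$A, partial_keep[i])
    }
  }

  ## independent post-split background divergence
  bg_a <- mutate_k2p(bg, split_years, r, cfg$kappa)
  bg_b <- mutate_k2p(bg, split_years, r, cfg$kappa)

  assemble <- function(bg_g, genome_tag) {
    pieces <- list()
    rows <- list()
    prev <- 1L
    for (i in seq_len(n_ins)) {
      cp <- copies[[i]][[genome_tag]]
      if (is.null(cp)) next
      p <- sites[i]
      tsd <- bg_g[seq2(p + 1L, p + cfg$tsd_length)]
      pieces[[length(pieces) + 1L]] <- bg_g[seq2(prev, p + cfg$tsd_length)]
      pieces[[length(pieces) + 1L]] <- c(cp$ltr5, cp$internal, cp$ltr3)
      pieces[[length(pieces) + 1L]] <- tsd
      rows[[length(rows) + 1L]] <- tibble(
        insertion_id = sprintf("INS%03d", i),
        piece_index = length(pieces) - 1L,
        ltr5_len = length(cp$ltr5), internal_len = length(cp$internal),
        ltr3_len = length(cp$ltr3), degraded = isTRUE(attr(cp, "degraded")))
      prev <- p + cfg$tsd_length + 1L
    }
    pieces[[length(pieces) + 1L]] <- bg_g[seq2(prev, length(bg_g))]
    cum <- cumsum(c(0L, lengths(pieces)))
    coords <- bind_rows(rows)
    if (nrow(coords) > 0L) {
      coords <- coords |>
        mutate(start = cum[.data$piece_index] + 1L,
               end = cum[.data$piece_index + 1L])
    }
    v <- unlist(pieces, use.names = FALSE)
    if (cfg$indel_rate > 0) {
      # apply indels only outside planted elements so truth coordinates of the
      # elements themselves stay exact; flank/background divergence is the point
      v2 <- list()
      shift <- 0L
      prev2 <- 1L
      new_starts <- integer(nrow(coords)); new_ends <- integer(nrow(coords))
      if (nrow(coords) > 0L) {
        for (j in seq_len(nrow(coords))) {
          seg <- v[seq2(prev2, coords$start[j] - 1L)]
          seg <- apply_indels(seg, cfg$indel_rate)
          v2[[length(v2) + 1L]] <- seg
          new_starts[j] <- sum(lengths(v2)) + 1L
          v2[[length(v2) + 1L]] <- v[seq2(coords$start[j], coords$end[j])]
          new_ends[j] <- sum(lengths(v2))
          prev2 <- coords$end[j] + 1L
        }
      }
      v2[[length(v2) + 1L]] <- apply_indels(v[seq2(prev2, length(v))], cfg$indel_rate)
      v <- unlist(v2, use.names = FALSE)
      if (nrow(coords) > 0L) {
        coords$start <- new_starts
        coords$end <- new_ends
      }
    }
    list(seq = v, coords = coords)
  }

  asm_a <- assemble(bg_a, "A")
  asm_b <- assemble(bg_b, "B")

  element_rows <- function(asm, genome_label) {
    coords <- asm$coords
    if (nrow(coords) == 0L) {
      return(tibble(element_id = character(0), insertion_id = character(0),
                    sequence_id = character(0), start = integer(0), end = integer(0),
                    ltr5_start = integer(0), ltr5_end = integer(0),
                    ltr3_start = integer(0), ltr3_end = integer(0),
                    internal_start = integer(0), internal_end = integer(0),
                    degraded = logical(0)))
    }
    coords |>
      mutate(element_id = sprintf("%s_%s", genome_label, .data$insertion_id),
             sequence_id = "chr1",
             ltr5_start = .data$start, ltr5_end = .data$start + .data$ltr5_len - 1L,
             internal_start = .data$ltr5_end + 1L,
             internal_end = .data$internal_start + .data$internal_len - 1L,
             ltr3_start = .data$internal_end + 1L,
             ltr3_end = .data$ltr3_start + .data$ltr3_len - 1L) |>
      select("element_id", "insertion_id", "sequence_id", "start", "end",
             "ltr5_start", "ltr5_end", "internal_start", "internal_end",
             "ltr3_start", "ltr3_end", "degraded")
  }

  els_a <- element_rows(asm_a, "A")
  els_b <- element_rows(asm_b, "B")

  ins_meta <- tibble(insertion_id = sprintf("INS%03d", seq_len(n_ins)),
                     family_id = fams,
                     superfamily = map_chr(consensi[fams], "superfamily"),
                     fate = fates, true_age_mya = ages, site_ancestral = sites)

  truth <- ins_meta |>
    left_join(els_a |> select("insertion_id",
                              start_a = "start", end_a = "end",
                              degraded_a = "degraded"), by = "insertion_id") |>
    left_join(els_b |> select("insertion_id",
                              start_b = "start", end_b = "end",
                              degraded_b = "degraded"), by = "insertion_id") |>
    mutate(element_id_a = if_else(is.na(.data$start_a), NA_character_,
                                  paste0("A_", .data$insertion_id)),
           element_id_b = if_else(is.na(.data$start_b), NA_character_,
                                  paste0("B_", .data$insertion_id)))

  # annotated elements: intact copies only (degraded remnants stay in truth)
  annot <- function(els) {
    els |> filter(!.data$degraded) |> select(-"degraded")
  }

  # domain spans are element-relative: offset by the internal region start
  domain_tbl <- function(els) {
    if (nrow(els) == 0L) {
      return(tibble(element_id = character(0), domain = character(0),
                    start = integer(0), end = integer(0), strand = character(0)))
    }
    purrr::pmap(els |> left_join(ins_meta, by = "insertion_id") |>
                  select("element_id", "family_id", "internal_start", "start"),
                function(element_id, family_id, internal_start, start) {
                  off <- internal_start - start
                  consensi[[family_id]]$domains |>
                    mutate(element_id = element_id,
                           start = .data$start + off, end = .data$end + off) |>
                    select("element_id", "domain", "start", "end", "strand")
                }) |> list_rbind()
  }

  to_dss <- function(v) {
    s <- Biostrings::DNAStringSet(int_to_dna(v))
    names(s) <- "chr1"
    s
  }

  # N regions are the NA runs of the assembled sequence; reading them back
  # from the final coordinates is exact even under the indel mode
  n_reg_coords <- function(v) {
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    tibble(sequence_id = rep("chr1", sum(keep)),
           start = starts[keep], end = ends[keep])
  }

  sim <- structure(list(
    genome_a = to_dss(asm_a$seq), genome_b = to_dss(asm_b$seq),
    elements_a = annot(els_a), elements_b = annot(els_b),
    domains_a = domain_tbl(annot(els_a)), domains_b = domain_tbl(annot(els_b)),
    truth = truth,
    n_regions_a = n_reg_coords(asm_a$seq),
    n_regions_b = n_reg_coords(asm_b$seq),
    consensi = consensi,
    config = cfg), class = "ltr_sim")
  sim
}

# Remove a central chunk of an element copy, keeping `keep_frac` of the total
# length at each end; marks the copy as degraded.
degrade_copy <- function(cp, keep_frac) {
  full <- c(cp$ltr5, cp$internal, cp$ltr3)
  n <- length(full)
  keep <- max(50L, as.integer(round(n * keep_frac)))
  remnant_left <- full[seq_len(keep)]
  remnant_right <- full[seq2(n - keep + 1L, n)]
  out <- list(ltr5 = remnant_left, internal = integer(0), ltr3 = remnant_right)
  attr(out, "degraded") <- TRUE
  out
}

#' @export
print.ltr_sim <- function(x, ...) {
  cat("<ltr_sim>", sum(x$config$fate_counts), "insertions,",
      x$config$n_families, "families, split", x$config$split_mya, "Mya\n")
  cat("  genome A:", length(x$genome_a[[1]]), "bp,",
      nrow(x$elements_a), "intact elements\n")
  cat("  genome B:", length(x$genome_b[[1]]), "bp,",
      nrow(x$elements_b), "intact elements\n")
  invisible(x)
}

#' Simulate dated LTR pairs
#'
#' Generates pairs of LTR sequences that were identical `age_mya` million
#' years ago and have each accumulated substitutions independently since,
#' under the same K2P process the genome simulator uses. Useful for
#' calibration studies of the insertion-dating estimator. The pairs contain
#' no indels, so each pair is also a valid gap-free alignment.
#'
#' @param ages_mya Numeric vector of true ages (one pair per entry).
#' @param ltr_length LTR length in bp.
#' @param rate Substitution rate per site per year.
#' @param kappa Transition/transversion rate ratio.
#' @param gc_content GC content of the ancestral LTR.
#' @return Tibble: `true_age_mya`, `ltr5`, `ltr3` (character sequences).
#' @export
simulate_dated_ltrs <- function(ages_mya, ltr_length = 1000L, rate = 1e-8,
                                kappa = 2, gc_content = 0.38) {
  rows <- map(ages_mya, function(a) {
    anc <- random_int_seq(ltr_length, gc_content)
    tibble(true_age_mya = a,
           ltr5 = int_to_dna(mutate_k2p(anc, a * 1e6, rate, kappa)),
           ltr3 = int_to_dna(mutate_k2p(anc, a * 1e6, rate, kappa)))
  })
  list_rbind(rows)
}

#' Simulate cohort deletion calls over reference insertions
#'
#' Emulates the evidence structure of resequenced cultivar cohorts: each
#' annotated reference insertion is assigned an allele frequency; cultivars
#' not carrying it yield a deletion call spanning the element with
#' Poisson-distributed supporting reads. Spurious deletion calls are added at
#' `noise_rate` to model caller noise.
#'
#' @param sim An `ltr_sim` from [simulate_genome_pair()].
#' @param genome `"A"` or `"B"`: which genome's insertions the cohort is
#'   resequenced against.
#' @param cohort_size Number of cultivars.
#' @param allele_freq Either a tibble with columns `freq` and `prob` (sampled
#'   per insertion) or a function taking the truth tibble and returning one
#'   frequency per insertion.
#' @param noise_rate Expected number of spurious deletion calls per cultivar,
#'   as a fraction of the number of insertions.
#' @param support_mean Mean supporting reads per true call (Poisson).
#' @return A list of class `ltr_cohort`: `calls` (tibble of deletion calls:
#'   `call_id`, `cultivar_id`, `sequence_id`, `start`, `end`,
#'   `support_reads`, `spurious`), `presence` (insertion x cultivar logical
#'   matrix as a long tibble), `allele_freq` (per-insertion frequency),
#'   `cohort` (cultivar ids).
#' @export
simulate_cohort <- function(sim, genome = c("A", "B"), cohort_size = 10L,
                            allele_freq = tibble(freq = c(1, 0.9, 0.5),
                                                 prob = c(0.7, 0.15, 0.15)),
                            noise_rate = 0.05, support_mean = 40) {
  genome <- match.arg(genome)
  els <- if (genome == "A") sim$elements_a else sim$elements_b
  gseq <- if (genome == "A") sim$genome_a else sim$genome_b
  glen <- length(gseq[[1]])
  cohort <- sprintf("cv%02d", seq_len(cohort_size))
  truth <- sim$truth |> filter(.data$insertion_id %in% els$insertion_id)
  truth <- truth[match(els$insertion_id, truth$insertion_id), ]
  if (is.function(allele_freq)) {
    af <- allele_freq(truth)
  } else {
    af <- sample(allele_freq$freq, nrow(els), replace = TRUE, prob = allele_freq$prob)
  }
  stopifnot(length(af) == nrow(els), all(af >= 0 & af <= 1))
  pres <- matrix(stats::runif(nrow(els) * cohort_size) < rep(af, cohort_size),
                 nrow = nrow(els))
  calls <- list()
  for (j in seq_len(cohort_size)) {
    absent <- which(!pres[, j])
    if (length(absent) > 0L) {
      calls[[length(calls) + 1L]] <- tibble(
        cultivar_id = cohort[j],
        sequence_id = els$sequence_id[absent],
        start = els$start[absent], end = els$end[absent],
        support_reads = stats::rpois(length(absent), support_mean),
        spurious = FALSE)
    }
    n_spur <- stats::rpois(1L, noise_rate * nrow(els))
    if (n_spur > 0L) {
      slen <- pmax(60L, as.integer(round(stats::rlnorm(n_spur, log(800), 1))))
      sstart <- sample.int(glen - max(slen) - 1L, n_spur)
      calls[[length(calls) + 1L]] <- tibble(
        cultivar_id = cohort[j], sequence_id = names(gseq)[1],
        start = sstart, end = sstart + slen - 1L,
        support_reads = stats::rpois(n_spur, support_mean),
        spurious = TRUE)
    }
  }
  calls <- bind_rows(calls)
  if (nrow(calls) > 0L) {
    calls <- calls |> mutate(call_id = sprintf("DEL%05d", row_number()), .before = 1)
  } else {
    calls <- tibble(call_id = character(0), cultivar_id = character(0),
                    sequence_id = character(0), start = integer(0),
                    end = integer(0), support_reads = integer(0),
                    spurious = logical(0))
  }
  presence <- tibble(
    element_id = rep(els$element_id, cohort_size),
    cultivar_id = rep(cohort, each = nrow(els)),
    present = as.vector(pres))
  structure(list(calls = calls, presence = presence,
                 allele_freq = tibble(element_id = els$element_id, freq = af),
                 cohort = cohort, genome = genome),
            class = "ltr_cohort")
}
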