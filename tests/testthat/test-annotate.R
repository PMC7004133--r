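test_that("structural detector recovers planted young elements with high precision", {
  sim <- small_sim()
  det <- detect_ltr_candidates(sim$genome_a)
  planted <- sim$truth |> dplyr::filter(!is.na(start_a))
  hit_planted <- vapply(seq_len(nrow(det)), function(i) {
    any(abs(det$start[i] - planted$start_a) <= 10 &
          abs(det$end[i] - planted$end_a) <= 10)
  }, logical(1))
  expect_gte(mean(hit_planted), 0.9)

  # recall over intact elements whose expected LTR divergence is <= 10%
  tr <- sim_truth_elements(sim, "A")
  young <- tr |> dplyr::filter(2 * 1e-2 * true_age_mya <= 0.10)
  recalled <- vapply(seq_len(nrow(young)), function(i) {
    any(abs(det$start - young$start[i]) <= 5 & abs(det$end - young$end[i]) <= 5)
  }, logical(1))
  expect_gte(mean(recalled), 0.9)
})

test_that("detector returns nothing on repeat-free sequence", {
  set.seed(31)
  expect_equal(nrow(detect_ltr_candidates(c(chr = random_dna(50000)))), 0L)
})

test_that("detector skips repeat pairs below the identity floor", {
  set.seed(32)
  ltr <- random_dna(400)
  ltr_div <- mutate_subs(ltr, 0.30)
  tsd <- random_dna(5)
  genome <- c(chr = paste0(random_dna(3000), tsd, ltr, random_dna(1500),
                           ltr_div, tsd, random_dna(3000)))
  expect_equal(nrow(detect_ltr_candidates(genome)), 0L)
})

test_that("element filters apply the coding, gap, tandem and single-hit rules", {
  sim <- small_sim()
  els <- sim$elements_a
  doms <- sim$domains_a
  res <- filter_elements(els, sim$genome_a, doms)
  # planted elements are coding, clean, multi-copy: all kept
  expect_true(all(res$kept))
  expect_true(all(is.na(res$reject_reason)))

  # kept/rejected partitions the input and the filter is idempotent
  expect_setequal(res$element_id, els$element_id)
  res2 <- filter_elements(res |> dplyr::select(dplyr::all_of(names(els))),
                          sim$genome_a, doms)
  expect_equal(res2$kept, res$kept)

  # non-coding rejection
  res3 <- filter_elements(els, sim$genome_a, doms |> dplyr::filter(element_id != els$element_id[1]))
  expect_false(res3$kept[res3$element_id == els$element_id[1]])
  expect_equal(res3$reject_reason[res3$element_id == els$element_id[1]], "non_coding")

  expect_error(filter_elements(els, sim$genome_a,
                               doms |> dplyr::mutate(element_id = paste0(element_id, "_x"))),
               class = "ltrdyn_input_error")
})

test_that("gap-rich and tandem-repeat bodies are rejected with the right reason", {
  set.seed(33)
  el_seq <- paste0(random_dna(500), strrep("N", 120), random_dna(180))  # 15% N
  ms_seq <- strrep("AT", 400)                                           # pure microsatellite
  ok_seq <- random_dna(800)
  genome <- c(chr = paste0(ok_seq, el_seq, ms_seq, ok_seq))
  els <- tibble::tibble(element_id = c("e_gap", "e_tandem"), sequence_id = "chr",
                        start = c(801L, 1601L), end = c(1600L, 2400L))
  doms <- tibble::tibble(element_id = c("e_gap", "e_tandem"), domain = "RT",
                         start = 10L, end = 50L, strand = "+")
  res <- filter_elements(els, genome, doms)
  expect_equal(res$reject_reason[res$element_id == "e_gap"], "gap_fraction")
  expect_equal(res$reject_reason[res$element_id == "e_tandem"], "tandem_fraction")
})

test_that("an element without a second 80/80 genomic copy is a single hit", {
  set.seed(34)
  body <- random_dna(1200)
  copy <- mutate_subs(body, 0.05)
  genome1 <- c(chr = paste0(random_dna(5000), body, random_dna(5000)))
  genome2 <- c(chr = paste0(random_dna(5000), body, random_dna(5000), copy,
                            random_dna(5000)))
  els <- tibble::tibble(element_id = "e1", sequence_id = "chr",
                        start = 5001L, end = 6200L)
  doms <- tibble::tibble(element_id = "e1", domain = "RT", start = 10L,
                         end = 50L, strand = "+")
  expect_equal(filter_elements(els, genome1, doms)$reject_reason, "single_hit")
  expect_true(filter_elements(els, genome2, doms)$kept)
})

test_that("superfamily classification follows internal domain order and strand", {
  els <- tibble::tibble(element_id = c("c", "g", "r"), sequence_id = "chr",
                        start = 1L, end = 5000L)
  mk <- function(id, doms, strand = "+") {
    tibble::tibble(element_id = id, domain = doms,
                   start = seq(500, by = 300, length.out = length(doms)),
                   end = seq(700, by = 300, length.out = length(doms)),
                   strand = strand)
  }
  hits <- dplyr::bind_rows(
    mk("c", c("GAG", "PR", "INT", "RT", "RH")),
    mk("g", c("GAG", "PR", "RT", "RH", "INT")),
    mk("r", "RT"))
  out <- classify_superfamily(els, hits)
  expect_equal(out$superfamily[match(c("c", "g", "r"), out$element_id)],
               c("Copia", "Gypsy", "unclassified"))
  expect_equal(out$completeness[match(c("c", "g", "r"), out$element_id)],
               c("complete", "complete", "incomplete"))

  # a minus-strand Copia has its domains mirrored in genome coordinates
  hits_minus <- mk("c", c("RH", "RT", "INT", "PR", "GAG"), strand = "-")
  out_minus <- classify_superfamily(els[1, ], hits_minus)
  expect_equal(out_minus$superfamily, "Copia")
})

test_that("MITE full-length filter keeps the closed +-20% band", {
  copies <- tibble::tibble(family_id = "m1", sequence_id = "chr", start = 1L,
                           end = 1L, consensus_length = 300L,
                           copy_length = c(290L, 239L, 240L, 360L, 361L))
  kept <- mite_full_length_filter(copies)
  expect_setequal(kept$copy_length, c(290L, 240L, 360L))
})
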