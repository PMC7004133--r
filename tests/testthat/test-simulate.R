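test_that("the simulator is reproducible and honours its fate counts", {
  cfg <- sim_config(seed = 91L, genome_length = 2e5, n_families = 2L,
                    fate_counts = c(conserved = 4L, specific_A = 4L,
                                    specific_B = 4L, partial_A_in_B = 2L,
                                    partial_B_in_A = 2L))
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(as.character(s1$genome_a), as.character(s2$genome_a))
  expect_identical(s1$truth, s2$truth)
  expect_equal(unname(table(s1$truth$fate)[names(cfg$fate_counts)]),
               unname(cfg$fate_counts), ignore_attr = TRUE)
  # lineage assignment: shared fates predate the split, specific ones postdate it
  shared <- s1$truth$fate %in% c("conserved", "partial_A_in_B", "partial_B_in_A")
  expect_true(all(s1$truth$true_age_mya[shared] > 5.88))
  expect_true(all(s1$truth$true_age_mya[!shared] < 5.88))
})

test_that("genome length equals ancestral length plus inserted bases", {
  cfg <- sim_config(seed = 92L, genome_length = 2e5, n_families = 2L,
                    fate_counts = c(conserved = 3L, specific_A = 3L,
                                    specific_B = 3L, partial_A_in_B = 2L,
                                    partial_B_in_A = 2L))
  sim <- simulate_genome_pair(cfg)
  tr <- sim$truth
  ins_a <- sum(tr$end_a - tr$start_a + 1L, na.rm = TRUE) +
    cfg$tsd_length * sum(!is.na(tr$start_a))
  expect_equal(Biostrings::width(sim$genome_a)[[1]], cfg$genome_length + ins_a)
  ins_b <- sum(tr$end_b - tr$start_b + 1L, na.rm = TRUE) +
    cfg$tsd_length * sum(!is.na(tr$start_b))
  expect_equal(Biostrings::width(sim$genome_b)[[1]], cfg$genome_length + ins_b)
})

test_that("with no insertions the genomes differ only by background divergence", {
  cfg <- sim_config(seed = 93L, genome_length = 2e5, n_families = 1L,
                    n_region_count = 0L,
                    fate_counts = c(conserved = 0L, specific_A = 0L,
                                    specific_B = 0L, partial_A_in_B = 0L,
                                    partial_B_in_A = 0L))
  sim <- simulate_genome_pair(cfg)
  a <- strsplit(as.character(sim$genome_a[[1]]), "")[[1]]
  b <- strsplit(as.character(sim$genome_b[[1]]), "")[[1]]
  expect_length(a, cfg$genome_length)
  p_diff <- mean(a != b)
  # expected raw divergence after 2 * 5.88 My of K2P drift at 1e-8/site/year,
  # slightly under 2 r t because of multiple hits: 1 - exp-based closed form
  t <- 2 * 5.88e6
  beta <- 1e-8 / 4; alpha <- 1e-8 / 2
  exp_diff <- (0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)) +
    (0.5 - 0.5 * exp(-4 * beta * t))
  se <- sqrt(exp_diff * (1 - exp_diff) / cfg$genome_length)
  expect_lt(abs(p_diff - exp_diff), 3 * se)
})

test_that("planted elements round-trip: annotation extracts to LTRs dating to their true age", {
  sim <- small_sim()
  ages <- date_elements(sim$elements_a, sim$genome_a)
  tr <- dplyr::inner_join(ages, sim$truth, by = c(element_id = "element_id_a"))
  ltr_len <- sim$config$ltr_length
  for (i in seq_len(nrow(tr))) {
    K_true <- 2 * 1e-8 * tr$true_age_mya[i] * 1e6
    # binomial CI on the substitution count at the LTR length
    se_K <- sqrt(K_true / ltr_len) * 1.3  # slack for the K2P correction
    expect_lt(abs(tr$K[i] - K_true), 4 * se_K + 0.01)
  }
})

test_that("emitted files parse cleanly with the package readers", {
  sim <- cached_sim("io", sim_config(seed = 94L, genome_length = 2e5,
                                     n_families = 2L,
                                     fate_counts = c(conserved = 3L, specific_A = 3L,
                                                     specific_B = 3L,
                                                     partial_A_in_B = 1L,
                                                     partial_B_in_A = 1L)))
  dir <- withr::local_tempdir()
  expect_no_warning(write_sim(sim, dir))
  g <- as_genome(file.path(dir, "genome_A.fa"))
  expect_equal(as.character(g), as.character(sim$genome_a))
  els <- read_elements_gff3(file.path(dir, "elements_A.gff3"))
  expect_equal(nrow(els), nrow(sim$elements_a))
  expect_equal(els$start, sim$elements_a$start)
  expect_equal(els$ltr3_end, sim$elements_a$ltr3_end)
})

test_that("cohort simulation matches its allele-frequency model", {
  sim <- small_sim()
  set.seed(95)
  coh1 <- simulate_cohort(sim, "A", cohort_size = 10L,
                          allele_freq = tibble::tibble(freq = 1, prob = 1),
                          noise_rate = 0)
  expect_equal(nrow(coh1$calls), 0L)
  expect_true(all(coh1$presence$present))

  coh2 <- simulate_cohort(sim, "A", cohort_size = 10L,
                          allele_freq = tibble::tibble(freq = 0.5, prob = 1),
                          noise_rate = 0)
  n_el <- nrow(sim$elements_a)
  n_abs <- sum(!coh2$presence$present)
  expect_lt(abs(n_abs - 0.5 * n_el * 10), 3 * sqrt(n_el * 10 * 0.25))

  # noise-free: presence matrix reconstructable from the emitted VCFs
  dir <- withr::local_tempdir()
  write_cohort(coh2, dir)
  calls <- purrr::map(coh2$cohort, function(cv) {
    read_deletion_vcf(file.path(dir, paste0(cv, ".deletions.vcf")), cultivar_id = cv)
  }) |> purrr::list_rbind()
  absent_pairs <- calls |>
    dplyr::inner_join(sim$elements_a, by = c("sequence_id", "start", "end")) |>
    dplyr::select(element_id, cultivar_id) |>
    dplyr::arrange(element_id, cultivar_id)
  want <- coh2$presence |>
    dplyr::filter(!present) |>
    dplyr::select(element_id, cultivar_id) |>
    dplyr::arrange(element_id, cultivar_id)
  expect_equal(as.data.frame(absent_pairs), as.data.frame(want))
})

test_that("infeasible packing raises a configuration error", {
  cfg <- sim_config(seed = 96L, genome_length = 3e4, n_families = 1L,
                    fate_counts = c(conserved = 30L, specific_A = 0L,
                                    specific_B = 0L, partial_A_in_B = 0L,
                                    partial_B_in_A = 0L))
  expect_error(simulate_genome_pair(cfg), class = "ltrdyn_config_error")
})
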