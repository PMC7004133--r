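mk_elements <- function(seqs, genome = "A") {
  # lay sequences head to tail on one chromosome per genome
  starts <- cumsum(c(1L, head(nchar(seqs), -1)))
  tibble::tibble(element_id = sprintf("%s_e%02d", genome, seq_along(seqs)),
                 genome = genome, sequence_id = "chr",
                 start = starts, end = starts + nchar(seqs) - 1L)
}

test_that("80/80 edges require both strict thresholds", {
  set.seed(51)
  s1 <- random_dna(1000)
  s2 <- s1                       # identical
  s3 <- mutate_subs(s1, 0.30)    # ~70% identity: no edge
  els <- mk_elements(c(s1, s2, s3))
  genomes <- list(A = c(chr = paste0(s1, s2, s3)))
  edges <- pairwise_8080_edges(els, genomes)
  expect_equal(nrow(edges), 1L)
  expect_setequal(c(edges$from, edges$to), c("A_e01", "A_e02"))
})

test_that("within-family pairs edge, cross-family pairs do not", {
  set.seed(52)
  fam1 <- random_dna(1200)
  fam2 <- mutate_subs(fam1, 0.40)
  seqs <- c(fam1, mutate_subs(fam1, 0.05), mutate_subs(fam1, 0.05),
            fam2, mutate_subs(fam2, 0.05))
  els <- mk_elements(seqs)
  genomes <- list(A = c(chr = paste(seqs, collapse = "")))
  edges <- pairwise_8080_edges(els, genomes)
  fam1_ids <- els$element_id[1:3]
  in_fam1 <- edges$from %in% fam1_ids & edges$to %in% fam1_ids
  fam2_ids <- els$element_id[4:5]
  in_fam2 <- edges$from %in% fam2_ids & edges$to %in% fam2_ids
  expect_true(all(in_fam1 | in_fam2))
  expect_equal(sum(in_fam1), 3L)  # all three within-family pairs
})

test_that("single-linkage components equal a union-find oracle on random graphs", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    ids <- sprintf("n%02d", 1:n)
    n_edges <- sample(0:(2 * n), 1)
    from <- sample(ids, n_edges, replace = TRUE)
    to <- sample(ids, n_edges, replace = TRUE)
    keep <- from != to
    edges <- tibble::tibble(from = from[keep], to = to[keep])
    els <- tibble::tibble(element_id = ids, genome = "A")
    got <- cluster_single_linkage(els, edges)
    want <- oracle_components(ids, edges$from, edges$to)
    # compare partitions: same component label pattern
    got_lab <- got$cluster_id
    got_lab[is.na(got_lab)] <- got$element_id[is.na(got_lab)]
    expect_equal(as.integer(factor(got_lab, levels = unique(got_lab))),
                 as.integer(factor(want[ids], levels = unique(want[ids]))))
  }
})

test_that("edge transitivity merges chains and no edges means no clusters", {
  els <- tibble::tibble(element_id = c("a", "b", "c", "d"), genome = "A")
  cl <- cluster_single_linkage(els, tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  expect_equal(length(unique(na.omit(cl$cluster_id))), 1L)
  expect_true(is.na(cl$cluster_id[cl$element_id == "d"]))

  cl0 <- cluster_single_linkage(els, tibble::tibble(from = character(0), to = character(0)))
  expect_true(all(is.na(cl0$cluster_id)))
})

test_that("clustering is invariant to input order", {
  set.seed(54)
  base <- random_dna(1000)
  seqs <- c(base, mutate_subs(base, 0.1), mutate_subs(base, 0.1), random_dna(1000))
  els <- mk_elements(seqs)
  genomes <- list(A = c(chr = paste(seqs, collapse = "")))
  edges <- pairwise_8080_edges(els, genomes)
  cl1 <- cluster_single_linkage(els, edges)
  perm <- c(3, 1, 4, 2)
  cl2 <- cluster_single_linkage(els[perm, ], edges)
  expect_equal(cl2$cluster_id[match(els$element_id, cl2$element_id)],
               cl1$cluster_id)
})

test_that("fast 80/80 clustering matches the exhaustive edge route", {
  sim <- small_sim()
  pooled <- dplyr::bind_rows(dplyr::mutate(sim$elements_a, genome = "A"),
                             dplyr::mutate(sim$elements_b, genome = "B"))
  pooled <- pooled[seq_len(min(20L, nrow(pooled))), ]
  genomes <- list(A = sim$genome_a, B = sim$genome_b)
  fast <- cluster_elements_8080(pooled, genomes)
  full <- cluster_single_linkage(pooled, pairwise_8080_edges(pooled, genomes))
  expect_equal(fast$clustered$cluster_id, full$cluster_id)
})

test_that("cluster statistics report fractions, mixed clusters and age medians", {
  clustered <- tibble::tibble(
    element_id = sprintf("e%02d", 1:10),
    genome = rep(c("A", "B"), each = 5),
    cluster_id = c("c1", "c1", "c2", "c2", NA, "c1", "c1", NA, NA, NA))
  ages <- tibble::tibble(element_id = clustered$element_id,
                         age_mya = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                         status = "dated")
  rep <- cluster_stats(clustered, ages)
  g <- glance(rep)
  expect_equal(g$fraction_clustered, 0.6)
  expect_equal(g$n_clusters, 2L)
  expect_equal(g$n_mixed, 1L)            # c1 has A and B members, c2 only A
  expect_equal(g$fraction_mixed, 0.5)
  expect_equal(g$fraction_clustered_in_mixed, 4 / 6)
  per <- tidy(rep)
  expect_equal(per$median_age_1[per$cluster_id == "c1"], median(c(1, 2)))
  expect_equal(per$median_age_2[per$cluster_id == "c1"], median(c(6, 7)))
})

test_that("a one-genome burst family forms a young unmixed cluster", {
  set.seed(55)
  fam_shared <- random_dna(1000)
  fam_burst <- random_dna(1000)
  seqs_a <- c(fam_shared, mutate_subs(fam_shared, 0.08))
  seqs_b <- c(mutate_subs(fam_shared, 0.08),
              fam_burst, mutate_subs(fam_burst, 0.02), mutate_subs(fam_burst, 0.02))
  els <- dplyr::bind_rows(mk_elements(seqs_a, "A"), mk_elements(seqs_b, "B"))
  genomes <- list(A = c(chr = paste(seqs_a, collapse = "")),
                  B = c(chr = paste(seqs_b, collapse = "")))
  cl <- cluster_elements_8080(els, genomes)$clustered
  rep <- cluster_stats(cl)
  burst_ids <- els$element_id[els$genome == "B"][2:4]
  burst_cluster <- unique(cl$cluster_id[cl$element_id %in% burst_ids])
  expect_length(burst_cluster, 1L)
  expect_false(tidy(rep)$is_mixed[tidy(rep)$cluster_id == burst_cluster])
})
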