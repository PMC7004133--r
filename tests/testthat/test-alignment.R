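test_that("global alignment handles identity and forced-mismatch cases", {
  a <- align_global("ACGT", "ACGT")
  expect_equal(a$aligned_query, "ACGT")
  expect_equal(a$aligned_target, "ACGT")
  ic <- identity_coverage(a)
  expect_equal(unname(ic["identity"]), 1.0)
  expect_equal(unname(ic["coverage"]), 1.0)

  b <- align_global("ACGT", "AGGT")
  expect_equal(unname(identity_coverage(b)["identity"]), 0.75)
  expect_equal(b$score, 3 * 2 - 3)

  expect_error(align_global("", "ACGT"), class = "ltrdyn_input_error")
})

test_that("alignment score matches an independent affine-gap oracle", {
  set.seed(11)
  for (i in 1:30) {
    n1 <- sample(40:120, 1)
    a <- random_dna(n1)
    b <- if (i %% 3 == 0) random_dna(sample(40:120, 1)) else mutate_subs(a, 0.15)
    expect_equal(align_global(a, b)$score, oracle_align_score(a, b))
  }
})

test_that("alignment score is symmetric under argument swap", {
  set.seed(12)
  for (i in 1:10) {
    a <- random_dna(80)
    b <- mutate_subs(a, 0.2)
    expect_equal(align_global(a, b)$score, align_global(b, a)$score)
  }
})

test_that("K2P distance follows the closed form and flags saturation", {
  # identical sequences
  res0 <- k2p_distance(c("ACGTACGT", "ACGTACGT"))
  expect_equal(res0$P, 0)
  expect_equal(res0$Q, 0)
  expect_equal(res0$K, 0)

  # P = 0.1, Q = 0.05 built from exact counts over 100 columns:
  # K = -1/2 ln((1-2*0.1-0.05) sqrt(1-2*0.05)) = 0.1701812...
  base <- strrep("A", 100)
  mut <- c(rep("G", 10), rep("C", 5), rep("A", 85))  # 10 transitions, 5 transversions
  res <- k2p_distance(c(base, paste(mut, collapse = "")))
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0.05)
  expect_equal(res$K, oracle_k2p(0.1, 0.05), tolerance = 1e-12)
  expect_equal(res$K, 0.1701812, tolerance = 1e-6)

  # P = 0.45, Q = 0.25: 1 - 2P - Q < 0
  mut2 <- c(rep("G", 45), rep("C", 25), rep("A", 30))
  expect_error(k2p_distance(c(base, paste(mut2, collapse = ""))),
               class = "ltrdyn_saturation_error")
  # all-N comparison has no usable columns
  expect_error(k2p_distance(c("NNNN", "ACGT")), class = "ltrdyn_input_error")
})

test_that("K2P is symmetric, never below P+Q, and linear in the small-distance limit", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_dna(500)
    b <- mutate_subs(a, runif(1, 0.01, 0.2))
    r1 <- k2p_distance(c(a, b))
    r2 <- k2p_distance(c(b, a))
    expect_equal(r1$K, r2$K)
    expect_gte(r1$K, r1$P + r1$Q)
  }
  # Taylor limit: K -> P + Q as divergence -> 0 (within 1% at P+Q <= 1e-3)
  n <- 10000
  a <- strrep("A", n)
  b <- paste(c(rep("G", 6), rep("C", 4), rep("A", n - 10)), collapse = "")
  r <- k2p_distance(c(a, b))
  expect_lte(abs(r$K - (r$P + r$Q)) / (r$P + r$Q), 0.01)
})

test_that("K2P ignores gap and N columns", {
  r <- k2p_distance(c("AC-GTN", "ACCGTA"))
  expect_equal(r$compared_sites, 4L)
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)
})

test_that("map_flank recovers planted queries on both strands", {
  set.seed(21)
  bg <- random_dna(20000)
  q <- random_dna(300)
  genome <- c(chr = paste0(substr(bg, 1, 5000), q, substr(bg, 5001, 20000)))
  hits <- map_flank(q, genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 5001L)
  expect_equal(hits$end, 5300L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$strand, "+")

  # planted at two loci
  genome2 <- c(chr = paste0(substr(bg, 1, 5000), q, substr(bg, 5001, 12000),
                            q, substr(bg, 12001, 20000)))
  expect_equal(nrow(map_flank(q, genome2)), 2L)

  # reverse-complement planting recovers the forward locus coordinates
  qrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  genome3 <- c(chr = paste0(substr(bg, 1, 5000), qrc, substr(bg, 5001, 20000)))
  hits3 <- map_flank(q, genome3)
  expect_equal(nrow(hits3), 1L)
  expect_equal(hits3$strand, "-")
  expect_equal(hits3$start, 5001L)
  expect_equal(hits3$end, 5300L)

  expect_error(map_flank(q, Biostrings::DNAStringSet(c(chr = ""))),
               class = "ltrdyn_input_error")
})

test_that("map_flank locates a diverged 500-nt query within a few bp", {
  set.seed(22)
  bg <- random_dna(50000)
  q <- random_dna(500)
  planted <- mutate_subs(q, 0.05)
  genome <- c(chr = paste0(substr(bg, 1, 30000), planted, substr(bg, 30001, 50000)))
  hits <- map_flank(q, genome)
  expect_gte(nrow(hits), 1L)
  expect_lte(abs(hits$start[1] - 30001L), 5L)
  expect_lte(abs(hits$end[1] - 30500L), 5L)
  expect_gt(hits$identity[1], 0.9)
})

test_that("identity and coverage match a brute-force column count", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_dna(100)
    keep <- sort(sample(100, sample(60:100, 1)))
    b <- paste(strsplit(mutate_subs(a, 0.1), "")[[1]][keep], collapse = "")
    aln <- align_global(a, b)
    qc <- strsplit(aln$aligned_query, "")[[1]]
    tc <- strsplit(aln$aligned_target, "")[[1]]
    both <- qc != "-" & tc != "-"
    expect_equal(unname(identity_coverage(aln)["identity"]),
                 sum(qc[both] == tc[both]) / sum(both))
    expect_equal(unname(identity_coverage(aln)["coverage"]),
                 sum(both) / max(nchar(a), nchar(b)))
  }
})
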