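test_that("deletion filtering enforces read support and N-region padding", {
  calls <- tibble::tibble(call_id = c("d1", "d2", "d3", "d4"),
                          cultivar_id = "cv01", sequence_id = "chr",
                          start = c(100L, 100L, 5500L, 9000L),
                          end = c(400L, 400L, 5800L, 9400L),
                          support_reads = c(19L, 20L, 40L, 40L))
  nreg <- tibble::tibble(sequence_id = "chr", start = 6300L, end = 7000L)
  kept <- filter_deletions(calls, nreg)
  # d1: 19 reads < 20; d3 ends 500 bp from the padded N region edge
  expect_setequal(kept$call_id, c("d2", "d4"))
})

test_that("deletion filtering matches a brute-force interval oracle", {
  set.seed(71)
  for (rep in 1:5) {
    calls <- tibble::tibble(
      call_id = sprintf("d%04d", 1:400), cultivar_id = "cv01",
      sequence_id = sample(c("c1", "c2"), 400, TRUE),
      start = sample(1:50000, 400, TRUE)) |>
      dplyr::mutate(end = start + sample(10:5000, 400, TRUE),
                    support_reads = sample(0:60, 400, TRUE))
    nreg <- tibble::tibble(sequence_id = sample(c("c1", "c2"), 6, TRUE),
                           start = sample(1:50000, 6)) |>
      dplyr::mutate(end = start + sample(100:2000, 6, TRUE))
    kept <- filter_deletions(calls, nreg, min_support = 20L, pad = 1000L)
    manual <- vapply(seq_len(nrow(calls)), function(i) {
      if (calls$support_reads[i] < 20) return(FALSE)
      nr <- nreg[nreg$sequence_id == calls$sequence_id[i], ]
      if (nrow(nr) == 0) return(TRUE)
      !any(calls$start[i] <= nr$end + 1000 & calls$end[i] >= nr$start - 1000)
    }, logical(1))
    expect_setequal(kept$call_id, calls$call_id[manual])
  }
})

test_that("the one-way 80% overlap rule is inclusive at its boundary and symmetric", {
  # 101-bp deletion vs 81-bp TE nested at its end: overlap = 81 >= 0.8*101 ... use
  # the canonical boundary: deletion of 100, TE covering exactly 80 of it
  expect_true(deletion_te_overlap(100L, 199L, 120L, 199L))   # overlap 80 = 0.8*100
  expect_false(deletion_te_overlap(100L, 199L, 150L, 400L))  # 50 of 100, 50 of 251
  # symmetric in the two intervals
  set.seed(72)
  for (i in 1:200) {
    a <- sort(sample(1:2000, 2)); b <- sort(sample(1:2000, 2))
    expect_equal(deletion_te_overlap(a[1], a[2], b[1], b[2]),
                 deletion_te_overlap(b[1], b[2], a[1], a[2]))
  }
})

test_that("one-way overlap matches a brute-force oracle on random pairs", {
  set.seed(73)
  n <- 2000
  a1 <- sample(1:5000, n, TRUE); a2 <- a1 + sample(0:500, n, TRUE)
  b1 <- sample(1:5000, n, TRUE); b2 <- b1 + sample(0:500, n, TRUE)
  got <- deletion_te_overlap(a1, a2, b1, b2)
  want <- vapply(seq_len(n), function(i) {
    ov <- length(intersect(a1[i]:a2[i], b1[i]:b2[i]))
    ov >= 0.8 * (a2[i] - a1[i] + 1) || ov >= 0.8 * (b2[i] - b1[i] + 1)
  }, logical(1))
  expect_equal(got, want)
})

test_that("fixed/polymorphic classification reconstructs the simulated cohort exactly", {
  sim <- small_sim()
  set.seed(74)
  coh <- simulate_cohort(sim, "A", cohort_size = 10L, noise_rate = 0,
                         support_mean = 60)
  kept <- filter_deletions(coh$calls, sim$n_regions_a)
  st <- classify_fixed_polymorphic(sim$elements_a, kept, coh$cohort)
  truth <- coh$presence |>
    dplyr::group_by(element_id) |>
    dplyr::summarise(absent = list(sort(cultivar_id[!present])), .groups = "drop")
  cmp <- dplyr::inner_join(st, truth, by = "element_id")
  expect_equal(cmp$status == "polymorphic", lengths(cmp$absent) > 0)
  expect_equal(cmp$absent_in, cmp$absent)
  # fixed/polymorphic partitions the input; absences bounded by cohort size
  expect_equal(nrow(st), nrow(sim$elements_a))
  expect_true(all(st$n_absent <= length(coh$cohort)))
  expect_error(classify_fixed_polymorphic(sim$elements_a, kept, character(0)),
               class = "ltrdyn_input_error")
})

test_that("an insertion with no overlapping deletion in any cultivar is fixed", {
  ins <- tibble::tibble(element_id = "e", sequence_id = "chr",
                        start = 1000L, end = 4000L)
  calls <- tibble::tibble(call_id = "d", cultivar_id = "cv01",
                          sequence_id = "chr", start = 50000L, end = 51000L,
                          support_reads = 40L)
  st <- classify_fixed_polymorphic(ins, calls, sprintf("cv%02d", 1:10))
  expect_equal(st$status, "fixed")
  expect_equal(st$n_absent, 0L)
})

test_that("size classes bin unique events and report TE overlap per class", {
  te <- tibble::tibble(sequence_id = "chr", start = 10000L, end = 18000L)
  calls <- tibble::tibble(
    call_id = sprintf("d%d", 1:6),
    cultivar_id = c("cv01", "cv02", "cv01", "cv01", "cv02", "cv01"),
    sequence_id = "chr",
    start = c(100L, 100L, 300L, 500L, 10000L, 60000L),
    end = c(149L, 149L, 350L, 1200L, 17999L, 125000L),
    support_reads = 40L)
  out <- size_class_summary(calls, te)
  sc <- out$size_classes
  expect_equal(sc$n_events[sc$size_class == "1-50"], 1L)    # 50 bp, deduplicated
  expect_equal(sc$n_events[sc$size_class == "51-500"], 1L)  # 51 bp
  expect_equal(sc$n_events[sc$size_class == "501-10000"], 2L)
  expect_equal(sc$n_events[sc$size_class == ">50000"], 1L)
  expect_equal(sc$pct_te_overlap[sc$size_class == "501-10000"], 50)
  expect_equal(out$n_unique_events, 5L)
  expect_equal(sum(sc$n_events), out$n_unique_events)
  expect_equal(out$per_cultivar$n_calls[out$per_cultivar$cultivar_id == "cv01"], 4L)
})

test_that("size-class table equals a direct recount on random cohorts", {
  set.seed(75)
  calls <- tibble::tibble(
    call_id = sprintf("d%04d", 1:300),
    cultivar_id = sample(sprintf("cv%02d", 1:5), 300, TRUE),
    sequence_id = "chr",
    start = sample(1:100000, 300, TRUE)) |>
    dplyr::mutate(end = start + sample(c(1:60, 100:800, 2000:12000), 300, TRUE) - 1L,
                  support_reads = 40L)
  te <- tibble::tibble(sequence_id = "chr", start = sample(1:100000, 30)) |>
    dplyr::mutate(end = start + sample(500:8000, 30, TRUE))
  out <- size_class_summary(calls, te)
  ev <- dplyr::distinct(calls, sequence_id, start, end)
  lens <- ev$end - ev$start + 1L
  class_of <- cut(lens, c(0, 50, 500, 10000, 50000, Inf),
                  labels = c("1-50", "51-500", "501-10000", "10001-50000", ">50000"))
  for (cl in levels(class_of)) {
    expect_equal(out$size_classes$n_events[out$size_classes$size_class == cl],
                 sum(class_of == cl))
  }
  expect_equal(sum(out$size_classes$n_events), nrow(ev))
})
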