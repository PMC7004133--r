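#' Pairwise 80/80 edges between elements of two genomes
#'
#' Emits an edge between two elements when the global alignment of their full
#' sequences shows identity strictly above `min_identity` over strictly more
#' than `min_coverage` of the longer sequence's length (the strict
#' inequalities follow the "higher than 80% ... more than 80%" family rule).
#' A shared-k-mer prefilter skips pairs that cannot possibly qualify, and
#' pairs whose length ratio is below `min_coverage` are skipped outright
#' since their coverage bound already fails.
#'
#' @param elements Tibble with `element_id`, `genome`, `sequence_id`,
#'   `start`, `end`; `genome` values index into `genomes`.
#' @param genomes Named list of genomes (e.g. `list(A = ..., B = ...)`).
#' @param min_identity,min_coverage Strict thresholds (default 0.8).
#' @param min_shared_kmers Prefilter: minimum distinct shared 13-mers.
#' @param params Alignment parameters.
#' @return Tibble of edges: `from`, `to`, `identity`, `coverage`.
#' @export
pairwise_8080_edges <- function(elements, genomes,
                                min_identity = 0.8, min_coverage = 0.8,
                                min_shared_kmers = 20L,
                                params = align_params()) {
  n <- nrow(elements)
  empty <- tibble(from = character(0), to = character(0),
                  identity = numeric(0), coverage = numeric(0))
  if (n < 2L) return(empty)
  genomes <- lapply(genomes, as_genome)
  seqs <- map_chr(seq_len(n), function(i) {
    extract_seq(genomes[[elements$genome[i]]], elements$sequence_id[i],
                elements$start[i], elements$end[i])
  })
  lens <- nchar(seqs)
  ksets <- map(seqs, function(s) unique(kmer_codes(s, 13L)))
  # candidate pairs share enough distinct k-mers
  km <- tibble(code = unlist(ksets),
               el = rep.int(seq_len(n), lengths(ksets))) |>
    group_by(.data$code) |>
    filter(n() > 1L) |>
    summarise(els = list(.data$el), .groups = "drop")
  if (nrow(km) == 0L) return(empty)
  pair_counts <- km$els |>
    map(function(e) {
      cmb <- utils::combn(sort(e), 2L)
      tibble(i = cmb[1L, ], j = cmb[2L, ])
    }) |>
    list_rbind() |>
    count(.data$i, .data$j, name = "shared") |>
    filter(.data$shared >= min_shared_kmers)
  if (nrow(pair_counts) == 0L) return(empty)
  edges <- list()
  for (p in seq_len(nrow(pair_counts))) {
    i <- pair_counts$i[p]; j <- pair_counts$j[p]
    if (min(lens[i], lens[j]) <= min_coverage * max(lens[i], lens[j])) next
    aln <- align_global(seqs[i], seqs[j], params = params)
    ic <- identity_coverage(aln)
    if (ic[["identity"]] > min_identity && ic[["coverage"]] > min_coverage) {
      edges[[length(edges) + 1L]] <- tibble(
        from = elements$element_id[i], to = elements$element_id[j],
        identity = ic[["identity"]], coverage = ic[["coverage"]])
    }
  }
  if (length(edges) == 0L) return(empty)
  bind_rows(edges)
}

#' Cluster elements under the 80/80 rule (single linkage)
#'
#' Drives [pairwise_8080_edges()] logic and [cluster_single_linkage()]
#' together, exploiting that single linkage only needs graph connectivity:
#' candidate pairs are tested in decreasing shared-k-mer order and a pair
#' whose members already share a component is skipped without aligning. The
#' resulting partition is identical to clustering the full edge list.
#'
#' @inheritParams pairwise_8080_edges
#' @return A list: `clustered` (elements with `cluster_id`) and `edges`
#'   (the evaluated edges).
#' @export
cluster_elements_8080 <- function(elements, genomes,
                                  min_identity = 0.8, min_coverage = 0.8,
                                  min_shared_kmers = 20L,
                                  params = align_params()) {
  n <- nrow(elements)
  empty <- tibble(from = character(0), to = character(0),
                  identity = numeric(0), coverage = numeric(0))
  if (n < 2L) {
    return(list(clustered = elements |> mutate(cluster_id = NA_character_),
                edges = empty))
  }
  genomes <- lapply(genomes, as_genome)
  seqs <- map_chr(seq_len(n), function(i) {
    extract_seq(genomes[[elements$genome[i]]], elements$sequence_id[i],
                elements$start[i], elements$end[i])
  })
  lens <- nchar(seqs)
  ksets <- map(seqs, function(s) unique(kmer_codes(s, 13L)))
  km <- tibble(code = unlist(ksets),
               el = rep.int(seq_len(n), lengths(ksets))) |>
    group_by(.data$code) |>
    filter(n() > 1L) |>
    summarise(els = list(.data$el), .groups = "drop")
  pair_counts <- if (nrow(km) == 0L) tibble(i = integer(0), j = integer(0), shared = integer(0)) else
    km$els |>
    map(function(e) {
      cmb <- utils::combn(sort(e), 2L)
      tibble(i = cmb[1L, ], j = cmb[2L, ])
    }) |>
    list_rbind() |>
    count(.data$i, .data$j, name = "shared") |>
    filter(.data$shared >= min_shared_kmers) |>
    arrange(desc(.data$shared))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  edges <- list()
  for (p in seq_len(nrow(pair_counts))) {
    i <- pair_counts$i[p]; j <- pair_counts$j[p]
    if (min(lens[i], lens[j]) <= min_coverage * max(lens[i], lens[j])) next
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    aln <- align_global(seqs[i], seqs[j], params = params)
    ic <- identity_coverage(aln)
    if (ic[["identity"]] > min_identity && ic[["coverage"]] > min_coverage) {
      parent[ri] <- rj
      edges[[length(edges) + 1L]] <- tibble(
        from = elements$element_id[i], to = elements$element_id[j],
        identity = ic[["identity"]], coverage = ic[["coverage"]])
    }
  }
  edges <- if (length(edges) == 0L) empty else bind_rows(edges)
  list(clustered = cluster_single_linkage(elements, edges), edges = edges)
}

#' Single-linkage clustering from an edge list
#'
#' Clusters are the connected components of the edge graph; elements with no
#' edge are reported as unclustered (`cluster_id` is `NA`). Cluster labels
#' are assigned by the smallest member element id, so the partition is
#' invariant to input order.
#'
#' @param elements Element tibble with `element_id` (and usually `genome`).
#' @param edges Edge tibble from [pairwise_8080_edges()].
#' @return `elements` with a `cluster_id` column (`NA` for singletons).
#' @export
cluster_single_linkage <- function(elements, edges) {
  g <- igraph::graph_from_data_frame(
    edges |> select("from", "to"), directed = FALSE,
    vertices = elements$element_id)
  comp <- igraph::components(g)
  member <- comp$membership[elements$element_id]
  sizes <- comp$csize[member]
  lab <- tapply(elements$element_id, member, min)[as.character(member)]
  elements |>
    mutate(cluster_id = if_else(sizes >= 2L,
                                paste0("CL_", unname(lab)), NA_character_))
}

#' Cross-species cluster statistics
#'
#' Summarises an 80/80 clustering of the pooled elements of two genomes:
#' fraction of elements clustered (in clusters of at least two), number and
#' fraction of mixed clusters (members from both genomes), fraction of
#' clustered elements lying in mixed clusters, and per-cluster age medians
#' split by genome.
#'
#' @param clustered Output of [cluster_single_linkage()] (needs `genome`).
#' @param ages Optional ages tibble ([date_elements()]) for age summaries.
#' @return A list of class `cluster_report` with `clusters` (per-cluster
#'   tibble) and summary fields; see [glance.cluster_report()].
#' @export
cluster_stats <- function(clustered, ages = NULL) {
  genomes <- sort(unique(clustered$genome))
  if (!is.null(ages)) {
    clustered <- clustered |>
      left_join(ages |> select("element_id", "age_mya"), by = "element_id")
  } else {
    clustered$age_mya <- NA_real_
  }
  per <- clustered |>
    filter(!is.na(.data$cluster_id)) |>
    group_by(.data$cluster_id) |>
    summarise(n_members = n(),
              n_genome_1 = sum(.data$genome == genomes[1]),
              n_genome_2 = sum(.data$genome == genomes[min(2L, length(genomes))]),
              is_mixed = length(genomes) > 1L &&
                all(genomes %in% .data$genome),
              median_age_1 = stats::median(
                .data$age_mya[.data$genome == genomes[1]], na.rm = TRUE),
              median_age_2 = stats::median(
                .data$age_mya[.data$genome == genomes[min(2L, length(genomes))]],
                na.rm = TRUE),
              .groups = "drop")
  n_el <- nrow(clustered)
  n_clustered <- sum(!is.na(clustered$cluster_id))
  in_mixed <- clustered |>
    filter(!is.na(.data$cluster_id)) |>
    semi_join(per |> filter(.data$is_mixed), by = "cluster_id") |>
    nrow()
  structure(list(
    clusters = per,
    genomes = genomes,
    n_elements = n_el,
    n_clustered = n_clustered,
    fraction_clustered = if (n_el > 0) n_clustered / n_el else NA_real_,
    n_clusters = nrow(per),
    n_mixed = sum(per$is_mixed),
    fraction_mixed = if (nrow(per) > 0) mean(per$is_mixed) else NA_real_,
    fraction_clustered_in_mixed = if (n_clustered > 0) in_mixed / n_clustered else NA_real_,
    comparison = "full element sequence (LTRs + internal)"),
    class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d elements, %.1f%% clustered into %d clusters (%d mixed)\n",
              x$n_elements, 100 * x$fraction_clustered, x$n_clusters, x$n_mixed))
  invisible(x)
}

#' Per-cluster table of a cluster report
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @export
tidy.cluster_report <- function(x, ...) x$clusters

#' One-row summary of a cluster report
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @export
glance.cluster_report <- function(x, ...) {
  tibble(n_elements = x$n_elements, n_clustered = x$n_clustered,
         fraction_clustered = x$fraction_clustered,
         n_clusters = x$n_clusters, n_mixed = x$n_mixed,
         fraction_mixed = x$fraction_mixed,
         fraction_clustered_in_mixed = x$fraction_clustered_in_mixed)
}
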