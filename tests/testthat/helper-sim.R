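# Shared small simulations, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_genome_pair(cfg)
  }
  .sim_cache[[key]]
}

small_sim <- function() {
  cached_sim("small", sim_config(
    seed = 7L, genome_length = 4e5, n_families = 4L,
    fate_counts = c(conserved = 8L, specific_A = 8L, specific_B = 8L,
                    partial_A_in_B = 4L, partial_B_in_A = 4L)))
}

# Truth rows of the intact elements of one genome, joined to annotation.
sim_truth_elements <- function(sim, genome = c("A", "B")) {
  genome <- match.arg(genome)
  els <- if (genome == "A") sim$elements_a else sim$elements_b
  dplyr::inner_join(els, sim$truth, by = "insertion_id")
}
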