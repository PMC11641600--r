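# Small in-code fixtures shared across test files.

# deterministic toy expression matrix with two classes
toy_expression <- function(n_genes = 6, n_samples = 8, seed = 42,
                           classes = c("A", "B")) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(n_genes * n_samples, 3, 0.5)), n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  labels <- rep(classes, length.out = n_samples)
  expression_matrix(vals, labels = labels)
}

write_expr_tsv <- function(expr, path = tempfile(fileext = ".tsv")) {
  write_expression(expr, path)
  path
}

# feature system for a hand-specified deviation structure is awkward to
# construct; tests that need full control go through small simulated data
small_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 20, samples_per_class = c(6L, 6L),
               n_node_plants = 2L, delta = 2, n_edge_plants = 2L,
               rho = c(0.8, -0.8), n_background_edges = 6L, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_dataset(do.call(simulation_design, args))
}

# feature system straight from a simulated dataset with default settings
sim_features <- function(sim, cutoff = 0.5, node_genes = NULL) {
  net <- prune_network(sim$network, sim$expr)
  aff <- mass_action_affinity(sim$expr, net)
  wts <- threshold_coexpression(spearman_coexpression(sim$expr, net), cutoff)
  assemble_features(aff, wts, sim$expr, node_genes = node_genes)
}
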