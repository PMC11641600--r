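test_that("mass-action affinity is the stoichiometry-weighted expression product", {
  vals <- rbind(u = c(2, 0, 1.5), v = c(3, 7, 2))
  colnames(vals) <- paste0("s", 1:3)
  expr <- expression_matrix(vals, labels = c("A", "A", "B"))
  net <- ppi_network(cbind("u", "v"))
  aff <- mass_action_affinity(expr, net)
  expect_equal(unname(aff$values[, 1]), c(6, 0, 3))     # product; zero absorbs
  # rho = alpha [A]^a [B]^b with alpha = 0.5, a = 2, b = 1
  aff2 <- mass_action_affinity(expr, net,
                               mass_action_params(0.5, 2, 1))
  expect_equal(unname(aff2$values[1, 1]), 0.5 * 2^2 * 3)

  # symmetry under default stoichiometry: endpoint order cannot matter
  netr <- ppi_network(cbind("v", "u"))
  expect_equal(unname(mass_action_affinity(expr, netr)$values),
               unname(aff$values))

  bad <- ppi_network(cbind("u", "w"))
  expect_error(mass_action_affinity(expr, bad),
               class = "ppiacoexp_validation_error")
})

test_that("class centroids are per-class arithmetic means", {
  vals <- rbind(g1 = c(1, 2, 6, 10), g2 = c(2, 4, 1, 3))
  colnames(vals) <- paste0("s", 1:4)
  expr <- expression_matrix(vals, labels = c("A", "A", "A", "B"))
  net <- ppi_network(cbind("g1", "g2"))
  aff <- mass_action_affinity(expr, net)
  cs <- class_centroids(aff, expr)
  expect_equal(unname(cs$edge_centroids["A", 1]), mean(c(2, 8, 6)))
  expect_equal(unname(cs$edge_centroids["B", 1]), 30)    # singleton class
  expect_equal(unname(cs$node_centroids["A", "g1"]), 3)
  expect_equal(cs$sizes, c(3L, 1L))
})

test_that("rank co-expression reproduces hand-computed coefficients", {
  vals <- rbind(a = c(1, 2, 3), b = c(10, 20, 30), c = c(3, 2, 1),
                d = c(1, 3, 2))
  colnames(vals) <- paste0("s", 1:3)
  expr <- expression_matrix(vals)
  net <- ppi_network(rbind(c("a", "b"), c("a", "c"), c("a", "d")))
  cw <- spearman_coexpression(expr, net, scope = "pooled")
  expect_equal(unname(cw$raw["a:b", 1]), 1)     # identical rank order
  expect_equal(unname(cw$raw["a:c", 1]), -1)    # reversed rank order
  expect_equal(unname(cw$raw["a:d", 1]), 0.5)   # 1 - 6*2/(3*8)

  lit <- spearman_coexpression(expr, net, scope = "pooled",
                               formula_mode = "literal")
  expect_equal(unname(lit$raw["a:d", 1]), 1 - 6 * 2 / (3 * 2))  # m(m-1) denominator
})

test_that("standard-mode coefficients match rank-then-Pearson and stats::cor", {
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(4:15, 1)
    x <- rnorm(m); y <- rnorm(m)
    vals <- rbind(x = x, y = y)
    colnames(vals) <- paste0("s", seq_len(m))
    expr <- expression_matrix(vals - min(vals) + 0.1)
    cw <- spearman_coexpression(expr, ppi_network(cbind("x", "y")),
                                scope = "pooled")
    expect_equal(unname(cw$raw[1, 1]), brute_spearman(x, y), tolerance = 1e-12)
    expect_equal(unname(cw$raw[1, 1]),
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("constant genes yield a zero coefficient with a warning", {
  vals <- rbind(a = c(1, 2, 3, 4), b = rep(2, 4))
  colnames(vals) <- paste0("s", 1:4)
  expr <- expression_matrix(vals)
  expect_warning(
    cw <- spearman_coexpression(expr, ppi_network(cbind("a", "b")),
                                scope = "pooled"),
    "constant")
  expect_equal(unname(cw$raw[1, 1]), 0)
})

test_that("per-class scope recovers class-specific correlation structure", {
  sim <- small_sim(seed = 2, samples_per_class = c(15L, 15L))
  net <- prune_network(sim$network, sim$expr)
  cw <- spearman_coexpression(sim$expr, net)
  planted <- paste0(sim$truth$edge_pairs$u, ":", sim$truth$edge_pairs$v)
  ix <- match(planted, rownames(cw$raw))
  expect_true(all(cw$raw[ix, "class1"] > 0.3))    # rho1 = 0.8
  expect_true(all(cw$raw[ix, "class2"] < -0.3))   # rho2 = -0.8
})

test_that("the cutoff rule zeroes below k and is idempotent and monotone", {
  raw <- matrix(c(0.6, 0.4, 0.3, -0.8), ncol = 1,
                dimnames = list(c("e1", "e2", "e3", "e4"), "pooled"))
  cw <- structure(list(raw = raw, thresholded = NULL, cutoff = NA,
                       scope = "pooled", formula_mode = "standard",
                       sign_rule = NA, constant_edges = character(0),
                       network = NULL),
                  class = "coexpression_weights")
  pos <- threshold_coexpression(cw, 0.5, sign = "positive")
  expect_equal(unname(pos$thresholded[, 1]), c(0.6, 0, 0, 0))
  all_pass <- threshold_coexpression(cw, 0, sign = "positive")
  expect_equal(unname(all_pass$thresholded["e3", 1]), 0.3)
  abs_ <- threshold_coexpression(cw, 0.5, sign = "absolute")
  expect_equal(unname(abs_$thresholded[, 1]), c(0.6, 0, 0, -0.8))

  twice <- threshold_coexpression(pos, 0.5, sign = "positive")
  expect_equal(twice$thresholded, pos$thresholded)
  # raising k never resurrects an edge zeroed at a lower k
  higher <- threshold_coexpression(pos, 0.7, sign = "positive")
  expect_true(all(higher$thresholded[pos$thresholded == 0] == 0))
})

test_that("feature assembly tracks block shapes and degenerate blocks", {
  sim <- small_sim(seed = 3)
  expr <- sim$expr
  net <- prune_network(sim$network, expr)
  aff <- mass_action_affinity(expr, net)
  cw <- spearman_coexpression(expr, net)

  wts <- threshold_coexpression(cw, 0.5)
  feats <- assemble_features(aff, wts, expr,
                             node_genes = rownames(expr$values)[1:3])
  expect_equal(feats$n_nodes, 3L)
  expect_equal(nrow(feats$node_values), ncol(expr$values))
  expect_equal(ncol(feats$aff_values), feats$n_edges)

  # cutoff above every coefficient -> node-only system
  allcut <- threshold_coexpression(cw, 1.1)
  node_only <- assemble_features(aff, allcut, expr)
  expect_equal(node_only$n_edges, 0L)
  expect_null(node_only$aff_values)

  # empty node list -> edge-only system
  edge_only <- assemble_features(aff, wts, expr, node_genes = character(0))
  expect_equal(edge_only$n_nodes, 0L)
  expect_gt(edge_only$n_edges, 0L)

  expect_error(assemble_features(aff, wts, expr, node_genes = "nope"),
               class = "ppiacoexp_validation_error")
  expect_error(assemble_features(NULL, NULL, expr, node_genes = character(0)),
               class = "ppiacoexp_validation_error")
})

test_that("zero-coefficient edges do not change the optimum", {
  sim <- small_sim(seed = 4)
  feats <- sim_features(sim)
  sol <- solve_lp(build_lp(feats))

  # graft an extra edge whose multiplier is identically zero
  feats2 <- feats
  feats2$aff_values <- cbind(feats$aff_values,
                             extra = feats$aff_values[, 1] * 2)
  feats2$edge_multiplier <- rbind(feats$edge_multiplier, extra = c(0, 0))
  feats2$edge_B <- rbind(feats$edge_B, extra = c(0, 0))
  feats2$edges <- rbind(feats$edges, data.frame(u = "gx", v = "gy"))
  feats2$n_edges <- feats$n_edges + 1L
  sol2 <- solve_lp(build_lp(feats2))
  expect_equal(sol2$objective, sol$objective, tolerance = 1e-9)
  expect_lt(sol2$w[feats$n_edges + 1L], 1e-9)
})

test_that("feature tables export ids, types and coefficients", {
  sim <- small_sim(seed = 5)
  feats <- sim_features(sim, node_genes = rownames(sim$expr$values)[1:2])
  tab <- feature_table(feats)
  expect_setequal(unique(tab$type), c("edge", "node"))
  expect_equal(sum(tab$type == "node"), 2L)
  p <- tempfile(fileext = ".tsv")
  feature_table(feats, p)
  expect_equal(nrow(read.delim(p)), nrow(tab))
})
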