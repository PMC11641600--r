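#' Design of a synthetic two-class expression study
#'
#' Describes a fully reproducible synthetic dataset with two kinds of
#' planted signal: *node* signals (a class mean shift in single genes) and
#' *edge* signals (a between-class change in a gene pair's correlation with
#' identical marginal means, invisible to any per-gene test).  Background
#' genes are i.i.d. log-normal noise, identical across classes.
#'
#' Defaults: 200 genes, 30 + 30 samples, 5 node plants shifted by 2 noise
#' SDs on the log scale, 5 edge plants with within-class correlations 0.8
#' and -0.8, log-scale noise SD 0.5 around a log-mean of 3 (so expression
#' is on a TPM-like scale around 20), and 40 random background edges in the
#' interaction network.
#'
#' @param n_genes total genes.
#' @param samples_per_class integer vector, one entry per class (>= 2
#'   classes).
#' @param n_node_plants,delta number of node-signal genes and their mean
#'   shift (in units of `noise_sd`) applied to class 2 on the log scale.
#' @param n_edge_plants number of edge-signal gene pairs; their genes are
#'   disjoint from the node plants.
#' @param rho per-class within-pair correlation of the edge plants
#'   (length = number of classes, entries in (-1, 1)).
#' @param noise_sd log-scale standard deviation of every gene.
#' @param log_mean log-scale mean expression.
#' @param n_background_edges random non-planted pairs added to the network.
#' @param seed integer seed governing all draws.
#' @export
simulation_design <- function(n_genes = 200L,
                              samples_per_class = c(30L, 30L),
                              n_node_plants = 5L, delta = 2,
                              n_edge_plants = 5L, rho = c(0.8, -0.8),
                              noise_sd = 0.5, log_mean = 3,
                              n_background_edges = 40L, seed = 1L) {
  if (length(samples_per_class) < 2L)
    validation_error("need at least 2 classes")
  if (length(rho) != length(samples_per_class))
    validation_error("rho needs one correlation per class")
  if (any(abs(rho) >= 1)) validation_error("|rho| must be < 1")
  if (n_node_plants + 2L * n_edge_plants > n_genes)
    validation_error("more planted genes than n_genes")
  if (noise_sd <= 0) validation_error("noise_sd must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 samples_per_class = as.integer(samples_per_class),
                 n_node_plants = as.integer(n_node_plants), delta = delta,
                 n_edge_plants = as.integer(n_edge_plants), rho = rho,
                 noise_sd = noise_sd, log_mean = log_mean,
                 n_background_edges = as.integer(n_background_edges),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate an expression matrix, interaction network and planted truth
#'
#' All genes are log-normal.  Background genes draw i.i.d.
#' \eqn{\log x \sim N(\mu, \sigma)} in every class; node plants add
#' \eqn{\Delta\sigma} to the class-2 log-mean; each edge-plant pair draws
#' bivariate normal logs with the class's correlation \eqn{\rho_k} and
#' identical marginals, so no single gene's distribution differs between
#' classes.  The network holds every planted pair plus random background
#' pairs.  Identical designs (including the seed) give byte-identical
#' output.
#'
#' @param design a [simulation_design()].
#' @return A list: `expr` (an [expression_matrix()] with labels
#'   `class1`, `class2`, ...), `network` (a [ppi_network()]), and `truth`
#'   (`node_genes`, `edge_pairs` data.frame, and the `design`).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  ng <- design$n_genes
  spc <- design$samples_per_class
  C <- length(spc)
  m <- sum(spc)
  genes <- sprintf("g%04d", seq_len(ng))
  cls <- rep(paste0("class", seq_len(C)), spc)
  samples <- sprintf("s%03d", seq_len(m))

  plant <- sample(ng, design$n_node_plants + 2L * design$n_edge_plants)
  node_ix <- plant[seq_len(design$n_node_plants)]
  edge_ix <- matrix(plant[design$n_node_plants + seq_len(2L * design$n_edge_plants)],
                    ncol = 2L)

  logx <- matrix(rnorm(ng * m, design$log_mean, design$noise_sd), ng, m)
  ## node plants: class-2 mean shift of delta * noise_sd on the log scale
  if (design$n_node_plants > 0) {
    in2 <- cls == "class2"
    logx[node_ix, in2] <- logx[node_ix, in2] + design$delta * design$noise_sd
  }
  ## edge plants: bivariate normal with per-class correlation, equal marginals
  if (design$n_edge_plants > 0) {
    for (e in seq_len(design$n_edge_plants)) {
      for (k in seq_len(C)) {
        ix <- which(cls == paste0("class", k))
        S <- design$noise_sd^2 *
          matrix(c(1, design$rho[k], design$rho[k], 1), 2L)
        z <- MASS::mvrnorm(length(ix), mu = rep(design$log_mean, 2L), Sigma = S)
        logx[edge_ix[e, ], ix] <- t(z)
      }
    }
  }
  values <- exp(logx)
  dimnames(values) <- list(genes, samples)
  expr <- expression_matrix(values, labels = setNames(cls, samples))

  edge_pairs <- data.frame(u = pmin(genes[edge_ix[, 1L]], genes[edge_ix[, 2L]]),
                           v = pmax(genes[edge_ix[, 1L]], genes[edge_ix[, 2L]]),
                           stringsAsFactors = FALSE)
  ## background pairs: random, excluding duplicates of planted pairs
  bg <- matrix(character(0), 0, 2)
  if (design$n_background_edges > 0) {
    want <- design$n_background_edges
    seen <- paste0(edge_pairs$u, ":", edge_pairs$v)
    acc <- matrix(character(0), 0, 2)
    while (nrow(acc) < want) {
      cand <- matrix(genes[sample(ng, 2L * (want - nrow(acc)) * 2L,
                                  replace = TRUE)], ncol = 2L)
      cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
      key <- paste0(pmin(cand[, 1L], cand[, 2L]), ":",
                    pmax(cand[, 1L], cand[, 2L]))
      fresh <- !key %in% seen & !duplicated(key)
      cand <- cand[fresh, , drop = FALSE]
      seen <- c(seen, key[fresh])
      acc <- rbind(acc, cand)
    }
    bg <- acc[seq_len(want), , drop = FALSE]
  }
  network <- ppi_network(rbind(as.matrix(edge_pairs), bg))
  list(expr = expr,
       network = network,
       truth = list(node_genes = sort(genes[node_ix]),
                    edge_pairs = edge_pairs[order(edge_pairs$u, edge_pairs$v), ,
                                            drop = FALSE],
                    design = design))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the expression TSV, a two-column labels TSV, the edge-list TSV
#' and a truth JSON into `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             edges = file.path(dir, "edges.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expr, paths[["expression"]])
  write.table(data.frame(sample = names(sim$expr$labels),
                         class = as.character(sim$expr$labels)),
              paths[["labels"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(sim$network), paths[["edges"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(node_genes = sim$truth$node_genes,
                            edge_pairs = sim$truth$edge_pairs,
                            design = unclass(sim$truth$design)),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}

prf <- function(n_hit, n_sel, n_true) {
  precision <- if (n_sel > 0) n_hit / n_sel else 0
  recall <- if (n_true > 0) n_hit / n_true else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       empty_selection = n_sel == 0L)
}

#' Score biomarker recovery against planted truth
#'
#' Edge matches are counted on unordered gene pairs; node matches on gene
#' identifiers.  An empty selection has recall 0 and, by convention,
#' precision 0 with `empty_selection = TRUE`.
#'
#' @param selected a `biomarker_set` (or a list with `edge_pairs`
#'   data.frame and `node_genes` character).
#' @param truth the `truth` element of [simulate_dataset()].
#' @return A `recovery_score`: `nodes` and `edges`, each with precision,
#'   recall, F1 and the empty-selection flag.
#' @export
score_recovery <- function(selected, truth) {
  if (inherits(selected, "biomarker_set")) {
    sel_nodes <- selected$node_biomarkers$gene
    eb <- selected$edge_biomarkers
    sel_edges <- if (nrow(eb)) paste0(pmin(eb$gene_u, eb$gene_v), ":",
                                      pmax(eb$gene_u, eb$gene_v)) else character(0)
  } else {
    sel_nodes <- selected$node_genes
    ep <- selected$edge_pairs
    sel_edges <- if (!is.null(ep) && nrow(ep)) paste0(pmin(ep$u, ep$v), ":",
                                                      pmax(ep$u, ep$v)) else character(0)
  }
  true_nodes <- truth$node_genes
  true_edges <- paste0(truth$edge_pairs$u, ":", truth$edge_pairs$v)
  sel_nodes <- unique(sel_nodes); sel_edges <- unique(sel_edges)
  structure(list(nodes = prf(sum(sel_nodes %in% true_nodes),
                             length(sel_nodes), length(true_nodes)),
                 edges = prf(sum(sel_edges %in% true_edges),
                             length(sel_edges), length(true_edges))),
            class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf("recovery: nodes P %.2f R %.2f F1 %.2f | edges P %.2f R %.2f F1 %.2f\n",
              x$nodes$precision, x$nodes$recall, x$nodes$f1,
              x$edges$precision, x$edges$recall, x$edges$f1))
  invisible(x)
}
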