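#' Mass-action parameters for interaction affinity
#'
#' Parameters of the law-of-mass-action affinity
#' \eqn{\rho_{AB} = \alpha [A]^a [B]^b}, where the protein concentrations
#' are taken proportional to the partners' mRNA expression.  With all three
#' constants at their default of 1 the affinity reduces to the elementwise
#' product of the two genes' expression.
#'
#' @param reaction_constant positive reaction constant \eqn{\alpha}.
#' @param stoich_u,stoich_v positive stoichiometric exponents of the two
#'   partners.
#' @export
mass_action_params <- function(reaction_constant = 1, stoich_u = 1, stoich_v = 1) {
  stopifnot(reaction_constant > 0, stoich_u > 0, stoich_v > 0)
  structure(list(reaction_constant = reaction_constant,
                 stoich_u = stoich_u, stoich_v = stoich_v),
            class = "mass_action_params")
}

#' Per-sample mass-action affinity of every interaction
#'
#' For edge \eqn{i = (u, v)} and sample \eqn{j}, the affinity is
#' \eqn{a_{ji} = \alpha\, x_{ju}^a\, x_{jv}^b}, a proxy for the concentration
#' of the protein complex in that sample.  Affinities are non-negative
#' whenever expression is.
#'
#' @param expr an [expression_matrix()] with non-negative values.
#' @param net a [ppi_network()]; every endpoint must have an expression row.
#' @param params a [mass_action_params()].
#' @return An `affinity_matrix`: list with `values` (samples x edges matrix,
#'   columns named `"u:v"`) and the `network` the columns index.
#' @export
mass_action_affinity <- function(expr, net, params = mass_action_params()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(net, "ppi_network"))
  genes <- rownames(expr$values)
  miss <- !(net$u %in% genes) | !(net$v %in% genes)
  if (any(miss)) {
    i <- which(miss)[1L]
    validation_error("edge %s:%s references a gene absent from the expression matrix",
                     net$u[i], net$v[i])
  }
  xu <- t(expr$values[net$u, , drop = FALSE])   # samples x edges
  xv <- t(expr$values[net$v, , drop = FALSE])
  vals <- params$reaction_constant * xu^params$stoich_u * xv^params$stoich_v
  colnames(vals) <- paste0(net$u, ":", net$v)
  rownames(vals) <- colnames(expr$values)
  structure(list(values = vals, network = net, params = params),
            class = "affinity_matrix")
}

#' Per-class centroids of affinities and expression
#'
#' For each class \eqn{K} with member set \eqn{I_K} of size \eqn{m_K}, the
#' edge centroid is the arithmetic mean affinity
#' \eqn{\bar a_{iK} = \sum_{j \in I_K} a_{ji} / m_K} and the node centroid is
#' the mean expression of each gene over the class's samples.
#'
#' @param aff an `affinity_matrix` from [mass_action_affinity()], or `NULL`
#'   when the model has no edge features.
#' @param expr an [expression_matrix()] whose samples match `aff`.
#' @param labels class labels; defaults to `expr$labels`.
#' @return A `class_spec`: classes, per-class sizes and member sets, and
#'   centroid matrices (classes x edges, classes x genes).
#' @export
class_centroids <- function(aff, expr, labels = expr$labels) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(labels)) validation_error("no class labels available")
  labels <- factor(as.character(labels))
  if (length(labels) != ncol(expr$values))
    validation_error("labels length does not match sample count")
  if (any(table(labels) == 0L)) validation_error("empty class")
  classes <- levels(labels)
  members <- split(seq_along(labels), labels)
  node_cent <- do.call(rbind, lapply(members, function(ix)
    rowMeans(expr$values[, ix, drop = FALSE])))
  edge_cent <- NULL
  if (!is.null(aff)) {
    stopifnot(inherits(aff, "affinity_matrix"))
    if (nrow(aff$values) != ncol(expr$values))
      validation_error("affinity and expression sample counts differ")
    edge_cent <- do.call(rbind, lapply(members, function(ix)
      colMeans(aff$values[ix, , drop = FALSE])))
    rownames(edge_cent) <- classes
  }
  rownames(node_cent) <- classes
  structure(list(classes = classes,
                 sizes = as.integer(table(labels)[classes]),
                 members = members,
                 labels = labels,
                 edge_centroids = edge_cent,
                 node_centroids = node_cent),
            class = "class_spec")
}

spearman_formula <- function(ru, rv, formula_mode) {
  m <- length(ru)
  denom <- if (formula_mode == "standard") m * (m^2 - 1) else m * (m - 1)
  1 - 6 * sum((ru - rv)^2) / denom
}

#' Rank co-expression coefficient of every interaction
#'
#' For edge \eqn{(u, v)} the coefficient is
#' \eqn{B_{uv} = 1 - 6 \sum_l (rg(x_{lu}) - rg(x_{lv}))^2 / D} with average
#' ranks for ties.  In `"standard"` mode the denominator is the Spearman
#' denominator \eqn{D = m(m^2-1)}, guaranteeing \eqn{B \in [-1, 1]};
#' `"literal"` mode uses \eqn{D = m(m-1)}, which is occasionally seen in the
#' applied literature but can leave the interval.
#'
#' By default the coefficient is computed separately within each class
#' (`scope = "per_class"`), so that an interaction co-expressed in one
#' condition but decoupled (or anti-correlated) in another keeps its
#' context-specific weight; `scope = "pooled"` computes a single coefficient
#' over all samples.  See the methods vignette for why the per-class scope is
#' the default.
#'
#' @param expr an [expression_matrix()].
#' @param net a [ppi_network()] with endpoints in `expr`.
#' @param scope `"per_class"` (default; needs labels) or `"pooled"`.
#' @param formula_mode `"standard"` or `"literal"` denominator.
#' @param labels class labels for the per-class scope; defaults to
#'   `expr$labels`.
#' @return A `coexpression_weights` object with `raw` (edges x classes matrix,
#'   single column `"pooled"` for pooled scope), `cutoff = NA` (not yet
#'   thresholded), and a record of edges involving constant genes (their
#'   coefficient is undefined and set to 0).
#' @export
spearman_coexpression <- function(expr, net,
                                  scope = c("per_class", "pooled"),
                                  formula_mode = c("standard", "literal"),
                                  labels = expr$labels) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(net, "ppi_network"))
  scope <- match.arg(scope)
  formula_mode <- match.arg(formula_mode)
  if (ncol(expr$values) < 3L) validation_error("need at least 3 samples")
  sets <- if (scope == "pooled") {
    list(pooled = seq_len(ncol(expr$values)))
  } else {
    if (is.null(labels)) validation_error("per-class co-expression needs class labels")
    split(seq_along(labels), factor(as.character(labels)))
  }
  genes <- unique(c(net$u, net$v))
  miss <- setdiff(genes, rownames(expr$values))
  if (length(miss))
    validation_error("network gene(s) absent from expression matrix: %s",
                     paste(head(miss, 3L), collapse = ", "))
  raw <- matrix(NA_real_, nrow(net), length(sets),
                dimnames = list(paste0(net$u, ":", net$v), names(sets)))
  const_edges <- character(0)
  for (s in seq_along(sets)) {
    ix <- sets[[s]]
    if (length(ix) < 3L)
      validation_error("class '%s' has fewer than 3 samples for co-expression",
                       names(sets)[s])
    sub <- expr$values[genes, ix, drop = FALSE]
    rk <- t(apply(sub, 1L, rank))      # average ranks for ties
    constant <- apply(sub, 1L, function(x) max(x) == min(x))
    names(constant) <- genes
    for (e in seq_len(nrow(net))) {
      if (constant[net$u[e]] || constant[net$v[e]]) {
        raw[e, s] <- 0
        const_edges <- c(const_edges, rownames(raw)[e])
      } else {
        raw[e, s] <- spearman_formula(rk[net$u[e], ], rk[net$v[e], ], formula_mode)
      }
    }
  }
  const_edges <- unique(const_edges)
  if (length(const_edges))
    warning(sprintf("%d edge(s) involve a constant gene; coefficient set to 0",
                    length(const_edges)))
  structure(list(raw = raw, thresholded = NULL, cutoff = NA_real_,
                 scope = scope, formula_mode = formula_mode,
                 sign_rule = NA_character_, constant_edges = const_edges,
                 network = net),
            class = "coexpression_weights")
}

#' Apply the co-expression cutoff rule
#'
#' Coefficients that pass the cutoff are kept, the rest are set to 0 and the
#' corresponding edge terms vanish from the selection model.  With
#' `sign = "absolute"` (default) a coefficient passes when \eqn{|B| \ge k},
#' so strong anti-correlation also counts as context-specific coupling; with
#' `sign = "positive"` only \eqn{B \ge k} passes, the stricter rule that
#' admits positive co-expression alone.
#'
#' Thresholding is idempotent and monotone in `k`: raising the cutoff never
#' resurrects a zeroed coefficient.
#'
#' @param weights a `coexpression_weights` object (raw or already
#'   thresholded; re-thresholding applies to the current values).
#' @param cutoff the cutoff \eqn{k} (default 0.5).
#' @param sign `"absolute"` or `"positive"`.
#' @return The `coexpression_weights` with `thresholded` filled in.
#' @export
threshold_coexpression <- function(weights, cutoff = 0.5,
                                   sign = c("absolute", "positive")) {
  stopifnot(inherits(weights, "coexpression_weights"))
  sign <- match.arg(sign)
  base <- if (is.null(weights$thresholded)) weights$raw else weights$thresholded
  pass <- if (sign == "absolute") abs(base) >= cutoff else base >= cutoff
  weights$thresholded <- ifelse(pass, base, 0)
  weights$cutoff <- cutoff
  weights$sign_rule <- sign
  weights
}

#' Assemble the joint edge + node feature system
#'
#' Combines the affinity columns of edges that survived the co-expression
#' cutoff with the expression columns of candidate node genes into the system
#' consumed by [build_lp()].  Edges whose thresholded coefficient is 0 in
#' every class are dropped: their constraint coefficients would be
#' identically zero and their weight cost would force \eqn{w = 0} anyway.
#'
#' @param aff an `affinity_matrix`, or `NULL` for a node-only system.
#' @param weights thresholded `coexpression_weights` matching `aff` (ignored
#'   when `aff` is `NULL`).
#' @param expr an [expression_matrix()].
#' @param node_genes candidate single-gene features; default all genes in
#'   `expr`.  Use `character(0)` for an edge-only system.
#' @param labels class labels; default `expr$labels`.
#' @return A `feature_system`: edge block (`aff_values` m x p,
#'   `edge_multiplier` p x C matrix of \eqn{|B|} values entering the
#'   constraints, `edges` table), node block (`node_values` m x n,
#'   `node_genes`), and the sample labels.
#' @export
assemble_features <- function(aff, weights, expr, node_genes = NULL,
                              labels = expr$labels) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(labels)) validation_error("class labels are required")
  labels <- factor(as.character(labels))
  classes <- levels(labels)
  if (is.null(node_genes)) node_genes <- rownames(expr$values)
  miss <- setdiff(node_genes, rownames(expr$values))
  if (length(miss))
    validation_error("node gene(s) absent from expression matrix: %s",
                     paste(head(miss, 3L), collapse = ", "))

  edges <- data.frame(u = character(0), v = character(0))
  aff_values <- NULL
  mult <- matrix(0, 0, length(classes), dimnames = list(NULL, classes))
  B_kept <- NULL
  if (!is.null(aff)) {
    stopifnot(inherits(aff, "affinity_matrix"),
              inherits(weights, "coexpression_weights"))
    if (is.null(weights$thresholded))
      validation_error("co-expression weights have not been thresholded")
    B <- weights$thresholded
    if (nrow(B) != ncol(aff$values))
      validation_error("co-expression weights do not match the affinity columns")
    keep <- apply(B != 0, 1L, any)
    if (any(keep)) {
      aff_values <- aff$values[, keep, drop = FALSE]
      B_kept <- B[keep, , drop = FALSE]
      ## the constraint multiplier is the coefficient magnitude, expanded to
      ## one column per class (a pooled coefficient applies to every class)
      mult <- if (ncol(B_kept) == length(classes) &&
                  identical(colnames(B_kept), classes)) {
        abs(B_kept)
      } else {
        matrix(abs(B_kept[, 1L]), nrow(B_kept), length(classes),
               dimnames = list(rownames(B_kept), classes))
      }
      edges <- aff$network[keep, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  node_values <- t(expr$values[node_genes, , drop = FALSE])
  if (nrow(edges) + length(node_genes) == 0L)
    validation_error("empty feature system: no surviving edges and no node genes")
  structure(list(aff_values = aff_values,
                 edge_multiplier = mult,
                 edge_B = B_kept,
                 edges = edges,
                 node_values = node_values,
                 node_genes = node_genes,
                 labels = labels,
                 sample_ids = colnames(expr$values),
                 n_edges = nrow(edges),
                 n_nodes = length(node_genes)),
            class = "feature_system")
}

#' @export
print.feature_system <- function(x, ...) {
  cat(sprintf("feature_system: %d edge + %d node features, %d samples, %d classes\n",
              x$n_edges, x$n_nodes, length(x$sample_ids), nlevels(x$labels)))
  invisible(x)
}

#' Export a feature system as a table
#'
#' One row per feature: identifier, type (`edge`/`node`), the genes involved,
#' and the per-class co-expression coefficient for edges.
#'
#' @param features a `feature_system`.
#' @param path optional output TSV path.
#' @return The table, invisibly when written to `path`.
#' @export
feature_table <- function(features, path = NULL) {
  stopifnot(inherits(features, "feature_system"))
  rows <- list()
  if (features$n_edges > 0) {
    Btxt <- apply(features$edge_B, 1L, function(b)
      paste(sprintf("%s=%.4f", colnames(features$edge_B), b), collapse = ";"))
    rows[[1]] <- data.frame(
      feature_id = paste0(features$edges$u, ":", features$edges$v),
      type = "edge", gene_u = features$edges$u, gene_v = features$edges$v,
      B = Btxt, stringsAsFactors = FALSE)
  }
  if (features$n_nodes > 0) {
    rows[[2]] <- data.frame(feature_id = features$node_genes, type = "node",
                            gene_u = features$node_genes, gene_v = NA,
                            B = NA, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
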