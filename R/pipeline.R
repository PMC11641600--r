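#' End-to-end biomarker selection
#'
#' Runs the full selection pipeline on in-memory objects: restrict the
#' interaction network to measured genes (optionally to anchor-touching
#' edges), compute mass-action affinities, rank co-expression with the
#' cutoff rule, assemble the edge + node feature system, build and solve
#' the linear program, and extract the selected biomarkers.
#'
#' @param expr an [expression_matrix()] with class labels (>= 2 classes).
#' @param network a [ppi_network()].
#' @param params a [model_params()].
#' @param anchors optional anchor gene set for [anchor_edge_filter()]
#'   (e.g. differentially expressed transcription factors).
#' @param node_genes candidate node features (default: all genes).
#' @param coexpression_scope,coexpression_sign,formula_mode passed to
#'   [spearman_coexpression()] / [threshold_coexpression()].
#' @param mass_params a [mass_action_params()].
#' @return A `selection_result`: `biomarkers` (a `biomarker_set`),
#'   `solution` (the `lp_solution`), `features`, `params`, and the pruned
#'   `network`.
#' @export
select_biomarkers <- function(expr, network, params = model_params(),
                              anchors = NULL, node_genes = NULL,
                              coexpression_scope = c("per_class", "pooled"),
                              coexpression_sign = c("absolute", "positive"),
                              formula_mode = c("standard", "literal"),
                              mass_params = mass_action_params()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(network, "ppi_network"))
  coexpression_scope <- match.arg(coexpression_scope)
  coexpression_sign <- match.arg(coexpression_sign)
  formula_mode <- match.arg(formula_mode)
  net <- prune_network(network, expr)
  if (!is.null(anchors)) net <- anchor_edge_filter(net, anchors)
  aff <- NULL
  weights <- NULL
  if (nrow(net)) {
    aff <- mass_action_affinity(expr, net, mass_params)
    weights <- spearman_coexpression(expr, net, scope = coexpression_scope,
                                     formula_mode = formula_mode)
    weights <- threshold_coexpression(weights, params$coexpression_cutoff,
                                      sign = coexpression_sign)
  }
  features <- assemble_features(aff, weights, expr, node_genes = node_genes)
  lp <- build_lp(features, params = params)
  sol <- solve_lp(lp)
  if (sol$status != "optimal")
    stop(errorCondition(
      sprintf("LP solve failed with status '%s'", sol$status),
      class = c("ppiacoexp_solver_error", "error")))
  bm <- extract_biomarkers(sol, features, params)
  structure(list(biomarkers = bm, solution = sol, features = features,
                 params = params, network = net),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  print(x$biomarkers)
  print(x$solution)
  invisible(x)
}

#' Write a biomarker report
#'
#' TSV with one row per selected feature: `feature_id`, `type`
#' (`edge`/`node`), `gene_u`, `gene_v` (`NA` for nodes), `weight`, and the
#' co-expression coefficient `B` (`NA` for nodes).
#'
#' @param bm a `biomarker_set`.
#' @param path output path.
#' @export
write_biomarker_report <- function(bm, path) {
  stopifnot(inherits(bm, "biomarker_set"))
  eb <- bm$edge_biomarkers
  nb <- bm$node_biomarkers
  tab <- rbind(
    if (nrow(eb)) data.frame(feature_id = eb$feature, type = "edge",
                             gene_u = eb$gene_u, gene_v = eb$gene_v,
                             weight = eb$weight, B = eb$B,
                             stringsAsFactors = FALSE),
    if (nrow(nb)) data.frame(feature_id = nb$gene, type = "node",
                             gene_u = nb$gene, gene_v = NA,
                             weight = nb$weight, B = NA,
                             stringsAsFactors = FALSE))
  if (is.null(tab))
    tab <- data.frame(feature_id = character(0), type = character(0),
                      gene_u = character(0), gene_v = character(0),
                      weight = numeric(0), B = numeric(0))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON record that makes a run reproducible: subcommand, resolved
#' parameters, seed, input file MD5 digests, solver status/objective and
#' output paths.
#'
#' @param path output JSON path.
#' @param subcommand what was run.
#' @param params a [model_params()] or any parameter list.
#' @param inputs named character vector of input file paths (digested).
#' @param outputs named character vector of output paths.
#' @param seed integer seed used.
#' @param extra additional fields to record.
#' @export
write_run_manifest <- function(path, subcommand, params = list(),
                               inputs = character(0), outputs = character(0),
                               seed = NA_integer_, extra = list()) {
  digests <- lapply(inputs, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  manifest <- c(list(subcommand = subcommand,
                     package_version = as.character(utils::packageVersion("ppiacoexp")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     seed = seed,
                     params = unclass(params),
                     inputs = digests,
                     outputs = as.list(outputs)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
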