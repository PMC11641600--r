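#' Construct a protein-protein interaction network
#'
#' An edge list of unordered gene pairs.  Pairs are canonicalised
#' (lexicographically ordered within each pair), self-loops and duplicate
#' pairs are dropped, and each surviving edge gets a stable index in input
#' order.
#'
#' @param pairs two-column matrix/data.frame of gene identifiers, one
#'   interaction per row.
#' @return An object of class `ppi_network`: a data.frame with columns
#'   `u`, `v` (with `u < v` lexicographically) and attributes
#'   `n_self_loops_dropped`, `n_duplicates_dropped`.
#' @export
ppi_network <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) validation_error("edge list needs two columns")
  a <- trimws(as.character(pairs[[1L]]))
  b <- trimws(as.character(pairs[[2L]]))
  ok <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  a <- a[ok]; b <- b[ok]
  self <- a == b
  u <- pmin(a[!self], b[!self])
  v <- pmax(a[!self], b[!self])
  dup <- duplicated(paste0(u, "\r", v))
  net <- data.frame(u = u[!dup], v = v[!dup], stringsAsFactors = FALSE)
  attr(net, "n_self_loops_dropped") <- sum(self)
  attr(net, "n_duplicates_dropped") <- sum(dup)
  class(net) <- c("ppi_network", "data.frame")
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d edges over %d genes\n",
              nrow(x), length(unique(c(x$u, x$v)))))
  invisible(x)
}

#' Read a protein-protein interaction edge list
#'
#' Reads a delimited interaction file and extracts two identifier columns.
#' Works on plain two-column files as well as BioGRID tab exports (pass the
#' interactor symbol column names, e.g. `"Official Symbol Interactor A"`).
#'
#' @param path file path.
#' @param col_u,col_v column names or indices holding the two interactors
#'   (defaults: first two columns).
#' @param header does the file carry a header row?  Defaults to `TRUE` when
#'   column names are given, `FALSE` otherwise.
#' @return A [ppi_network()].
#' @export
read_ppi_edges <- function(path, col_u = 1L, col_v = 2L, header = NULL) {
  if (!file.exists(path)) validation_error("edge list not found: %s", path)
  if (is.null(header)) header <- is.character(col_u) || is.character(col_v)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (col in list(col_u, col_v))
    if (is.character(col) && !col %in% names(df))
      validation_error("column '%s' not present in %s", col, path)
  ppi_network(data.frame(df[[col_u]], df[[col_v]], stringsAsFactors = FALSE))
}

#' Keep only edges anchored on a gene set
#'
#' Retains exactly the edges with at least one endpoint in `anchors` --
#' typically differentially expressed transcription factors, so that every
#' candidate edge couples a regulator to a responding gene.  Edge order (and
#' hence re-assigned indices) follows the original edge order.
#'
#' @param net a [ppi_network()].
#' @param anchors character vector of anchor gene identifiers (non-empty).
#' @return A [ppi_network()] containing the anchored edges.
#' @export
anchor_edge_filter <- function(net, anchors) {
  stopifnot(inherits(net, "ppi_network"))
  anchors <- trimws(as.character(anchors))
  anchors <- anchors[nzchar(anchors)]
  if (!length(anchors)) validation_error("empty anchor gene set")
  keep <- net$u %in% anchors | net$v %in% anchors
  if (!any(keep)) warning("no edge touches any anchor gene; network is empty")
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' Restrict a network to genes present in an expression matrix
#'
#' Drops edges with an endpoint that has no expression row.  Identifier
#' matching is exact string match after whitespace stripping; no alias
#' resolution is attempted.
#'
#' @param net a [ppi_network()].
#' @param expr an [expression_matrix()] (or a character vector of gene ids).
#' @return A [ppi_network()].
#' @export
prune_network <- function(net, expr) {
  stopifnot(inherits(net, "ppi_network"))
  genes <- if (inherits(expr, "expression_matrix")) rownames(expr$values) else as.character(expr)
  out <- net[net$u %in% genes & net$v %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}
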