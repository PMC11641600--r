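#' Construct an expression matrix object
#'
#' The central data container: a genes x samples matrix of non-negative
#' expression values (TPM, array intensity, ...) with unique gene and sample
#' identifiers and, optionally, a class label per sample.
#'
#' @param values numeric matrix, one row per gene, one column per sample;
#'   `rownames` are gene identifiers, `colnames` sample identifiers.
#' @param labels optional class labels: a factor/character vector either named
#'   by sample identifier or in column order of `values`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `labels` (a named factor, or `NULL`).
#' @examples
#' x <- matrix(rexp(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(x, labels = c(s1 = "tumour", s2 = "normal"))
#' @export
expression_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    validation_error("expression values need row (gene) and column (sample) names")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values)))
    validation_error("duplicated gene identifiers: %s",
                     paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    validation_error("duplicated sample identifiers: %s",
                     paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(colnames(values), names(labels))
      if (length(miss))
        validation_error("samples without class label: %s", paste(miss, collapse = ", "))
      labels <- labels[colnames(values)]
    } else if (length(labels) != ncol(values)) {
      validation_error("labels length (%d) != number of samples (%d)",
                       length(labels), ncol(values))
    }
    labels <- factor(as.character(labels))
    names(labels) <- colnames(values)
  }
  structure(list(values = values, labels = labels), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a delimited expression matrix
#'
#' Expects one header row of sample identifiers and gene identifiers in the
#' first column (or the transpose, with `samples_as_rows = TRUE`).  The
#' delimiter defaults to tab and is taken as comma for `.csv` files.  Empty
#' fields and the tokens `NA`/`NaN` are read as missing.
#'
#' @param path file path.
#' @param samples_as_rows logical; set when rows are samples and columns genes.
#' @param labels optional named class labels to attach (see
#'   [expression_matrix()]), or a labels file path readable by [read_labels()].
#' @param sep field separator; `NULL` chooses by file extension.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, samples_as_rows = FALSE, labels = NULL,
                            sep = NULL) {
  if (!file.exists(path)) validation_error("expression file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) validation_error("%s: need a header row and at least one data row", path)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("%s: ragged row %d has %d fields where %d were expected",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = c("", "NA", "NaN"), stringsAsFactors = FALSE,
                   comment.char = "")
  ids <- trimws(as.character(df[[1L]]))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop(sprintf("%s: non-numeric expression values", path))
  rownames(vals) <- ids
  if (samples_as_rows) vals <- t(vals)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  expression_matrix(vals, labels = labels)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: header row of sample identifiers, gene
#' identifiers in the first column.
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Two-column delimited text: `sample_id<TAB>class`, no header required
#' (a header line is tolerated when its first field is `sample_id`).
#'
#' @param path file path.
#' @return A named character vector of class labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) validation_error("labels file not found: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) validation_error("%s: expected two columns (sample, class)", path)
  if (tolower(trimws(df[1L, 1L])) %in% c("sample", "sample_id")) df <- df[-1L, , drop = FALSE]
  setNames(trimws(as.character(df[[2L]])), trimws(as.character(df[[1L]])))
}

filter_report <- function(rule, removed, kept, parameters = list()) {
  structure(list(rule = rule, genes_removed = length(removed),
                 genes_kept = kept, removed_ids = removed,
                 parameters = parameters),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': removed %d, kept %d genes\n",
              x$rule, x$genes_removed, x$genes_kept))
  invisible(x)
}

apply_gene_filter <- function(expr, keep, rule, parameters) {
  if (!any(keep))
    validation_error("filter '%s' would remove every gene", rule)
  kept <- expr$values[keep, , drop = FALSE]
  list(expr = expression_matrix(kept, labels = expr$labels),
       report = filter_report(rule, rownames(expr$values)[!keep], sum(keep),
                              parameters))
}

#' Drop genes with missing values
#'
#' Removes every gene with at least one missing measurement, preserving the
#' order of the remaining genes.
#'
#' @param expr an [expression_matrix()].
#' @return A list with the filtered `expr` and a `report`.
#' @export
filter_missing <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  apply_gene_filter(expr, complete.cases(expr$values), "missing", list())
}

#' Shannon entropy of each gene's expression distribution
#'
#' Expression across samples is discretised into `n_bins` equal-width bins
#' between the gene's own minimum and maximum; the entropy (base 2) of the
#' bin-occupancy distribution is returned.  A constant gene has entropy 0.
#'
#' @param expr an [expression_matrix()].
#' @param n_bins number of bins (>= 2).
#' @return Named numeric vector of entropies in bits.
#' @export
gene_entropy <- function(expr, n_bins = 10L) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (n_bins < 2L) validation_error("n_bins must be >= 2")
  apply(expr$values, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x) || max(x) == min(x)) return(0)
    ## half-open bins [min, min+w), ..., last bin closed at max
    idx <- pmin(floor((x - min(x)) / (max(x) - min(x)) * n_bins) + 1L, n_bins)
    p <- tabulate(idx, nbins = n_bins) / length(x)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Filter genes with low-information expression distributions
#'
#' Genes whose binned expression entropy (see [gene_entropy()]) falls below
#' `min_entropy` bits are removed.  When `min_entropy` is `NULL` the lowest
#' 10% of entropies are removed instead, a parameter-free default for data
#' without a natural cutoff.
#'
#' @param expr an [expression_matrix()].
#' @param n_bins bins used to discretise each gene (default 10).
#' @param min_entropy entropy threshold in bits, or `NULL` for the decile rule.
#' @return A list with the filtered `expr` and a `report`.
#' @export
entropy_filter <- function(expr, n_bins = 10L, min_entropy = NULL) {
  ent <- gene_entropy(expr, n_bins)
  thr <- if (is.null(min_entropy)) quantile(ent, 0.10, names = FALSE) else min_entropy
  keep <- if (is.null(min_entropy)) ent > thr | ent >= max(ent) else ent >= thr
  apply_gene_filter(expr, keep, "entropy",
                    list(n_bins = n_bins, min_entropy = min_entropy,
                         threshold_used = thr))
}

#' Filter genes by replicate max/min expression ratio
#'
#' A gene is removed when, within any replicate group, the ratio of its
#' maximum to minimum expression (after adding `pseudocount` to both) exceeds
#' `max_ratio`.  The default ratio of 100 flags measurements that are wildly
#' inconsistent between technical or biological replicates.
#'
#' @param expr an [expression_matrix()].
#' @param replicate_groups named list mapping group name -> sample identifiers
#'   (each group needs >= 2 samples).
#' @param max_ratio allowed max/min ratio (default 100).
#' @param pseudocount added to numerator and denominator (default 0; set > 0
#'   to guard against zero expression).
#' @return A list with the filtered `expr` and a `report`.
#' @export
replicate_ratio_filter <- function(expr, replicate_groups, max_ratio = 100,
                                   pseudocount = 0) {
  stopifnot(inherits(expr, "expression_matrix"), max_ratio > 0, pseudocount >= 0)
  if (!length(replicate_groups)) validation_error("no replicate groups given")
  for (g in names(replicate_groups)) {
    ids <- replicate_groups[[g]]
    if (length(ids) < 2L)
      validation_error("replicate group '%s' has fewer than 2 samples", g)
    unknown <- setdiff(ids, colnames(expr$values))
    if (length(unknown))
      validation_error("replicate group '%s' references unknown samples: %s",
                       g, paste(unknown, collapse = ", "))
  }
  bad <- Reduce(`|`, lapply(replicate_groups, function(ids) {
    sub <- expr$values[, ids, drop = FALSE]
    ratio <- (apply(sub, 1L, max) + pseudocount) /
      (apply(sub, 1L, min) + pseudocount)
    ratio > max_ratio & !is.na(ratio)      # 0/0 with no pseudocount: keep
  }))
  apply_gene_filter(expr, !bad, "replicate_ratio",
                    list(max_ratio = max_ratio, pseudocount = pseudocount,
                         groups = names(replicate_groups)))
}

#' Write filter reports as JSON lines
#'
#' One JSON record per filtering rule, in the order applied.
#'
#' @param reports a list of filter reports as returned by the `filter_*`
#'   functions (the `report` element), or a single report.
#' @param path output path.
#' @export
write_filter_reports <- function(reports, path) {
  if (inherits(reports, "filter_report")) reports <- list(reports)
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(rule = r$rule, genes_removed = r$genes_removed,
                          genes_kept = r$genes_kept, parameters = r$parameters),
                     auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
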