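# Independent oracles used to cross-check the package's own computations.
# The LP oracle re-derives the linear program from the feature data with its
# own code path (different variable ordering, different row ordering) and
# solves it with an entirely separate solver (scipy's HiGHS via the python
# interpreter), so an agreement is evidence about both the model
# construction and the simplex implementation.

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter found for the LP oracle")
  p
}

# independent LP construction: variables ordered [Z1, Z2, eta(j,k row-major), w]
oracle_build <- function(features, params) {
  labels <- features$labels
  cls <- levels(labels)
  C <- length(cls)
  m <- length(labels)
  p <- features$n_edges
  n <- features$n_nodes
  nf <- p + n
  # deviations, recomputed here from the raw blocks
  dev <- function(j, k, i) {
    ix <- which(labels == cls[k])
    if (i <= p) {
      a <- features$aff_values[, i]
      features$edge_multiplier[i, k] * (a[j] - mean(a[ix]))^2
    } else {
      x <- features$node_values[, i - p]
      (x[j] - mean(x[ix]))^2
    }
  }
  nv <- 2 * C + m * C + nf
  iZ1 <- seq_len(C); iZ2 <- C + seq_len(C)
  ieta <- function(j, k) 2 * C + (j - 1) * C + k
  iw <- 2 * C + m * C + seq_len(nf)
  cc <- numeric(nv)
  cc[iZ1] <- params$alpha; cc[iZ2] <- -params$alpha
  cc[2 * C + seq_len(m * C)] <- params$penalty_C
  cc[iw] <- c(rep(1, p), rep(params$lambda, n))
  A <- NULL; b <- NULL
  for (j in seq_len(m)) for (k in seq_len(C)) {
    row <- numeric(nv)
    dv <- vapply(seq_len(nf), function(i) dev(j, k, i), numeric(1))
    if (labels[j] == cls[k]) {
      row[iw] <- dv; row[iZ1[k]] <- -1; row[ieta(j, k)] <- -1
    } else {
      row[iw] <- -dv; row[iZ2[k]] <- 1; row[ieta(j, k)] <- -1
    }
    A <- rbind(A, row); b <- c(b, 0)
  }
  for (k in seq_len(C)) {
    row <- numeric(nv); row[iZ1[k]] <- 1; row[iZ2[k]] <- -1
    A <- rbind(A, row); b <- c(b, 0)
  }
  for (i in iw) {
    row <- numeric(nv); row[i] <- 1
    A <- rbind(A, row); b <- c(b, 1)
  }
  list(cc = cc, A = unname(A), b = b)
}

# solve a batch of LPs (list of cc/A/b) with scipy HiGHS; returns a data.frame
# with status (scipy codes: 0 optimal, 3 unbounded) and objective
scipy_lp_batch <- function(lps) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(lps, function(l)
    list(c = l$cc, A = l$A, b = l$b)), infile, digits = NA, matrix = "rowmajor")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("probs = json.load(open(%s))", deparse(infile)),
    "out = []",
    "for p in probs:",
    "    r = linprog(np.array(p['c']), A_ub=np.array(p['A']),",
    "                b_ub=np.array(p['b']), bounds=(0, None), method='highs')",
    "    out.append({'status': int(r.status),",
    "                'objective': float(r.fun) if r.status == 0 else None})",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outfile))), script)
  rc <- system2(python_bin(), script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("scipy oracle failed: ", paste(rc, collapse = "\n"))
  res <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  data.frame(status = vapply(res, `[[`, 0L, "status"),
             objective = vapply(res, function(r)
               if (is.null(r$objective)) NA_real_ else r$objective, 0))
}

# brute-force Spearman: explicit ranking, then Pearson on the ranks
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force AUC: loop over all positive-negative pairs, ties count 1/2
brute_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# random small feature system for oracle comparisons: log-normal expression,
# a few edges, random two-class labels
random_small_features <- function(seed) {
  set.seed(seed)
  n_genes <- sample(4:6, 1)
  m <- sample(6:12, 1)
  vals <- matrix(exp(rnorm(n_genes * m, sample(0:3, 1), runif(1, 0.3, 1))),
                 n_genes, m,
                 dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                 sprintf("s%d", seq_len(m))))
  labels <- c(rep(c("A", "B"), 3), sample(c("A", "B"), m - 6, replace = TRUE))
  expr <- expression_matrix(vals, labels = labels)
  n_edges <- sample(0:2, 1)
  feats <- NULL
  if (n_edges > 0) {
    pairs <- t(replicate(n_edges, sample(rownames(vals), 2)))
    net <- ppi_network(pairs)
    if (nrow(net) > 0) {
      aff <- mass_action_affinity(expr, net)
      wts <- threshold_coexpression(spearman_coexpression(expr, net), 0.2)
      feats <- tryCatch(assemble_features(aff, wts, expr,
                                          node_genes = rownames(vals)[1:3]),
                        error = function(e) NULL)
    }
  }
  if (is.null(feats))
    feats <- assemble_features(NULL, NULL, expr,
                               node_genes = rownames(vals)[1:3])
  feats
}
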