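#' Model parameters for the biomarker-selection linear program
#'
#' @param lambda trade-off between edge-weight and node-weight cost in the
#'   objective (default 1: interactions and single genes are equally costly,
#'   i.e. equally important as biomarkers).
#' @param alpha weight of the radius-gap term \eqn{\sum_k Z1_k - Z2_k}
#'   (default 0.1).  A smaller `alpha` yields fewer biomarkers; too small and
#'   the trivial all-zero solution becomes optimal.
#' @param penalty_C penalty per unit of slack (default 100).  Larger values
#'   buy fewer classification errors; written `penalty_C` because the class
#'   count is conventionally also called C.
#' @param coexpression_cutoff co-expression cutoff \eqn{k} applied upstream
#'   (recorded here so one object carries the full configuration).
#' @param weight_tol a feature counts as selected when its optimal weight
#'   \eqn{w_i \ge} `weight_tol` (default 1e-6).
#' @param standardize z-score each feature's deviations before building the
#'   constraints (default `FALSE`; edge deviations live on a squared scale,
#'   so this flag can help when mixing very unequal units).
#' @export
model_params <- function(lambda = 1, alpha = 0.1, penalty_C = 100,
                         coexpression_cutoff = 0.5, weight_tol = 1e-6,
                         standardize = FALSE) {
  stopifnot(lambda >= 0, alpha >= 0, penalty_C > 0, weight_tol > 0)
  structure(list(lambda = lambda, alpha = alpha, penalty_C = penalty_C,
                 coexpression_cutoff = coexpression_cutoff,
                 weight_tol = weight_tol, standardize = standardize),
            class = "model_params")
}

#' Build the ellipsoid-separation linear program
#'
#' Variables are the feature weights \eqn{w} (one per edge feature, one per
#' node feature), per-class inner and outer radii \eqn{Z1_k \le Z2_k}, and a
#' slack \eqn{\eta_{jk}} per sample-class pair.  With the precomputed
#' constants \eqn{d_{jik} = |B_{ik}| (a_{ji} - \bar a_{iK})^2} for edges and
#' \eqn{d_{jik} = (x_{ji} - \bar x_{iK})^2} for nodes, the program is
#'
#' \deqn{\min \sum_{edges} w_i + \lambda \sum_{nodes} w_i +
#'       \alpha \sum_k (Z1_k - Z2_k) + C \sum_{j,k} \eta_{jk}}
#'
#' subject to, for every sample \eqn{j} and class \eqn{k},
#' \eqn{\sum_i w_i d_{jik} \le Z1_k + \eta_{jk}} when \eqn{j} belongs to
#' class \eqn{k} (in-class samples fall inside the inner radius up to slack)
#' and \eqn{\sum_i w_i d_{jik} \ge Z2_k - \eta_{jk}} otherwise (other
#' samples fall outside the outer radius), with
#' \eqn{0 \le Z1_k \le Z2_k}, \eqn{0 \le w_i \le 1}, \eqn{\eta \ge 0}.
#' The all-zero point satisfies every constraint, so the optimal objective
#' is never positive; a strictly negative optimum requires some class's
#' radius gap to pay for the selected weights and slack.
#'
#' @param features a `feature_system` from [assemble_features()].
#' @param classes a `class_spec` from [class_centroids()] computed on the
#'   same data, or `NULL` to compute it here.
#' @param params a [model_params()].
#' @return An `lp_instance`: objective `cc`, dense constraint matrix `A`,
#'   right-hand side `b` (rows are `<=` constraints), index `blocks`, the
#'   deviation array `d` (m x C x features), and bookkeeping fields.
#' @export
build_lp <- function(features, classes = NULL, params = model_params()) {
  stopifnot(inherits(features, "feature_system"), inherits(params, "model_params"))
  p <- features$n_edges; n <- features$n_nodes
  if (p + n < 1L) validation_error("empty feature system")
  labels <- features$labels
  m <- length(labels)
  cls <- levels(labels)
  C <- length(cls)
  if (C < 2L) validation_error("need at least 2 classes")
  members <- split(seq_len(m), labels)

  ## deviation constants d[j, k, i]
  d <- array(0, dim = c(m, C, p + n))
  if (p > 0) {
    for (k in seq_len(C)) {
      cent <- colMeans(features$aff_values[members[[k]], , drop = FALSE])
      dev2 <- sweep(features$aff_values, 2L, cent)^2
      d[, k, seq_len(p)] <- sweep(dev2, 2L, features$edge_multiplier[, k], "*")
    }
  }
  if (n > 0) {
    for (k in seq_len(C)) {
      cent <- colMeans(features$node_values[members[[k]], , drop = FALSE])
      d[, k, p + seq_len(n)] <- sweep(features$node_values, 2L, cent)^2
    }
  }
  if (params$standardize) {
    for (i in seq_len(p + n)) {
      s <- sd(d[, , i])
      if (s > 0) d[, , i] <- d[, , i] / s
    }
  }

  nf <- p + n
  nv <- nf + 2L * C + m * C
  iw <- seq_len(nf)
  iZ1 <- nf + seq_len(C)
  iZ2 <- nf + C + seq_len(C)
  ieta <- function(j, k) nf + 2L * C + (k - 1L) * m + j
  cc <- c(rep(1, p), rep(params$lambda, n),
          rep(params$alpha, C), rep(-params$alpha, C),
          rep(params$penalty_C, m * C))

  nr <- m * C + C + nf
  A <- matrix(0, nr, nv)
  b <- numeric(nr)
  rowtype <- character(nr)
  r <- 0L
  for (k in seq_len(C)) {
    for (j in seq_len(m)) {
      r <- r + 1L
      if (labels[j] == cls[k]) {            # sum w d - Z1_k - eta <= 0
        A[r, iw] <- d[j, k, ]
        A[r, iZ1[k]] <- -1
        rowtype[r] <- "in"
      } else {                              # -(sum w d) + Z2_k - eta <= 0
        A[r, iw] <- -d[j, k, ]
        A[r, iZ2[k]] <- 1
        rowtype[r] <- "out"
      }
      A[r, ieta(j, k)] <- -1
    }
  }
  for (k in seq_len(C)) {                   # Z1_k - Z2_k <= 0
    r <- r + 1L
    A[r, iZ1[k]] <- 1
    A[r, iZ2[k]] <- -1
    rowtype[r] <- "radius_order"
  }
  for (i in iw) {                           # w_i <= 1
    r <- r + 1L
    A[r, i] <- 1
    b[r] <- 1
    rowtype[r] <- "weight_ub"
  }
  structure(list(cc = cc, A = A, b = b, rowtype = rowtype, d = d,
                 blocks = list(w = iw, Z1 = iZ1, Z2 = iZ2,
                               eta = nf + 2L * C + seq_len(m * C)),
                 n_edges = p, n_nodes = n, n_samples = m, n_classes = C,
                 classes = cls, labels = labels, params = params,
                 feature_ids = c(if (p > 0) paste0(features$edges$u, ":", features$edges$v),
                                 features$node_genes)),
            class = "lp_instance")
}

#' Solve the biomarker-selection linear program
#'
#' Runs the deterministic dense simplex (see [simplex_solve()]) on an
#' instance built by [build_lp()] and unpacks the solution into its variable
#' blocks.  A solve whose scaled primal feasibility residual exceeds
#' `residual_tol` is reported as `failed` rather than returned silently.
#'
#' @param lp an `lp_instance`.
#' @param maxit simplex iteration cap (default scales with problem size).
#' @param residual_tol maximum accepted scaled feasibility violation.
#' @return An `lp_solution`: `status` (`"optimal"`, `"unbounded"`,
#'   `"failed"`), weight vector `w` (named by feature), radii `Z1`, `Z2`,
#'   slack matrix `eta` (samples x classes), `objective`, `residual`, and
#'   `iterations`.
#' @export
solve_lp <- function(lp, maxit = NULL, residual_tol = 1e-8) {
  stopifnot(inherits(lp, "lp_instance"))
  sol <- simplex_solve(lp$cc, lp$A, lp$b, maxit = maxit)
  status <- sol$status
  if (status == "optimal" && sol$residual > residual_tol) status <- "failed"
  w <- sol$x[lp$blocks$w]
  names(w) <- lp$feature_ids
  eta <- matrix(sol$x[lp$blocks$eta], lp$n_samples, lp$n_classes,
                dimnames = list(NULL, lp$classes))
  structure(list(status = status,
                 w = w,
                 Z1 = setNames(sol$x[lp$blocks$Z1], lp$classes),
                 Z2 = setNames(sol$x[lp$blocks$Z2], lp$classes),
                 eta = eta,
                 objective = sol$objective,
                 residual = sol$residual,
                 iterations = sol$iterations),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("lp_solution: %s, objective %.6g, %d selected weights (>= 1e-6), total slack %.4g\n",
              x$status, x$objective, sum(x$w >= 1e-6), sum(x$eta)))
  invisible(x)
}

#' Extract the selected biomarkers from an optimal solution
#'
#' Features whose weight reaches `params$weight_tol` are reported, split
#' into edge and node biomarkers and sorted by decreasing weight (ties
#' broken by feature index, so the output is deterministic).  The all-zero
#' solution -- no feature selected -- is flagged as trivial: it signals an
#' over-regularised `alpha`/`penalty_C` choice, not an error.
#'
#' @param sol an `lp_solution` with `status == "optimal"`.
#' @param features the `feature_system` the instance was built from.
#' @param params the [model_params()] used (supplies `weight_tol`).
#' @return A `biomarker_set`: data.frames `edge_biomarkers`
#'   (feature, gene_u, gene_v, weight, B) and `node_biomarkers`
#'   (gene, weight), logical `trivial`, and the `params`.
#' @export
extract_biomarkers <- function(sol, features, params = model_params()) {
  stopifnot(inherits(sol, "lp_solution"), inherits(features, "feature_system"))
  if (sol$status != "optimal")
    validation_error("cannot extract biomarkers from a %s solution", sol$status)
  p <- features$n_edges
  tol <- params$weight_tol
  sel <- which(sol$w >= tol)
  ord <- sel[order(-sol$w[sel], sel)]
  esel <- ord[ord <= p]
  nsel <- ord[ord > p]
  edge_bm <- data.frame(
    feature = names(sol$w)[esel],
    gene_u = features$edges$u[esel],
    gene_v = features$edges$v[esel],
    weight = unname(sol$w[esel]),
    B = if (length(esel)) apply(features$edge_B[esel, , drop = FALSE], 1L,
                                function(b) b[which.max(abs(b))]) else numeric(0),
    stringsAsFactors = FALSE)
  node_bm <- data.frame(
    gene = features$node_genes[nsel - p],
    weight = unname(sol$w[nsel]),
    stringsAsFactors = FALSE)
  rownames(edge_bm) <- rownames(node_bm) <- NULL
  structure(list(edge_biomarkers = edge_bm, node_biomarkers = node_bm,
                 trivial = length(sel) == 0L, params = params,
                 objective = sol$objective),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  if (x$trivial) {
    cat("biomarker_set: trivial all-zero solution (no biomarkers selected)\n")
  } else {
    cat(sprintf("biomarker_set: %d edge + %d node biomarkers\n",
                nrow(x$edge_biomarkers), nrow(x$node_biomarkers)))
  }
  invisible(x)
}

#' Count biomarkers in a set
#' @param bm a `biomarker_set`.
#' @return Named integer vector: edges, nodes, total.
#' @export
n_biomarkers <- function(bm) {
  stopifnot(inherits(bm, "biomarker_set"))
  c(edges = nrow(bm$edge_biomarkers), nodes = nrow(bm$node_biomarkers),
    total = nrow(bm$edge_biomarkers) + nrow(bm$node_biomarkers))
}

#' Grid search over the radius-gap and slack-penalty parameters
#'
#' Solves the selection program for every `(alpha, penalty_C)` cell and
#' records whether the solution is trivial, the biomarker count, total
#' slack, and objective.  Two selection rules are available:
#' `"sparsest_accurate"` (default) picks, among non-trivial cells, the
#' largest `penalty_C` and then the smallest `alpha` -- the largest
#' affordable error penalty with the sparsest panel it admits;
#' `"cv_auc"` picks the cell whose selected panel maximises cross-validated
#' AUC (requires `expr`), with the same tie-break.
#'
#' @param features a `feature_system`.
#' @param params base [model_params()]; `alpha`/`penalty_C` are overridden
#'   cell by cell.
#' @param alpha_grid,C_grid parameter grids (defaults: 0.02, 0.1, 0.5, 1 and
#'   0.1, 1, 10, 100).
#' @param selection_rule `"sparsest_accurate"` or `"cv_auc"`.
#' @param expr expression matrix, needed for `"cv_auc"`.
#' @param k_folds,seed cross-validation settings for `"cv_auc"`.
#' @return A list with `best` ([model_params()] of the chosen cell), `grid`
#'   (one row per cell), and `solutions` (per-cell `lp_solution`s).
#' @export
grid_search <- function(features, params = model_params(),
                        alpha_grid = c(0.02, 0.1, 0.5, 1),
                        C_grid = c(0.1, 1, 10, 100),
                        selection_rule = c("sparsest_accurate", "cv_auc"),
                        expr = NULL, k_folds = 10L, seed = 1L) {
  stopifnot(length(alpha_grid) > 0, length(C_grid) > 0)
  selection_rule <- match.arg(selection_rule)
  cells <- expand.grid(alpha = alpha_grid, penalty_C = C_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  grid <- cells
  grid$status <- NA_character_
  grid$trivial <- NA
  grid$n_biomarkers <- NA_integer_
  grid$total_slack <- NA_real_
  grid$objective <- NA_real_
  grid$cv_auc <- NA_real_
  for (i in seq_len(nrow(cells))) {
    pr <- params
    pr$alpha <- cells$alpha[i]
    pr$penalty_C <- cells$penalty_C[i]
    lp <- build_lp(features, params = pr)
    sol <- solve_lp(lp)
    res[[i]] <- sol
    grid$status[i] <- sol$status
    if (sol$status == "optimal") {
      bm <- extract_biomarkers(sol, features, pr)
      grid$trivial[i] <- bm$trivial
      grid$n_biomarkers[i] <- n_biomarkers(bm)[["total"]]
      grid$total_slack[i] <- sum(sol$eta)
      grid$objective[i] <- sol$objective
      if (selection_rule == "cv_auc" && !bm$trivial) {
        if (is.null(expr)) validation_error("selection_rule 'cv_auc' needs expr")
        cv <- kfold_evaluate(expr, bm, k_folds = k_folds, seed = seed,
                             mode = "select_once")
        grid$cv_auc[i] <- cv$auc
      }
    }
  }
  ok <- which(grid$status == "optimal" & !grid$trivial)
  if (!length(ok))
    validation_error("every grid cell gave the trivial solution; extend the grid towards larger alpha or smaller penalty_C")
  pick <- if (selection_rule == "cv_auc") {
    best_auc <- max(grid$cv_auc[ok], na.rm = TRUE)
    cand <- ok[!is.na(grid$cv_auc[ok]) & grid$cv_auc[ok] >= best_auc - 1e-12]
    cand[order(-grid$penalty_C[cand], grid$alpha[cand])][1L]
  } else {
    ok[order(-grid$penalty_C[ok], grid$alpha[ok])][1L]
  }
  best <- params
  best$alpha <- grid$alpha[pick]
  best$penalty_C <- grid$penalty_C[pick]
  list(best = best, grid = grid, solutions = res, picked = pick)
}
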