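#' Confusion-table metrics
#'
#' Sensitivity \eqn{Sn = TP/(TP+FN)}, specificity \eqn{Sp = TN/(TN+FP)} and
#' accuracy \eqn{ACC = (TP+TN)/(TP+TN+FP+FN)}.
#'
#' @param TP,TN,FP,FN non-negative counts; `TP+FN` and `TN+FP` must be
#'   positive, otherwise the corresponding metric is undefined and an error
#'   is raised rather than a silent 0.
#' @return A `confusion_metrics` list with the four counts and `Sn`, `Sp`,
#'   `ACC`.
#' @examples
#' confusion_metrics(9, 8, 2, 1)  # Sn 0.9, Sp 0.8, ACC 0.85
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    validation_error("counts must be non-negative integers")
  if (TP + FN == 0) validation_error("Sn undefined: no positive samples (TP+FN = 0)")
  if (TN + FP == 0) validation_error("Sp undefined: no negative samples (TN+FP = 0)")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 Sn = TP / (TP + FN),
                 Sp = TN / (TN + FP),
                 ACC = (TP + TN) / (TP + TN + FP + FN)),
            class = "confusion_metrics")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with tie correction: ties between a
#' positive and a negative score count one half.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels binary labels, any two-valued vector.
#' @param positive the label treated as positive; default the larger factor
#'   level.
#' @return AUC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = NULL) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L)
    validation_error("AUC needs exactly two classes present (got %d)", nlevels(labels))
  if (is.null(positive)) positive <- levels(labels)[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)                       # average ranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## logistic regression with a small L2 (ridge) penalty, fitted by IRLS.
## Used only as the documented stabiliser when the ordinary fit separates
## perfectly; the penalty keeps coefficients finite and the scorer
## deterministic.  (No installed package fits a ridge GLM for a single
## predictor without side conditions, hence this small local fit.)
ridge_logistic <- function(x, y01, ridge = 1e-3, maxit = 100L) {
  X <- cbind(1, x)
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(ridge, ncol(X) - 1L)))   # intercept unpenalised
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wt <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X, y01 - mu) - pen %*% beta
    H <- crossprod(X * Wt, X) + pen
    step <- drop(solve(H, g))
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Binomial GLM classifier over a feature matrix
#'
#' Fits an intercept-plus-linear binomial model on the training features and
#' returns a scorer mapping new feature rows to probability-like scores in
#' (0, 1).  Under perfect separation (where the ordinary fit diverges) the
#' model is refitted with a small ridge penalty, keeping the scorer finite
#' and deterministic.  A training matrix with zero columns yields the
#' intercept-only scorer (all scores equal).
#'
#' @param x training feature matrix (samples x features).
#' @param y training labels, two classes, >= 2 samples in each.
#' @param positive label scored towards 1; default the larger factor level.
#' @param ridge penalty used by the separation fallback.
#' @return A function `f(newx)` returning scores.
#' @export
glm_classifier <- function(x, y, positive = NULL, ridge = 1e-3) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) validation_error("classifier needs exactly 2 classes")
  if (any(table(y) < 2L)) validation_error("need >= 2 training samples per class")
  if (is.null(positive)) positive <- levels(y)[2L]
  y01 <- as.numeric(y == positive)
  if (ncol(x) == 0L) {
    p0 <- mean(y01)
    return(function(newx) rep(p0, nrow(as.matrix(newx))))
  }
  keep <- apply(x, 2L, function(col) sd(col) > 0)
  if (!any(keep)) {
    p0 <- mean(y01)
    return(function(newx) rep(p0, nrow(as.matrix(newx))))
  }
  xk <- x[, keep, drop = FALSE]
  ## centre/scale for numerical sanity; folded into the returned scorer
  ctr <- colMeans(xk); scl <- apply(xk, 2L, sd)
  xs <- scale(xk, ctr, scl)
  df <- data.frame(y01 = y01, xs)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y01 ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- if (separated) ridge_logistic(xs, y01, ridge = ridge) else
    ifelse(is.na(coef(fit)), 0, coef(fit))
  function(newx) {
    newx <- as.matrix(newx)
    ns <- scale(newx[, keep, drop = FALSE], ctr, scl)
    drop(1 / (1 + exp(-(beta[1L] + ns %*% beta[-1L]))))
  }
}

#' Feature matrix of a biomarker panel
#'
#' Builds the sample x feature matrix a downstream classifier consumes:
#' one mass-action affinity column (product of the two genes' expression)
#' per edge biomarker and one expression column per node biomarker.
#'
#' @param expr an [expression_matrix()] containing all involved genes.
#' @param bm a `biomarker_set`, or a list with elements `edges`
#'   (data.frame with `gene_u`, `gene_v`) and/or `genes` (character).
#' @return Numeric matrix, samples x features (possibly zero columns for a
#'   trivial panel).
#' @export
biomarker_features <- function(expr, bm) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (inherits(bm, "biomarker_set")) {
    edges <- bm$edge_biomarkers
    genes <- bm$node_biomarkers$gene
  } else {
    edges <- bm$edges
    genes <- bm$genes
  }
  cols <- list()
  if (!is.null(edges) && nrow(edges)) {
    miss <- setdiff(c(edges$gene_u, edges$gene_v), rownames(expr$values))
    if (length(miss))
      validation_error("biomarker gene(s) absent from expression matrix: %s",
                       paste(head(miss, 3L), collapse = ", "))
    ecol <- t(expr$values[edges$gene_u, , drop = FALSE] *
              expr$values[edges$gene_v, , drop = FALSE])
    colnames(ecol) <- paste0(edges$gene_u, ":", edges$gene_v)
    cols$edges <- ecol
  }
  if (!is.null(genes) && length(genes)) {
    miss <- setdiff(genes, rownames(expr$values))
    if (length(miss))
      validation_error("biomarker gene(s) absent from expression matrix: %s",
                       paste(head(miss, 3L), collapse = ", "))
    cols$genes <- t(expr$values[genes, , drop = FALSE])
  }
  if (!length(cols))
    return(matrix(numeric(0), ncol(expr$values), 0,
                  dimnames = list(colnames(expr$values), NULL)))
  do.call(cbind, cols)
}

## deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  labels <- factor(as.character(labels))
  if (any(table(labels) < k))
    validation_error("k_folds = %d exceeds the size of the smallest class (%d)",
                     k, min(table(labels)))
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds
}

#' Stratified k-fold cross-validated evaluation
#'
#' Scores every sample exactly once out-of-fold with a binomial GLM over a
#' biomarker panel and reports per-fold and pooled confusion metrics plus
#' the AUC of the pooled out-of-fold scores.
#'
#' Two protocols are supported.  `mode = "select_once"` fixes the panel
#' before cross-validation -- either a ready `biomarker_set` or the result
#' of applying `selector` to the full data -- and only the classifier is
#' re-fitted per fold.  This is the common published protocol, but the
#' selection has seen the test samples, so its estimates lean optimistic.
#' `mode = "nested"` re-runs `selector` inside every training fold, paying
#' more computation for leakage-free estimates.  See the methods vignette.
#'
#' @param expr an [expression_matrix()] with two-class labels.
#' @param selector a `biomarker_set` (only valid with `"select_once"`), or a
#'   function `f(expr_train)` returning one.
#' @param k_folds number of folds (default 10), at most the smallest class.
#' @param seed fold-assignment seed (mandatory part of the design).
#' @param mode `"select_once"` or `"nested"`.
#' @param positive positive class; default the larger factor level.
#' @param threshold score cutoff for the confusion table (default 0.5).
#' @return A `cv_result`: `folds`, `scores` (out-of-fold, in sample order),
#'   `per_fold` metric table, pooled `Sn`, `Sp`, `ACC`, `auc`, and the mode.
#' @export
kfold_evaluate <- function(expr, selector, k_folds = 10L, seed = 1L,
                           mode = c("select_once", "nested"),
                           positive = NULL, threshold = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  mode <- match.arg(mode)
  labels <- expr$labels
  if (is.null(labels)) validation_error("expression matrix has no class labels")
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L)
    validation_error("cross-validated evaluation supports exactly 2 classes")
  if (is.null(positive)) positive <- levels(labels)[2L]
  folds <- stratified_folds(labels, k_folds, seed)
  m <- length(labels)

  fixed_panel <- NULL
  if (mode == "select_once") {
    fixed_panel <- if (is.function(selector)) selector(expr) else selector
  } else if (!is.function(selector)) {
    validation_error("nested mode needs a selector function, not a fixed panel")
  }

  scores <- numeric(m)
  per_fold <- data.frame(fold = seq_len(k_folds), Sn = NA_real_,
                         Sp = NA_real_, ACC = NA_real_)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    sub <- expression_matrix(expr$values[, !test, drop = FALSE],
                             labels = labels[!test])
    panel <- if (mode == "select_once") fixed_panel else selector(sub)
    feats_train <- biomarker_features(sub, panel)
    feats_test <- biomarker_features(
      expression_matrix(expr$values[, test, drop = FALSE], labels = labels[test]),
      panel)
    scorer <- glm_classifier(feats_train, labels[!test], positive = positive)
    scores[test] <- scorer(feats_test)
    pred <- scores[test] >= threshold
    truth <- labels[test] == positive
    if (any(truth) && any(!truth)) {
      cmx <- confusion_metrics(sum(pred & truth), sum(!pred & !truth),
                               sum(pred & !truth), sum(!pred & truth))
      per_fold[f, c("Sn", "Sp", "ACC")] <- c(cmx$Sn, cmx$Sp, cmx$ACC)
    }
  }
  pred <- scores >= threshold
  truth <- labels == positive
  pooled <- confusion_metrics(sum(pred & truth), sum(!pred & !truth),
                              sum(pred & !truth), sum(!pred & truth))
  structure(list(folds = folds, scores = scores, per_fold = per_fold,
                 Sn = pooled$Sn, Sp = pooled$Sp, ACC = pooled$ACC,
                 auc = auroc(scores, labels, positive = positive),
                 mode = mode, seed = seed, k_folds = k_folds,
                 positive = positive),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%d-fold, %s): Sn %.4f  Sp %.4f  ACC %.4f  AUC %.4f\n",
              x$k_folds, x$mode, x$Sn, x$Sp, x$ACC, x$auc))
  invisible(x)
}

#' Write cross-validation metrics
#'
#' `path_json` gets the per-fold and pooled metrics; `path_tsv` gets a
#' one-line table in the column order Sn, Sp, ACC, AUC.
#'
#' @param cv a `cv_result`.
#' @param path_json,path_tsv output paths (either may be `NULL`).
#' @export
write_cv_metrics <- function(cv, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  if (!is.null(path_json))
    jsonlite::write_json(list(per_fold = cv$per_fold,
                              pooled = list(Sn = cv$Sn, Sp = cv$Sp,
                                            ACC = cv$ACC, AUC = cv$auc),
                              mode = cv$mode, seed = cv$seed,
                              k_folds = cv$k_folds),
                         path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_tsv)) {
    tab <- data.frame(Sn = cv$Sn, Sp = cv$Sp, ACC = cv$ACC, AUC = cv$auc)
    write.table(format(tab, digits = 6), path_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(cv)
}

#' Per-gene Welch t-test gene selector
#'
#' The classical node-only baseline: a two-sample unequal-variance t-test
#' per gene, returning the genes with p below `p_threshold` (default
#' 5e-5).
#'
#' @param expr an [expression_matrix()] with two-class labels.
#' @param p_threshold significance cutoff.
#' @param labels class labels; default `expr$labels`.
#' @return Character vector of selected genes, with the p-values as the
#'   `p_values` attribute (all genes, named).
#' @export
ttest_selector <- function(expr, p_threshold = 5e-5, labels = expr$labels) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(labels)) validation_error("no class labels")
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) validation_error("t-test selector needs 2 classes")
  if (any(table(labels) < 2L)) validation_error("need >= 2 samples per class")
  g1 <- labels == levels(labels)[1L]
  pv <- apply(expr$values, 1L, function(x) {
    if (sd(x[g1]) == 0 && sd(x[!g1]) == 0) return(1)
    t.test(x[g1], x[!g1])$p.value
  })
  sel <- names(pv)[pv < p_threshold]
  attr(sel, "p_values") <- pv
  sel
}
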