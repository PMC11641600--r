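test_that("confusion metrics match their closed forms", {
  cm <- confusion_metrics(9, 8, 2, 1)
  expect_equal(cm$Sn, 0.9)
  expect_equal(cm$Sp, 0.8)
  expect_equal(cm$ACC, 0.85)
  perfect <- confusion_metrics(5, 7, 0, 0)
  expect_equal(c(perfect$Sn, perfect$Sp, perfect$ACC), c(1, 1, 1))
  expect_error(confusion_metrics(0, 5, 2, 0), class = "ppiacoexp_validation_error")
  expect_error(confusion_metrics(-1, 5, 2, 1), class = "ppiacoexp_validation_error")
})

test_that("AUC is the Mann-Whitney statistic with tie correction", {
  expect_equal(auroc(c(1, 2, 10, 20), c(0, 0, 1, 1), positive = "1"), 1)
  expect_equal(auroc(rep(3, 6), rep(c(0, 1), 3), positive = "1"), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = "1"),
               0.75)
  expect_error(auroc(1:4, rep("a", 4)), class = "ppiacoexp_validation_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  for (rep in 1:10) {
    sc <- rnorm(30)
    lab <- sample(c("n", "p"), 30, replace = TRUE, prob = c(.5, .5))
    if (length(unique(lab)) < 2) next
    a <- auroc(sc, lab, positive = "p")
    expect_equal(auroc(exp(sc), lab, positive = "p"), a)
    expect_equal(auroc(rank(sc), lab, positive = "p"), a)
    expect_equal(auroc(-1 / (1 + exp(-sc)) * -1, lab, positive = "p"), a)
  }
})

test_that("the GLM scorer is monotone, symmetric under label swap, and flat on constants", {
  set.seed(31)
  x <- matrix(c(rnorm(10, -1, .3), rnorm(10, 1, .3)), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  scorer <- glm_classifier(x, y, positive = "b")
  grid <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  expect_true(all(diff(scorer(grid)) > 0))

  y_swapped <- rep(c("b", "a"), each = 10)
  sc1 <- glm_classifier(x, y, positive = "b")(x)
  sc2 <- glm_classifier(x, y_swapped, positive = "b")(x)
  expect_equal(auroc(sc2, y_swapped, positive = "b"),
               1 - auroc(sc1, y_swapped, positive = "b"), tolerance = 1e-9)

  const <- matrix(1, 20, 1)
  csc <- glm_classifier(const, y)(const)
  expect_equal(auroc(csc, y, positive = "b"), 0.5)
})

test_that("perfect separation falls back to a finite deterministic ridge fit", {
  x <- matrix(c(1:5, 101:105), ncol = 1)
  y <- rep(c("a", "b"), each = 5)
  s1 <- glm_classifier(x, y, positive = "b")
  s2 <- glm_classifier(x, y, positive = "b")
  newx <- matrix(c(0, 50, 200), ncol = 1)
  expect_true(all(is.finite(s1(newx))))
  expect_identical(s1(newx), s2(newx))
  expect_true(all(diff(s1(newx)) > 0))
})

test_that("the internal ridge fit approaches the ordinary GLM as the penalty vanishes", {
  set.seed(41)
  x <- matrix(rnorm(60), ncol = 2)
  y01 <- rbinom(30, 1, 1 / (1 + exp(-(0.5 + x[, 1] - 0.7 * x[, 2]))))
  fit <- glm(y01 ~ x, family = binomial())
  beta <- ppiacoexp:::ridge_logistic(x, y01, ridge = 1e-10)
  expect_equal(unname(beta), unname(coef(fit)), tolerance = 1e-5)
})

test_that("stratified folds partition samples and respect class balance", {
  expr <- toy_expression(n_genes = 4, n_samples = 20)
  sel <- list(genes = rownames(expr$values)[1:2])
  cv <- kfold_evaluate(expr, sel, k_folds = 10, seed = 3)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_true(all(table(cv$folds) == 2))            # 20 samples, 10 folds of 2
  expect_equal(length(cv$scores), 20)

  cv2 <- kfold_evaluate(expr, sel, k_folds = 10, seed = 3)
  expect_identical(cv$folds, cv2$folds)             # same seed, same split
  expect_identical(cv$scores, cv2$scores)
  expect_identical(cv$auc, cv2$auc)

  expect_error(kfold_evaluate(expr, sel, k_folds = 11, seed = 1),
               class = "ppiacoexp_validation_error")
})

test_that("nested mode re-selects inside folds and needs a selector function", {
  sim <- small_sim(seed = 10, samples_per_class = c(10L, 10L))
  sel_fun <- function(e) list(genes = ttest_selector(e, p_threshold = 0.01))
  cv <- kfold_evaluate(sim$expr, sel_fun, k_folds = 5, seed = 1,
                       mode = "nested")
  expect_equal(length(cv$scores), 20)
  expect_true(cv$auc >= 0 && cv$auc <= 1)
  expect_error(kfold_evaluate(sim$expr, list(genes = "g0001"), k_folds = 5,
                              seed = 1, mode = "nested"),
               class = "ppiacoexp_validation_error")
})

test_that("a planted shift is detected and an empty threshold selects nothing", {
  sim <- small_sim(seed = 11, samples_per_class = c(20L, 20L), delta = 10)
  sel <- ttest_selector(sim$expr)
  expect_true(all(sim$truth$node_genes %in% sel))    # 10 SD shift, n = 20/20
  expect_length(ttest_selector(sim$expr, p_threshold = 0), 0)
  one_class <- expression_matrix(sim$expr$values,
                                 labels = rep("A", ncol(sim$expr$values)))
  expect_error(ttest_selector(one_class), class = "ppiacoexp_validation_error")
})

test_that("the t-test selector holds its nominal type-I level on null genes", {
  set.seed(51)
  ng <- 10000
  vals <- matrix(exp(rnorm(ng * 40, 3, 0.5)), ng, 40,
                 dimnames = list(sprintf("g%05d", 1:ng), sprintf("s%02d", 1:40)))
  expr <- expression_matrix(vals, labels = rep(c("A", "B"), each = 20))
  sel <- ttest_selector(expr, p_threshold = 0.05)
  expect_lt(abs(length(sel) / ng - 0.05), 0.01)
})

test_that("cross-validation metrics serialize to JSON and a table row", {
  expr <- toy_expression(n_genes = 4, n_samples = 20)
  cv <- kfold_evaluate(expr, list(genes = "g01"), k_folds = 5, seed = 2)
  pj <- tempfile(fileext = ".json"); pt <- tempfile(fileext = ".tsv")
  write_cv_metrics(cv, pj, pt)
  rec <- jsonlite::fromJSON(pj)
  expect_equal(rec$pooled$AUC, cv$auc)
  tab <- read.delim(pt)
  expect_equal(names(tab), c("Sn", "Sp", "ACC", "AUC"))
})

test_that("edge-only signal is visible to interaction features but not per-gene tests", {
  # planted pairs change correlation between classes with identical marginals:
  # the t-test baseline must select nothing, while the co-expression-surviving
  # affinity features carry class information a GLM can use out-of-fold
  aucs <- vapply(1:5, function(s) {
    sim <- simulate_dataset(simulation_design(n_node_plants = 0L, seed = 300 + s))
    expect_length(ttest_selector(sim$expr, p_threshold = 5e-5), 0)
    net <- prune_network(sim$network, sim$expr)
    aff <- mass_action_affinity(sim$expr, net)
    wts <- threshold_coexpression(spearman_coexpression(sim$expr, net), 0.5)
    feats <- assemble_features(aff, wts, sim$expr, node_genes = character(0))
    panel <- list(edges = data.frame(gene_u = feats$edges$u,
                                     gene_v = feats$edges$v))
    kfold_evaluate(sim$expr, panel, k_folds = 10, seed = s)$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.6)
})
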