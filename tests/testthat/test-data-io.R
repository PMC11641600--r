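test_that("expression round-trips through TSV and CSV unchanged", {
  expr <- toy_expression()
  p_tsv <- write_expr_tsv(expr)
  back <- read_expression(p_tsv, labels = expr$labels)
  expect_equal(back$values, expr$values)
  expect_equal(as.character(back$labels), as.character(expr$labels))

  p_csv <- tempfile(fileext = ".csv")
  write_expression(expr, p_csv, sep = ",")
  expect_equal(read_expression(p_csv)$values, expr$values)
})

test_that("transposed input with samples_as_rows matches the straight read", {
  expr <- toy_expression()
  p1 <- write_expr_tsv(expr)
  p2 <- tempfile(fileext = ".tsv")
  tdf <- data.frame(sample_id = colnames(expr$values), t(expr$values),
                    check.names = FALSE)
  write.table(tdf, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(p2, samples_as_rows = TRUE)$values,
               read_expression(p1)$values)
})

test_that("ragged rows are rejected with the offending line number", {
  p <- tempfile()
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4", "g3\t5"), p)
  expect_error(read_expression(p), "row 4")
})

test_that("duplicate identifiers are rejected", {
  p <- tempfile()
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), p)
  expect_error(read_expression(p), class = "ppiacoexp_validation_error")
  vals <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(vals), class = "ppiacoexp_validation_error")
})

test_that("labels attach by sample name and missing labels are caught", {
  expr <- toy_expression()
  lp <- tempfile()
  writeLines(paste(colnames(expr$values),
                   rep(c("x", "y"), length.out = ncol(expr$values)),
                   sep = "\t"), lp)
  lab <- read_labels(lp)
  e2 <- expression_matrix(expr$values, labels = lab)
  expect_equal(unname(as.character(e2$labels[colnames(expr$values)])),
               rep(c("x", "y"), length.out = ncol(expr$values)))
  expect_error(expression_matrix(expr$values, labels = lab[-1]),
               class = "ppiacoexp_validation_error")
})

test_that("missing-value filter removes exactly the incomplete genes", {
  expr <- toy_expression(n_genes = 5)
  expr$values[2, 3] <- NA
  res <- filter_missing(expr)
  expect_equal(res$report$genes_removed, 1L)
  expect_equal(res$report$genes_kept, 4L)
  expect_equal(rownames(res$expr$values), rownames(expr$values)[-2])
  expect_false(anyNA(res$expr$values))

  clean <- filter_missing(res$expr)            # identity on complete data
  expect_equal(clean$expr$values, res$expr$values)
  expect_equal(clean$report$genes_removed, 0L)

  allna <- expr
  allna$values[, 1] <- NA
  expect_error(filter_missing(allna), class = "ppiacoexp_validation_error")
})

test_that("gene entropy matches hand-computed distributions", {
  vals <- rbind(
    constant = rep(5, 8),
    uniform4 = c(0, 1, 2, 3, 0.1, 1.1, 2.1, 3.1),  # 2 samples in each of 4 bins
    skewed   = c(0, 0.1, 1.1, 2.1, 3, 3.1, 3.2, 3.3))
  colnames(vals) <- paste0("s", 1:8)
  expr <- expression_matrix(vals)
  ent <- gene_entropy(expr, n_bins = 4)
  expect_equal(unname(ent["constant"]), 0)
  expect_equal(unname(ent["uniform4"]), 2)           # log2(4)
  # occupancies (1/4, 1/8, 1/8, 1/2) -> 1.75 bits
  expect_equal(unname(ent["skewed"]), -sum(c(.25, .125, .125, .5) *
                                           log2(c(.25, .125, .125, .5))))
  # the filter contract: entropy below the threshold is dropped
  res <- entropy_filter(expr, n_bins = 4, min_entropy = 1.0)
  expect_false("constant" %in% rownames(res$expr$values))
  expect_true("uniform4" %in% rownames(res$expr$values))
})

test_that("binned occupancy (1/2, 1/4, 1/4, 0) gives 1.5 bits", {
  # 4 bins over [0, 4): values 0,0.5 in bin 1; 1.2 bin 2; 2.2 bin 3; max=3.9
  # falls in bin 4 -- construct 8 samples: 4 in bin1, 2 bin2, 2 bin4? use the
  # direct occupancy instead: p = (1/2, 1/4, 1/4)
  x <- c(0, 0.1, 0.2, 0.3, 1.1, 1.2, 2.9, 2.95)  # bins: 1,1,1,1,2,2,4,4 of 4
  vals <- matrix(x, 1, 8, dimnames = list("g", paste0("s", 1:8)))
  ent <- gene_entropy(expression_matrix(vals), n_bins = 4)
  expect_equal(unname(ent), 1.5)
})

test_that("entropy decile default drops the least-informative genes only", {
  expr <- toy_expression(n_genes = 20, seed = 7)
  expr$values[1, ] <- 3                       # constant, entropy 0
  res <- entropy_filter(expr)
  expect_false("g01" %in% rownames(res$expr$values))
  expect_equal(res$report$genes_removed + res$report$genes_kept, 20L)
})

test_that("replicate ratio filter checks every replicate group", {
  vals <- rbind(ok = c(10, 5, 8, 9), bad2 = c(2, 3, 900, 4))
  colnames(vals) <- paste0("s", 1:4)
  expr <- expression_matrix(vals)
  groups <- list(r1 = c("s1", "s2"), r2 = c("s3", "s4"))
  res <- replicate_ratio_filter(expr, groups, max_ratio = 100)
  expect_equal(rownames(res$expr$values), "ok")  # bad2 fails only in group r2
  expect_equal(res$report$parameters$max_ratio, 100)
})

test_that("replicate ratio boundary: 101 > 100 removes, 2 keeps, 0/0 guarded", {
  vals <- rbind(ok = c(10, 5), bad = c(505, 5), zeros = c(0, 0))
  colnames(vals) <- c("s1", "s2")
  expr <- expression_matrix(vals)
  g <- list(r = c("s1", "s2"))
  res0 <- replicate_ratio_filter(expr, g, max_ratio = 100, pseudocount = 0)
  expect_false("bad" %in% rownames(res0$expr$values))    # ratio 101 > 100
  expect_true("ok" %in% rownames(res0$expr$values))      # ratio 2
  expect_true("zeros" %in% rownames(res0$expr$values))   # 0/0 -> NaN not > 100
  res1 <- replicate_ratio_filter(expr, g, pseudocount = 1)
  expect_true("zeros" %in% rownames(res1$expr$values))   # ratio 1
  expect_error(replicate_ratio_filter(expr, list(r = c("s1", "nope"))),
               class = "ppiacoexp_validation_error")
  expect_error(replicate_ratio_filter(expr, list(r = "s1")),
               class = "ppiacoexp_validation_error")
})

test_that("filters are idempotent and commute when rules do not interact", {
  expr <- toy_expression(n_genes = 12, seed = 3)
  expr$values[4, 2] <- NA
  expr$values[7, ] <- 1                        # constant: entropy 0

  m1 <- filter_missing(expr)$expr
  e1 <- entropy_filter(m1, min_entropy = 0.5)$expr
  e2 <- entropy_filter(expr, min_entropy = 0.5)$expr
  m2 <- filter_missing(e2)$expr
  expect_equal(rownames(e1$values), rownames(m2$values))
  expect_equal(e1$values, m2$values)

  twice <- entropy_filter(e1, min_entropy = 0.5)$expr
  expect_equal(twice$values, e1$values)
  expect_equal(filter_missing(m1)$expr$values, m1$values)
})

test_that("filter reports serialize as JSON lines", {
  expr <- toy_expression(n_genes = 5)
  expr$values[1, 1] <- NA
  res <- filter_missing(expr)
  p <- tempfile(fileext = ".jsonl")
  write_filter_reports(list(res$report), p)
  rec <- jsonlite::fromJSON(readLines(p)[1])
  expect_equal(rec$rule, "missing")
  expect_equal(rec$genes_removed, 1L)
})
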