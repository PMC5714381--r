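# Probe collapse, scaling, correlation, clustering, DE, set tests.

test_that("probe collapse keeps the largest-IQR probe with documented ties", {
  m <- rbind(p1 = c(0, 1, 2, 10), # IQR larger
             p2 = c(5, 5.2, 5.4, 5.6),
             p3 = c(1, 1, 1, 1),
             p4 = c(2, 2, 2, 2),
             px = c(9, 9, 9, 9))
  colnames(m) <- paste0("s", 1:4)
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("gA", "gA", "gB", "gB"))
  expect_message(out <- collapse_probes(m, map), "unmapped")
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(unname(out["gA", ]), unname(m["p1", ]))
  # equal IQRs: lexicographically smaller probe wins
  expect_equal(unname(attr(out, "probe_ids")["gB"]), "p3")

  single <- collapse_probes(m[1:2, ], data.frame(probe_id = c("p1", "p2"),
                                                 gene_id = c("gA", "gC")))
  expect_equal(nrow(single), 2)
  expect_error(collapse_probes(m, map[0, ]), "empty")
  bad <- rbind(map, data.frame(probe_id = "p1", gene_id = "gZ"))
  expect_error(collapse_probes(m, bad), "more than one gene")
})

test_that("gene-wise scaling centers, scales and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- zscale_genes(m), "zero-variance")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  set.seed(1)
  m2 <- matrix(stats::rnorm(200), 20)
  z1 <- zscale_genes(m2)
  expect_lt(max(abs(rowMeans(z1))), 1e-12)
  expect_lt(max(abs(apply(z1, 1, stats::sd) - 1)), 1e-12)
  expect_equal(zscale_genes(z1), z1, tolerance = 1e-12)
})

test_that("pairwise correlations behave on duplicates, negations and noise", {
  set.seed(2)
  base <- stats::rnorm(1000)
  m <- rbind(g1 = base, g2 = base, g3 = -base, g4 = stats::rnorm(1000))
  r <- pairwise_correlation(m)
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  expect_lt(abs(r["g1", "g4"]), 0.1)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r, t(r))
  expect_error(pairwise_correlation(m, c("g1", "gX")), "gX")
})

test_that("complete-linkage clustering separates known structure", {
  m <- rbind(a = c(0, 0, 0, 1), b = c(0, 0, 0, 1.01), c = c(9, 9, 9, 2))
  cl <- hier_cluster(m, k = 2)
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_false(cl$clusters[["a"]] == cl$clusters[["c"]])

  # 1-D points 0, 1, 10, 11: complete linkage joins {0,1} and {10,11}
  d <- stats::dist(c(0, 1, 10, 11))
  hc <- stats::hclust(d, method = "complete")
  expect_equal(sort(unname(stats::cutree(hc, 2))), c(1, 1, 2, 2))
  corr <- 1 - as.matrix(d) / max(d) # monotone transform as similarity
  cl2 <- hier_cluster(corr, input = "correlation", k = 2)
  expect_equal(unname(cl2$clusters), c(1, 1, 2, 2))
})

test_that("cluster partitions are invariant under row permutation", {
  e <- generate_expression(n_samples = 50, seed = 61)
  m <- e$matrix
  cl <- hier_cluster(m, k = 2)
  set.seed(62)
  perm <- sample.int(nrow(m))
  cl_p <- hier_cluster(m[perm, ], k = 2)
  expect_equal(ari(cl$clusters[rownames(m)], cl_p$clusters[rownames(m)]), 1)
})

test_that("two-block anticorrelated design is recovered exactly at k = 2", {
  e <- generate_expression(n_samples = 60, within_cor = 0.8,
                           between_cor = -0.8, seed = 63)
  cl <- hier_cluster(e$matrix, k = 2)
  expect_equal(ari(cl$clusters[names(e$truth$blocks)], e$truth$blocks), 1)
})

test_that("differential expression computes fold changes and flags", {
  m <- rbind(gene1 = c(1.0, 1.2, 0.8, 4.0, 4.2, 3.8),
             gene2 = c(2, 2.1, 1.9, 2.05, 1.95, 2.0))
  labels <- rep(c("g1", "g2"), each = 3)
  for (method in c("moderated", "welch")) {
    de <- differential_expression(m, labels, method = method)
    expect_equal(de$log2fc[de$gene_id == "gene1"], 3.0, tolerance = 1e-12)
    expect_equal(de$log2fc[de$gene_id == "gene2"], 0, tolerance = 0.1)
    expect_false(de$significant[de$gene_id == "gene2"])
    expect_true(all(de$p_adjusted >= de$p_value - 1e-15))
  }
  expect_error(differential_expression(m, c("a", "a", "a", "a", "a", "b")),
               "at least 2")
})

test_that("BH adjustment preserves the p-value ordering", {
  e <- generate_expression(n_samples = 6, block_sizes = c(0, 0),
                           n_de_genes = 10, n_null_genes = 200,
                           groups = c(3, 3), seed = 64)
  de <- differential_expression(e$matrix, e$truth$group_labels)
  o <- order(de$p_value)
  expect_true(all(diff(de$p_adjusted[o]) >= -1e-15))
})

test_that("planted DE genes are recovered under the standard thresholds", {
  e <- generate_expression(n_samples = 6, block_sizes = c(0, 0),
                           n_de_genes = 20, n_null_genes = 500,
                           de_effect = 2, de_sigma = 0.25, groups = c(3, 3),
                           seed = 65)
  de <- differential_expression(e$matrix, e$truth$group_labels)
  planted <- de$gene_id %in% e$truth$de_genes
  expect_gte(sum(de$significant & planted), 18)
  expect_lte(sum(de$significant & !planted), 1)
})

mk_de <- function(lfc, ids = sprintf("g%04d", seq_along(lfc))) {
  df <- data.frame(gene_id = ids, log2fc = lfc, t = 0, df = 4,
                   p_value = 0.5, p_adjusted = 0.5, significant = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("de_table", "data.frame")
  df
}

test_that("gene-set perturbation test enforces bounds and detects shifts", {
  set.seed(66)
  de <- mk_de(stats::rnorm(2000, 0, 0.5))
  small <- gene_set("small", de$gene_id[1:5])
  expect_error(geneset_perturbation_test(de, small), "size bounds")

  null_set <- gene_set("null", de$gene_id[1:40])
  r <- geneset_perturbation_test(de, null_set, mode = "directed")
  expect_gt(r$p_value, 0.01)

  shifted <- mk_de(c(stats::rnorm(1960, 0, 0.5), stats::rnorm(40, 1, 0.5)))
  up <- gene_set("up", shifted$gene_id[1961:2000])
  r2 <- geneset_perturbation_test(shifted, up, mode = "directed")
  expect_lt(r2$p_value, 0.01)
  r3 <- geneset_perturbation_test(shifted, up, mode = "undirected")
  expect_lt(r3$p_value, 0.01)
})

test_that("directed test is antisymmetric under sign flip", {
  set.seed(67)
  lfc <- stats::rnorm(1000, 0, 1)
  de_pos <- mk_de(lfc)
  de_neg <- mk_de(-lfc)
  s <- gene_set("s", de_pos$gene_id[1:50])
  p1 <- geneset_perturbation_test(de_pos, s, mode = "directed")$p_value
  p2 <- geneset_perturbation_test(de_neg, s, mode = "directed")$p_value
  expect_equal(p1 + p2, 1, tolerance = 1e-9)
})

test_that("expression TSV round-trips and drops incomplete rows", {
  e <- generate_expression(n_samples = 8, block_sizes = c(5, 5), seed = 68)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(e$matrix, f)
  back <- read_expression(f)
  expect_equal(back, e$matrix, tolerance = 1e-12)
  m <- e$matrix
  m[2, 3] <- NA
  write_expression(m, f)
  expect_message(back2 <- read_expression(f), "1 row")
  expect_equal(nrow(back2), nrow(m) - 1)
})
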