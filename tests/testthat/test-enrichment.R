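# Peak-gene association, hypergeometric feature tests, bootstrap
# enrichment with skew-normal tails.

test_that("gene sets deduplicate, read and write", {
  expect_message(gs <- gene_set("s", c("a", "b", "a")), "duplicate")
  expect_equal(length(gs), 2)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header comment", "geneA", "geneB # trailing note", "",
               "geneC"), f)
  gs2 <- read_gene_set(f, "x")
  expect_equal(gs2$gene_ids, c("geneA", "geneB", "geneC"))
  write_gene_set(gs2, f)
  expect_equal(read_gene_set(f)$gene_ids, gs2$gene_ids)
})

test_that("peak-gene association counts cover the whole universe", {
  ann <- toy_annotation()
  df <- data.frame(chrom = "chr1", start = 0, end = 1, summit = 0,
                   feature = "Promoter",
                   gene_id = c("geneA", "geneB", "geneB"),
                   dist_to_tss = 0, stringsAsFactors = FALSE)
  class(df) <- c("annotated_peaks", "data.frame")
  assoc <- associate_peaks(df, ann)
  expect_equal(unname(assoc$counts), c(1L, 2L))
  expect_equal(assoc$n_genes, 2)
  expect_equal(assoc$n_peaks, 3)
  df_bad <- df
  df_bad$gene_id <- NULL
  expect_error(associate_peaks(df_bad, ann), "classify_peaks")
})

test_that("per-gene peak counts follow the generator's Poisson-like law", {
  g <- generate_genome(n_genes = 500, seed = 31)
  p <- generate_peaks(g$annotation, n_peaks = 1000, seed = 32)
  assoc <- associate_peaks(classify_peaks(p$peaks, g$annotation),
                           g$annotation)
  expect_equal(sum(assoc$counts), 1000)
  expect_equal(assoc$n_genes, 500)
})

test_that("hypergeometric tests match exhaustive enumeration", {
  # spec-scale examples first
  mk_dist <- function(counts, total) {
    cn <- stats::setNames(integer(7), feature_classes())
    cn["Intron"] <- counts
    cn["DistalIntergenic"] <- total - counts
    structure(list(counts = cn, fractions = cn / total, total = total),
              class = "feature_distribution")
  }
  h <- hypergeom_feature_test(mk_dist(4, 5), mk_dist(4, 10), "Intron")
  expect_equal(h$p_enrich, 6 / 252, tolerance = 1e-12)
  h2 <- hypergeom_feature_test(mk_dist(2, 5), mk_dist(4, 10), "Intron")
  expect_equal(h2$p_enrich, 186 / 252, tolerance = 1e-12)
  # K = N_pop forces k = n and certainty
  h3 <- hypergeom_feature_test(mk_dist(5, 5), mk_dist(10, 10), "Intron")
  expect_equal(h3$p_enrich, 1)

  # random instances against the enumeration oracle
  set.seed(5)
  for (i in 1:40) {
    N_pop <- sample(2:12, 1)
    K <- sample.int(N_pop, 1)
    n <- sample.int(N_pop, 1)
    k_range <- max(0, n + K - N_pop):min(n, K)
    k <- k_range[sample.int(length(k_range), 1)]
    want <- oracle_hypergeom(N_pop, K, n, k)
    got_e <- stats::phyper(k - 1, K, N_pop - K, n, lower.tail = FALSE)
    got_d <- stats::phyper(k, K, N_pop - K, n)
    # package path via feature distributions
    cn_s <- stats::setNames(integer(7), feature_classes())
    cn_b <- cn_s
    cn_s["Exon"] <- k
    cn_s["DistalIntergenic"] <- n - k
    cn_b["Exon"] <- K
    cn_b["DistalIntergenic"] <- N_pop - K
    sd <- structure(list(counts = cn_s, fractions = cn_s / n, total = n),
                    class = "feature_distribution")
    bd <- structure(list(counts = cn_b, fractions = cn_b / N_pop,
                         total = N_pop), class = "feature_distribution")
    h <- hypergeom_feature_test(sd, bd, "Exon")
    expect_equal(h$p_enrich, want$p_enrich, tolerance = 1e-12)
    expect_equal(h$p_deplete, want$p_deplete, tolerance = 1e-12)
    expect_gte(h$p_enrich + h$p_deplete, 1)
    expect_equal(got_e, want$p_enrich, tolerance = 1e-12)
    expect_equal(got_d, want$p_deplete, tolerance = 1e-12)
  }
})

test_that("inconsistent set/background pairs are rejected", {
  cn_s <- stats::setNames(c(5L, rep(0L, 6)), feature_classes())
  cn_b <- stats::setNames(c(3L, rep(0L, 6)), feature_classes())
  sd <- structure(list(counts = cn_s, fractions = cn_s / 5, total = 5L),
                  class = "feature_distribution")
  bd <- structure(list(counts = cn_b, fractions = cn_b / 3, total = 3L),
                  class = "feature_distribution")
  expect_error(hypergeom_feature_test(sd, bd, "Promoter"), "subset")
})

mk_assoc <- function(counts) {
  structure(list(counts = stats::setNames(as.integer(counts),
                                          sprintf("g%03d", seq_along(counts))),
                 n_genes = length(counts), n_peaks = sum(counts)),
            class = "peak_gene_association")
}

test_that("bootstrap null sampling honours degenerate and exhaustive cases", {
  nc <- bootstrap_null(mk_assoc(rep(2, 20)), set_size = 5, B = 50, seed = 1)
  expect_true(all(nc == 10))
  nc2 <- bootstrap_null(mk_assoc(c(3, 1, 4)), set_size = 3, B = 20, seed = 2)
  expect_true(all(nc2 == 8))
  expect_error(bootstrap_null(mk_assoc(c(1, 2)), set_size = 3, B = 10),
               "exceeds")
  # {0,1,2}, N = 2: sums 1, 2, 3 equally likely -> mean 2
  nc3 <- bootstrap_null(mk_assoc(c(0, 1, 2)), set_size = 2, B = 20000,
                        seed = 3)
  se <- stats::sd(nc3) / sqrt(length(nc3))
  expect_lt(abs(mean(nc3) - 2), 3 * se)
  expect_setequal(unique(nc3), c(1, 2, 3))
  # identical seed -> identical null
  expect_identical(nc3, bootstrap_null(mk_assoc(c(0, 1, 2)), 2, 20000, seed = 3))
})

test_that("tail probabilities combine fitted and empirical views", {
  set.seed(9)
  null <- stats::rnorm(10000, 100, 10)
  res <- bootstrap_p(stats::qnorm(0.95, 100, 10), fit = NULL,
                     null_counts = null)
  expect_lt(abs(res$p_high - 0.05), 0.01)
  expect_lt(abs(res$p_high - res$p_high_emp), 0.02)

  res2 <- bootstrap_p(max(null) + 1, fit = res$fit, null_counts = null)
  expect_equal(res2$p_high_emp, 1 / 10001)

  res3 <- bootstrap_p(stats::median(null), fit = res$fit, null_counts = null)
  expect_lt(abs(res3$p_high - 0.5), 0.02)
  expect_lt(abs(res3$p_low - 0.5), 0.02)
})

test_that("degenerate nulls fall back to empirical tails", {
  assoc <- mk_assoc(rep(1, 30))
  res <- bootstrap_enrichment(assoc, gene_set("q", sprintf("g%03d", 1:5)),
                              B = 200, seed = 4)
  expect_true(res$fit$degenerate)
  expect_true(is.na(res$p_high))
  expect_equal(res$observed, 5)
  expect_equal(res$p_high_emp, 1, tolerance = 1e-12) # all ties
})

test_that("bootstrap enrichment is reproducible end to end", {
  g <- generate_genome(n_genes = 200, seed = 41)
  p <- generate_peaks(g$annotation, n_peaks = 800, seed = 42)
  assoc <- associate_peaks(classify_peaks(p$peaks, g$annotation),
                           g$annotation)
  qs <- gene_set("q", g$annotation$genes$gene_id[11:40])
  r1 <- bootstrap_enrichment(assoc, qs, B = 500, seed = 7)
  r2 <- bootstrap_enrichment(assoc, qs, B = 500, seed = 7)
  expect_identical(r1[c("null_counts", "p_high", "p_low", "p_high_emp",
                        "p_low_emp", "observed")],
                   r2[c("null_counts", "p_high", "p_low", "p_high_emp",
                        "p_low_emp", "observed")])
  expect_warning(
    bootstrap_enrichment(assoc, gene_set("x", c(qs$gene_ids, "missing")),
                         B = 200, seed = 1),
    "not in the annotation universe")
})

test_that("planted density enrichment is detected", {
  g <- generate_genome(n_genes = 400, seed = 51)
  qs <- gene_set("planted", g$annotation$genes$gene_id[1:40])
  p <- generate_peaks(g$annotation, n_peaks = 2000, rho = 3, gene_set = qs,
                      seed = 52)
  assoc <- associate_peaks(classify_peaks(p$peaks, g$annotation),
                           g$annotation)
  res <- bootstrap_enrichment(assoc, qs, B = 2000, seed = 53)
  expect_lt(res$p_high, 0.01)
  expect_gt(res$p_low, 0.9)
})
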