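# Gene model parsing and seven-feature summit classification.

test_that("BED12 gene models parse with TSS, exons and CDS", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t1000\t5000\tgeneA\t0\t+\t1200\t4800\t0\t2\t500,1000\t0,3000",
    "chr1\t9000\t12000\tgeneB\t0\t-\t9500\t11500\t0\t1\t3000\t0",
    "chr2\t100\t900\tgeneC\t0\t+\t100\t100\t0\t1\t800\t0"), f)
  ann <- read_gene_models(f)
  g <- ann$genes
  expect_equal(g$tss[g$gene_id == "geneA"], 1000)
  expect_equal(g$tss[g$gene_id == "geneB"], 11999) # minus strand: end - 1
  exA <- ann$exons[ann$exons$gene_id == "geneA", ]
  expect_equal(exA$start, c(1000, 4000))
  expect_equal(exA$end, c(1500, 5000))
  expect_equal(g$cds_start[g$gene_id == "geneA"], 1200)
  # thickStart == thickEnd -> non-coding
  expect_true(is.na(g$cds_start[g$gene_id == "geneC"]))
})

test_that("malformed BED12 lines raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000\tgeneA\t0\t+\t1200\t4800\t0\t2\t500,1000\t0,3000",
               "chr1\t1\t2\tshort"), f)
  expect_error(read_gene_models(f), "line 2")

  writeLines("chr1\t5000\t1000\tgeneA\t0\t+\t1200\t4800\t0\t1\t100\t0", f)
  expect_error(read_gene_models(f), "start >= end")

  writeLines(c("chr1\t1000\t5000\tgeneA\t0\t+\t1200\t4800\t0\t1\t4000\t0",
               "chr2\t1000\t5000\tgeneA\t0\t+\t1200\t4800\t0\t1\t4000\t0"), f)
  expect_error(read_gene_models(f), "duplicate")

  writeLines("chr1\t1000\t5000\tgeneA\t0\t+\t1200\t4800\t0\t2\t500\t0,3000", f)
  expect_error(read_gene_models(f), "blockCount|blocks")
})

test_that("BED12 writer round-trips generated genomes", {
  g <- generate_genome(n_genes = 30, seed = 5)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(g$annotation, f)
  back <- read_gene_models(f)
  expect_equal(back$genes[, c("gene_id", "chrom", "start", "end", "strand",
                              "tss")],
               g$annotation$genes[, c("gene_id", "chrom", "start", "end",
                                      "strand", "tss")])
  expect_equal(back$exons, g$annotation$exons)
  cds_cols <- c("cds_start", "cds_end")
  expect_equal(back$genes[, cds_cols], g$annotation$genes[, cds_cols])
})

test_that("summit classification follows the documented feature rules", {
  ann <- toy_annotation() # geneA: + strand [10000,20000) tss 10000
  cls <- function(pos) classify_peak(
    make_peak_df("chr1", pos - 50, pos + 50, pos), ann)

  r <- cls(9500) # within 3 kb upstream of TSS
  expect_equal(r$feature, "Promoter")
  expect_equal(r$dist_to_tss, -500)

  r <- cls(14000) # inside span, outside exons, beyond promoter window
  expect_equal(r$feature, "Intron")
  expect_equal(r$gene_id, "geneA")

  r <- cls(21500) # past gene end, next TSS far away
  expect_equal(r$feature, "Downstream")
  expect_equal(r$gene_id, "geneA")

  r <- cls(30000) # between the genes, outside all windows
  expect_equal(r$feature, "DistalIntergenic")

  r <- cls(10200) # exonic, before cds_start on + strand
  expect_equal(r$feature, "Promoter") # promoter wins by precedence
  r <- cls(19000) # exonic past cds_end = 3' UTR territory, > 3 kb from TSS
  expect_equal(r$feature, "ThreePrimeUTR")
})

test_that("promoter classification is symmetric around the TSS on both strands", {
  ann <- toy_annotation()
  w <- 2999
  for (gene in c("geneA", "geneB")) {
    tss <- ann$genes$tss[ann$genes$gene_id == gene]
    for (pos in c(tss - w, tss + w)) {
      r <- classify_peak(make_peak_df("chr1", pos - 10, pos + 10, pos), ann)
      expect_equal(r$feature, "Promoter")
    }
  }
})

test_that("classification matches the per-position brute-force oracle", {
  for (seed in 1:5) {
    ann <- random_toy_annotation(seed)
    set.seed(seed + 1000)
    pos <- sample.int(99000, 400)
    got <- classify_peaks(make_peak_df("chr1", pos, pos + 1, pos), ann)
    for (i in seq_along(pos)) {
      want <- oracle_classify_pos("chr1", pos[i], ann)
      expect_equal(got$feature[i], want$feature,
                   info = sprintf("seed %d pos %d", seed, pos[i]))
      expect_equal(got$gene_id[i], want$gene_id,
                   info = sprintf("seed %d pos %d", seed, pos[i]))
      expect_equal(got$dist_to_tss[i], want$dist,
                   info = sprintf("seed %d pos %d", seed, pos[i]))
    }
  }
})

test_that("classification partitions peaks and is reproducible", {
  g <- generate_genome(n_genes = 60, seed = 3)
  p <- generate_peaks(g$annotation, n_peaks = 500, seed = 4)
  a1 <- classify_peaks(p$peaks, g$annotation)
  a2 <- classify_peaks(p$peaks, g$annotation)
  expect_identical(a1, a2)
  expect_false(anyNA(a1$feature))
  expect_equal(sum(table(a1$feature)), nrow(a1))
  expect_true(all(a1$feature %in% feature_classes()))
  # promoter peaks lie within the promoter window
  prom <- a1[a1$feature == "Promoter", ]
  expect_true(all(abs(prom$dist_to_tss) <= 3000))
})

test_that("chromosomes without genes are rejected", {
  ann <- toy_annotation()
  expect_error(classify_peak(make_peak_df("chrX", 100, 200), ann),
               "unassignable chromosome.*chrX")
})

test_that("feature distributions count, normalize and restrict correctly", {
  ann_df <- data.frame(chrom = "chr1", start = 0, end = 1, summit = 0,
                       feature = c(rep("Promoter", 4), rep("Intron", 6)),
                       gene_id = c(rep("geneA", 4), rep("geneB", 6)),
                       dist_to_tss = 0)
  class(ann_df) <- c("annotated_peaks", "data.frame")
  fd <- feature_distribution(ann_df)
  expect_equal(fd$total, 10)
  expect_equal(unname(fd$fractions["Promoter"]), 0.4)
  expect_equal(unname(fd$fractions["Intron"]), 0.6)
  expect_equal(sum(fd$fractions), 1, tolerance = 1e-12)

  only_a <- feature_distribution(ann_df, gene_set("a", "geneA"))
  expect_equal(only_a$total, 4)
  expect_equal(unname(only_a$fractions["Promoter"]), 1)
  expect_error(feature_distribution(ann_df, gene_set("x", "nope")),
               "no peaks associated")
})

test_that("generator feature weights are recovered in the distribution", {
  g <- generate_genome(n_genes = 150, seed = 11)
  p <- generate_peaks(g$annotation, n_peaks = 2000,
                      feature_weights = c(Promoter = 0.5,
                                          DistalIntergenic = 0.5),
                      seed = 12)
  fd <- feature_distribution(classify_peaks(p$peaks, g$annotation))
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(fd$fractions[["Promoter"]] - 0.5), 3 * se)
  expect_lt(abs(fd$fractions[["DistalIntergenic"]] - 0.5), 3 * se)
})

test_that("annotated peaks write the documented TSV columns", {
  g <- generate_genome(n_genes = 20, seed = 2)
  p <- generate_peaks(g$annotation, n_peaks = 50, seed = 3)
  ann <- classify_peaks(p$peaks, g$annotation)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_peaks(ann, f)
  back <- utils::read.delim(f)
  expect_equal(names(back), c("chrom", "start", "end", "summit", "feature",
                              "gene_id", "dist_to_tss"))
  expect_equal(nrow(back), 50)
})
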