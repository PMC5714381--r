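# Segmentation IO, summit-bin state assignment, abundance profiles.

test_that("segmentation BED parses onto the bin grid", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t600\tQuies", "chr1\t600\t800\tEnh"), f)
  seg <- read_segmentation(f)
  expect_equal(seg$bins$chr1, c(15L, 15L, 15L, 7L)) # Quies = 15, Enh = 7
  expect_equal(seg$states[seg$bins$chr1], c("Quies", "Quies", "Quies", "Enh"))

  writeLines("chr1\t100\t300\tEnh", f)
  expect_error(read_segmentation(f), "off the 200 bp grid")
  writeLines(c("chr1\t0\t400\tEnh", "chr1\t200\t600\tQuies"), f)
  expect_error(read_segmentation(f), "overlapping")
  writeLines("chr1\t0\t200\tNotAState", f)
  expect_error(read_segmentation(f), "outside the vocabulary")
})

test_that("segmentations from several files merge over disjoint chromosomes", {
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t400\tTssA", f1)
  writeLines("chr2\t0\t200\tQuies", f2)
  seg <- read_segmentation(c(f1, f2))
  expect_setequal(names(seg$bins), c("chr1", "chr2"))
  expect_equal(assign_state(list(chrom = "chr2", summit = 100), seg), "Quies")
})

test_that("summits map to bins by integer division with half-open bins", {
  seg <- chromatin_segmentation(list(chr1 = c(1L, 15L)), bin_size = 200)
  expect_equal(assign_state(list(chrom = "chr1", summit = 0), seg), "TssA")
  expect_equal(assign_state(list(chrom = "chr1", summit = 199), seg), "TssA")
  expect_equal(assign_state(list(chrom = "chr1", summit = 200), seg), "Quies")
  # past the annotated extent and uncovered bins -> unannotated
  expect_equal(assign_state(list(chrom = "chr1", summit = 4000), seg),
               "unannotated")
  seg0 <- chromatin_segmentation(list(chr1 = c(0L, 7L)), bin_size = 200)
  expect_equal(assign_state(list(chrom = "chr1", summit = 10), seg0),
               "unannotated")
  expect_error(assign_state(list(chrom = "chr9", summit = 10), seg),
               "absent")
  # summit 1234 with 200 bp bins sits in bin 6 (0-based)
  seg2 <- chromatin_segmentation(list(chr1 = as.integer(c(rep(15, 6), 7))),
                                 bin_size = 200)
  expect_equal(assign_state(list(chrom = "chr1", summit = 1234), seg2), "Enh")
})

test_that("state assignment agrees with a record-scan oracle", {
  set.seed(42)
  records <- data.frame(chrom = "chr1",
                        start = seq(0, 9800, by = 200))
  records$end <- records$start + 200
  records$state <- sample(roadmap_states(), nrow(records), replace = TRUE)
  # drop some records to create unannotated holes
  records <- records[-sample.int(nrow(records), 10), ]
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", records$chrom, records$start,
                     records$end, records$state), f)
  seg <- read_segmentation(f)
  for (s in sample.int(9999, 200)) {
    expect_equal(assign_state(list(chrom = "chr1", summit = s), seg),
                 oracle_state_scan("chr1", s, records),
                 info = paste("summit", s))
  }
})

test_that("segmentation write/read round-trips including holes", {
  g <- generate_genome(n_genes = 30, seed = 8)
  seg <- generate_segmentation(g$annotation, seed = 9)$segmentation
  seg$bins$chr1[5:10] <- 0L # punch an unannotated hole
  f <- withr::local_tempfile(fileext = ".bed")
  write_segmentation(seg, f)
  back <- read_segmentation(f)
  expect_equal(back$bins, seg$bins)
  expect_equal(back$states, seg$states)
})

mk_annotated <- function(feature, gene_id, summit) {
  df <- data.frame(chrom = "chr1", start = pmax(summit - 50, 0),
                   end = summit + 50, summit = summit, feature = feature,
                   gene_id = gene_id, dist_to_tss = 0,
                   stringsAsFactors = FALSE)
  class(df) <- c("annotated_peaks", "data.frame")
  df
}

test_that("state abundance sums to 100% and respects filters", {
  # bins: 0-4 Enh, 5-9 Quies
  seg <- chromatin_segmentation(list(chr1 = as.integer(c(rep(7, 5), rep(15, 5)))),
                                bin_size = 200)
  ann <- mk_annotated(rep(c("Intron", "DistalIntergenic"), each = 5),
                      rep(c("geneA", "geneB"), each = 5),
                      c(seq(0, 800, 200), seq(1000, 1800, 200)))
  prof <- state_abundance(ann, seg)
  expect_equal(sum(prof$profile$percent), 100, tolerance = 1e-9)
  expect_equal(prof$n_peaks, 10)
  expect_equal(prof$states_represented, 2)
  expect_equal(prof$profile$percent[prof$profile$state == "Enh"], 50)

  only_intron <- state_abundance(ann, seg, feature_filter = "Intron")
  expect_equal(only_intron$profile$percent[only_intron$profile$state == "Enh"],
               100)
  # filter order commutes
  a <- state_abundance(ann, seg, feature_filter = "DistalIntergenic",
                       gene_set = gene_set("b", "geneB"))
  b <- state_abundance(ann[ann$gene_id == "geneB", ], seg,
                       feature_filter = "DistalIntergenic")
  expect_equal(a$profile, b$profile)

  expect_error(state_abundance(ann, seg, feature_filter = "Promoter"),
               "feature filter")
  expect_error(state_abundance(ann, seg, gene_set = gene_set("x", "nope")),
               "gene-set filter")
})

test_that("unannotated summits are excluded unless requested", {
  seg <- chromatin_segmentation(list(chr1 = c(7L, 0L)), bin_size = 200)
  ann <- mk_annotated(rep("Intron", 4), "geneA", c(10, 100, 250, 350))
  prof <- state_abundance(ann, seg)
  expect_equal(prof$n_peaks, 2)
  expect_equal(prof$profile$percent[prof$profile$state == "Enh"], 100)
  prof2 <- state_abundance(ann, seg, include_unannotated = TRUE)
  expect_equal(prof2$n_peaks, 4)
  expect_equal(prof2$profile$percent[prof2$profile$state == "unannotated"], 50)
})

test_that("planted emission distributions are recovered from profiles", {
  g <- generate_genome(n_genes = 120, seed = 21)
  em <- list(
    Promoter = c(TssA = 0.9, Quies = 0.1),
    FivePrimeUTR = c(Tx = 1), ThreePrimeUTR = c(Tx = 1), Exon = c(Tx = 1),
    Intron = c(TxWk = 1), Downstream = c(Enh = 1),
    DistalIntergenic = c(Quies = 1))
  seg <- generate_segmentation(g$annotation, emissions = em, seed = 22)
  prom_bins <- seg$truth$bins[seg$truth$bins$feature == "Promoter", ]
  n <- nrow(prom_bins)
  expect_gt(n, 2000)
  frac <- mean(prom_bins$state == "TssA")
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / n))
  # peaks placed in promoters see the same emission fractions
  p <- generate_peaks(g$annotation, n_peaks = 1000,
                      feature_weights = c(Promoter = 1), seed = 23)
  ann <- classify_peaks(p$peaks, g$annotation)
  prof <- state_abundance(ann, seg$segmentation)
  tssa <- prof$profile$percent[prof$profile$state == "TssA"]
  expect_lt(abs(tssa - 90), 3 * 100 * sqrt(0.9 * 0.1 / 1000))
})
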