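# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive (per-position scans, exhaustive enumeration, pairwise
# closure loops) and share no code with the package internals they check.

# position-by-position feature classification over a toy annotation;
# mirrors the documented rules directly, without interval machinery
oracle_classify_pos <- function(chrom, pos, annotation,
                                promoter_window = 3000,
                                downstream_window = 3000) {
  g <- annotation$genes
  ex <- annotation$exons
  ranks <- c(Promoter = 1, FivePrimeUTR = 2, ThreePrimeUTR = 3, Exon = 4,
             Intron = 5, Downstream = 6)
  best <- NULL # list(rank, absd, gene, feature, d)
  consider <- function(feature, gi) {
    d <- if (g$strand[gi] == "+") pos - g$tss[gi] else g$tss[gi] - pos
    cand <- list(rank = ranks[[feature]], absd = abs(d),
                 gene = g$gene_id[gi], feature = feature, d = d)
    if (is.null(best)) return(cand)
    if (cand$rank < best$rank ||
        (cand$rank == best$rank && cand$absd < best$absd) ||
        (cand$rank == best$rank && cand$absd == best$absd &&
           cand$gene < best$gene)) return(cand)
    best
  }
  for (gi in seq_len(nrow(g))) {
    if (g$chrom[gi] != chrom) next
    in_exon <- FALSE
    exg <- ex[ex$gene_id == g$gene_id[gi], , drop = FALSE]
    if (nrow(exg)) in_exon <- any(pos >= exg$start & pos < exg$end)
    coding <- !is.na(g$cds_start[gi])
    if (abs(pos - g$tss[gi]) <= promoter_window) {
      best <- consider("Promoter", gi)
    }
    if (in_exon && coding) {
      five <- if (g$strand[gi] == "+") pos < g$cds_start[gi] else pos >= g$cds_end[gi]
      three <- if (g$strand[gi] == "+") pos >= g$cds_end[gi] else pos < g$cds_start[gi]
      if (five) best <- consider("FivePrimeUTR", gi)
      if (three) best <- consider("ThreePrimeUTR", gi)
    }
    if (in_exon) best <- consider("Exon", gi)
    if (!in_exon && pos >= g$start[gi] && pos < g$end[gi]) {
      best <- consider("Intron", gi)
    }
    down <- if (g$strand[gi] == "+") {
      pos >= g$end[gi] && pos < g$end[gi] + downstream_window
    } else {
      pos >= g$start[gi] - downstream_window && pos < g$start[gi]
    }
    if (down) best <- consider("Downstream", gi)
  }
  if (!is.null(best)) {
    return(list(feature = best$feature, gene_id = best$gene, dist = best$d))
  }
  on_ch <- g[g$chrom == chrom, , drop = FALSE]
  if (nrow(on_ch) == 0) stop("oracle: no genes on ", chrom)
  absd <- abs(pos - on_ch$tss)
  cand <- on_ch[absd == min(absd), , drop = FALSE]
  cand <- cand[order(cand$gene_id), , drop = FALSE]
  d <- if (cand$strand[1] == "+") pos - cand$tss[1] else cand$tss[1] - pos
  list(feature = "DistalIntergenic", gene_id = cand$gene_id[1], dist = d)
}

# exhaustive hypergeometric tail probabilities by enumerating all C(N, n)
# draws from a population with K marked items
oracle_hypergeom <- function(N_pop, K, n, k) {
  draws <- utils::combn(N_pop, n)
  marked <- colSums(draws <= K) # items 1..K are "in the feature"
  list(p_enrich = mean(marked >= k), p_deplete = mean(marked <= k))
}

# single-linkage closure of peaks under the "< max_gap" rule, by iterating
# pairwise merges to a fixed point
oracle_linkage <- function(df, max_gap = 1000) {
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (df$chrom[i] != df$chrom[j]) next
        gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
        linked <- gap < max_gap # negative gap = intersecting
        if (linked && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  memb <- vapply(split(df$sample, comp),
                 function(s) paste(sort(unique(s)), collapse = "&"),
                 character(1))
  sort(table(memb))
}

# record-by-record scan assigning a summit the state of the covering record
oracle_state_scan <- function(chrom, summit, records, bin_size = 200) {
  hit <- records$chrom == chrom & records$start <= summit & summit < records$end
  if (!any(hit)) return("unannotated")
  records$state[which(hit)[1]]
}

# small deterministic two-gene annotation used across tests
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"),
    chrom = "chr1",
    start = c(10000, 40000), end = c(20000, 48000),
    strand = c("+", "-"),
    cds_start = c(10800, 41000), cds_end = c(18000, 47000),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneB"),
    chrom = "chr1",
    start = c(10000, 15000, 40000, 46000),
    end = c(10500, 20000, 42000, 48000),
    stringsAsFactors = FALSE)
  genome_annotation(genes, exons)
}

# random toy annotations (<= 5 genes, <= 100 kb) for oracle comparisons
random_toy_annotation <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  starts <- sort(sample(seq(2000, 80000, by = 500), n))
  lens <- sample(seq(1500, 12000, by = 100), n, replace = TRUE)
  ends <- pmin(starts + lens, 99000)
  # enforce 0 <= start < end but allow gene overlap on purpose
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
                      start = starts, end = ends,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      cds_start = NA_real_, cds_end = NA_real_,
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    len <- ends[i] - starts[i]
    k <- sample(1:3, 1)
    if (k == 1 || len < 900) {
      return(data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
                        start = starts[i], end = ends[i]))
    }
    cuts <- sort(sample(seq(starts[i] + 100, ends[i] - 100, by = 50),
                        2 * (k - 1)))
    bounds <- c(starts[i], cuts, ends[i])
    odd <- seq(1, length(bounds) - 1, by = 2)
    data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
               start = bounds[odd], end = bounds[odd + 1])
  }))
  coding <- runif(n) < 0.8
  cs <- starts + pmax(200, round((ends - starts) * 0.1))
  ce <- ends - pmax(200, round((ends - starts) * 0.1))
  ok <- coding & cs < ce
  genes$cds_start[ok] <- cs[ok]
  genes$cds_end[ok] <- ce[ok]
  genome_annotation(genes, exons, chrom_lengths = c(chr1 = 100000))
}

# adjusted Rand index between two labelings (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

make_peak_df <- function(chrom, start, end, summit = NULL) {
  if (is.null(summit)) summit <- floor((start + end) / 2)
  data.frame(chrom = chrom, start = start, end = end, summit = summit,
             stringsAsFactors = FALSE)
}
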