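# Synthetic data with planted, parameterized structure: annotated genomes,
# peak sets with per-feature placement bias and gene-set density
# enrichment, feature-dependent chromatin-state segmentations, and
# two-block expression matrices with planted differential expression.
#
# Every generator is a pure function of its parameters including the seed
# (the caller's RNG state is untouched), and returns the generated object
# together with a `truth` record sufficient to score recovery tests.

#' Generate a synthetic annotated genome
#'
#' Lays out non-overlapping, strand-mixed multi-exon genes along one or
#' more chromosomes.  Gene lengths and intergenic spacings are log-normal;
#' exon counts uniform on a range; a fraction of genes is non-coding (no
#' CDS, hence no UTR features).
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes (genes split contiguously).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (defaults log(20000), 0.8 — the scale of human gene models,
#'   so the 3 kb promoter/downstream windows do not swallow gene bodies).
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param spacing_meanlog,spacing_sdlog Log-normal intergenic spacing
#'   parameters (defaults log(30000), 0.9).
#' @param frac_noncoding Fraction of non-coding genes (default 0.1).
#' @param chrom_length Optional fixed chromosome extent; an error is raised
#'   if the layout does not fit.
#' @param seed Integer seed.
#' @return List with `annotation` (a [genome_annotation()]) and `truth`.
#' @export
generate_genome <- function(n_genes = 200, n_chromosomes = 1,
                            gene_length_meanlog = log(20000),
                            gene_length_sdlog = 0.8,
                            exons_per_gene = c(2, 8),
                            spacing_meanlog = log(30000),
                            spacing_sdlog = 0.9,
                            frac_noncoding = 0.1,
                            chrom_length = NULL,
                            seed = 1) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 1,
            exons_per_gene[2] >= exons_per_gene[1])
  with_seed(seed, {
    chrom <- paste0("chr", rep(seq_len(n_chromosomes),
                               each = ceiling(n_genes / n_chromosomes)))[seq_len(n_genes)]
    len <- pmax(round(stats::rlnorm(n_genes, gene_length_meanlog,
                                    gene_length_sdlog)), 400)
    spacing <- pmax(round(stats::rlnorm(n_genes, spacing_meanlog,
                                        spacing_sdlog)), 1000)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    ex_range <- seq.int(exons_per_gene[1], exons_per_gene[2])
    n_ex <- ex_range[sample.int(length(ex_range), n_genes, replace = TRUE)]
    coding <- stats::runif(n_genes) >= frac_noncoding

    start <- numeric(n_genes)
    offset <- 10000
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      pos <- offset
      for (i in sel) {
        start[i] <- pos
        pos <- pos + len[i] + spacing[i]
      }
    }
    end <- start + len
    if (!is.null(chrom_length)) {
      last_end <- tapply(end, chrom, max)
      if (any(last_end + 3000 > chrom_length)) {
        stop("infeasible packing: genes exceed chrom_length; increase the chromosome extents")
      }
    }

    exons_list <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      k <- n_ex[i]
      nseg <- 2 * k - 1
      if (len[i] < 2 * nseg) k <- 1
      if (k == 1) {
        exons_list[[i]] <- cbind(start[i], end[i])
        next
      }
      nseg <- 2 * k - 1
      shape <- ifelse(seq_len(nseg) %% 2 == 1, 2, 1.5) # exons a bit larger
      w <- stats::rgamma(nseg, shape = shape)
      lens <- 1 + floor(w / sum(w) * (len[i] - nseg))
      lens[which.max(lens)] <- lens[which.max(lens)] + (len[i] - sum(lens))
      bounds <- start[i] + cumsum(c(0, lens))
      odd <- seq(1, nseg, by = 2)
      exons_list[[i]] <- cbind(bounds[odd], bounds[odd + 1])
    }
    ex_counts <- vapply(exons_list, nrow, integer(1))
    exons <- data.frame(
      gene_id = rep(sprintf("G%05d", seq_len(n_genes)), ex_counts),
      chrom = rep(chrom, ex_counts),
      start = unlist(lapply(exons_list, function(x) x[, 1])),
      end = unlist(lapply(exons_list, function(x) x[, 2])),
      stringsAsFactors = FALSE)

    cds_start <- rep(NA_real_, n_genes)
    cds_end <- rep(NA_real_, n_genes)
    u1 <- pmax(1, round(len * stats::runif(n_genes, 0.03, 0.15)))
    u2 <- pmax(1, round(len * stats::runif(n_genes, 0.03, 0.15)))
    cs <- start + u1
    ce <- end - u2
    swap <- cs >= ce
    cs[swap] <- start[swap] + floor(len[swap] / 4)
    ce[swap] <- end[swap] - floor(len[swap] / 4)
    cds_start[coding] <- cs[coding]
    cds_end[coding] <- ce[coding]

    genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                        chrom = chrom, start = start, end = end,
                        strand = strand, cds_start = cds_start,
                        cds_end = cds_end, stringsAsFactors = FALSE)
    lengths_out <- if (is.null(chrom_length)) {
      tapply(end, chrom, max) + 10000
    } else {
      stats::setNames(rep(chrom_length, length(unique(chrom))), unique(chrom))
    }
    lengths_out <- stats::setNames(as.numeric(lengths_out),
                                   names(tapply(end, chrom, max)))
    annotation <- genome_annotation(genes, exons, chrom_lengths = lengths_out)
    list(annotation = annotation,
         truth = list(seed = seed, n_genes = n_genes, genes = genes,
                      coding = coding))
  })
}

# ---- stratum geometry shared with the classifier ---------------------------

# Disjoint per-(gene, feature) regions obtained by subtracting every
# higher-precedence candidate region, plus distal-intergenic cells cut at
# nearest-TSS midpoints.  A summit placed inside one of these regions is
# classified into exactly that feature.  Cached on the annotation.
disjoint_strata <- function(annotation, params = annotation_params()) {
  key <- sprintf("strata_%d_%d", params$promoter_window,
                 params$downstream_window)
  if (!is.null(annotation$cache[[key]])) return(annotation$cache[[key]])
  map <- feature_map(annotation, params)
  cand <- map$cand
  mc <- S4Vectors::mcols(cand)
  pieces <- list()
  for (r in 2:6) {
    sel <- mc$rank == r
    if (!any(sel)) next
    higher <- GenomicRanges::reduce(cand[mc$rank < r])
    sub <- GenomicRanges::subtract(cand[sel], higher, ignore.strand = TRUE)
    flat <- unlist(sub, use.names = FALSE)
    idx <- rep(which(sel), S4Vectors::elementNROWS(sub))
    if (length(flat) == 0) next
    S4Vectors::mcols(flat) <- S4Vectors::DataFrame(
      feature = mc$feature[idx], gene_id = mc$gene_id[idx])
    pieces[[length(pieces) + 1L]] <- flat
  }
  prom <- cand[mc$rank == 1]
  S4Vectors::mcols(prom) <- S4Vectors::DataFrame(
    feature = mc$feature[mc$rank == 1], gene_id = mc$gene_id[mc$rank == 1])
  pieces <- c(list(prom), pieces)

  # distal intergenic: complement of all candidate regions, partitioned by
  # nearest-TSS cells (midpoint boundaries)
  for (ch in names(annotation$chrom_lengths)) {
    clen <- annotation$chrom_lengths[[ch]]
    on_ch <- GenomicRanges::seqnames(cand) == ch
    covered <- IRanges::reduce(IRanges::ranges(cand[on_ch]))
    compl <- IRanges::gaps(covered, start = 1L, end = as.integer(clen))
    if (length(compl) == 0) next
    tab <- map$tss_tab[[ch]]
    u <- tab$tss
    mids <- if (length(u) > 1) floor((u[-length(u)] + u[-1]) / 2) else numeric(0)
    cell_lo <- c(0, mids + 1)             # 0-based inclusive
    cell_hi <- c(mids, clen - 1)
    cells <- IRanges::IRanges(start = cell_lo + 1, end = cell_hi + 1)
    hits <- IRanges::findOverlaps(cells, compl)
    if (length(hits) == 0) next
    parts <- IRanges::pintersect(cells[S4Vectors::queryHits(hits)],
                                 compl[S4Vectors::subjectHits(hits)])
    gr <- GenomicRanges::GRanges(ch, parts)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      feature = "DistalIntergenic",
      gene_id = tab$gene_id[S4Vectors::queryHits(hits)])
    pieces[[length(pieces) + 1L]] <- gr
  }
  all_gr <- suppressWarnings(do.call(c, pieces))
  strata <- list(gr = all_gr,
                 key = paste(S4Vectors::mcols(all_gr)$gene_id,
                             S4Vectors::mcols(all_gr)$feature, sep = "\r"))
  annotation$cache[[key]] <- strata
  strata
}

#' Generate a synthetic peak set with planted placement structure
#'
#' Each peak is placed by (i) drawing a gene with probability proportional
#' to 1, or to `rho` for members of `gene_set`, (ii) drawing a feature
#' stratum from `feature_weights`, and (iii) placing the summit uniformly
#' within that stratum of that gene (strata use the same geometry as the
#' classifier, with higher-precedence regions carved out, so the intended
#' stratum is recovered on classification).  If the drawn gene lacks the
#' drawn stratum (e.g. a single-exon gene has no intron) the pair is
#' redrawn; redraws are counted in the truth record.
#'
#' @param annotation A [genome_annotation()].
#' @param n_peaks Number of peaks.
#' @param feature_weights Named weights over the seven features (normalized
#'   internally).  The default favours distal intergenic, intronic and
#'   promoter placement.
#' @param rho Gene-set density multiplier (>= 0); 1 means no preference.
#' @param gene_set Optional [gene_set()] receiving the `rho` multiplier.
#' @param width_meanlog,width_sdlog Log-normal peak width parameters.
#' @param pileup_meanlog,pileup_sdlog Log-normal pileup parameters; may be
#'   named vectors over features for per-stratum pileup distributions.
#' @param params [annotation_params()] defining the stratum geometry.
#' @param sample_id Label of the generated peak set.
#' @param seed Integer seed.
#' @return List with `peaks` (a [peak_set()]) and `truth` (per-peak intended
#'   gene/feature keyed by peak name, redraw count, parameters).
#' @export
generate_peaks <- function(annotation, n_peaks = 2000,
                           feature_weights = c(Promoter = 0.20,
                                               FivePrimeUTR = 0.02,
                                               ThreePrimeUTR = 0.03,
                                               Exon = 0.05, Intron = 0.30,
                                               Downstream = 0.05,
                                               DistalIntergenic = 0.35),
                           rho = 1, gene_set = NULL,
                           width_meanlog = log(300), width_sdlog = 0.4,
                           pileup_meanlog = log(20), pileup_sdlog = 0.7,
                           params = annotation_params(),
                           sample_id = "sim", seed = 1) {
  stopifnot(n_peaks >= 1, rho >= 0)
  if (is.null(names(feature_weights)) ||
      !all(names(feature_weights) %in% .FEATURE_CLASSES)) {
    stop("'feature_weights' must be named with feature classes")
  }
  fw <- stats::setNames(numeric(7), .FEATURE_CLASSES)
  fw[names(feature_weights)] <- feature_weights
  if (sum(fw) <= 0) stop("feature weights must have positive sum")
  fw <- fw / sum(fw)

  strata <- disjoint_strata(annotation, params)
  gr <- strata$gr
  widths_gr <- GenomicRanges::width(gr)
  grp <- split(seq_along(gr), strata$key)
  G <- nrow(annotation$genes)
  gene_ids <- annotation$genes$gene_id
  wg <- rep(1, G)
  if (!is.null(gene_set) && rho != 1) {
    wg[gene_ids %in% gene_set$gene_ids] <- rho
  }

  # genes offering at least one region of each feature; a peak whose drawn
  # gene lacks the drawn stratum redraws its GENE conditional on the
  # feature (so feature marginals stay exactly at the requested weights);
  # only a feature absent from the whole genome redraws the feature itself
  key_parts <- strsplit(names(grp), "\r", fixed = TRUE)
  key_gene <- vapply(key_parts, `[`, character(1), 1)
  key_feat <- vapply(key_parts, `[`, character(1), 2)
  avail <- lapply(stats::setNames(.FEATURE_CLASSES, .FEATURE_CLASSES),
                  function(f) match(unique(key_gene[key_feat == f]), gene_ids))
  usable_f <- .FEATURE_CLASSES[lengths(avail) > 0 & fw > 0]
  if (length(usable_f) == 0) stop("no feature stratum available anywhere")

  with_seed(seed, {
    gene_i <- sample.int(G, n_peaks, replace = TRUE, prob = wg)
    feat <- sample(.FEATURE_CLASSES, n_peaks, replace = TRUE, prob = fw)
    n_redraws <- 0L
    no_gene <- !(feat %in% usable_f)
    if (any(no_gene)) {
      n_redraws <- n_redraws + sum(no_gene)
      feat[no_gene] <- sample(usable_f, sum(no_gene), replace = TRUE,
                              prob = fw[usable_f] / sum(fw[usable_f]))
    }
    key <- paste(gene_ids[gene_i], feat, sep = "\r")
    bad <- which(!(key %in% names(grp)))
    n_redraws <- n_redraws + length(bad)
    for (f in unique(feat[bad])) {
      sel <- bad[feat[bad] == f]
      pool <- avail[[f]]
      gene_i[sel] <- pool[sample.int(length(pool), length(sel),
                                     replace = TRUE, prob = wg[pool])]
    }
    key[bad] <- paste(gene_ids[gene_i[bad]], feat[bad], sep = "\r")
    summit0 <- numeric(n_peaks)
    chrom <- character(n_peaks)
    seqn <- as.character(GenomicRanges::seqnames(gr))
    starts1 <- GenomicRanges::start(gr)
    peaks_by_key <- split(seq_len(n_peaks), key)
    for (k in names(peaks_by_key)) {
      peaks_k <- peaks_by_key[[k]]
      ridx <- grp[[k]]
      w <- widths_gr[ridx]
      cw <- cumsum(w)
      off <- sample.int(cw[length(cw)], length(peaks_k), replace = TRUE)
      j <- findInterval(off - 0.5, c(0, cw))
      pos1 <- starts1[ridx][j] + (off - c(0, cw)[j]) - 1
      summit0[peaks_k] <- pos1 - 1 # back to 0-based
      chrom[peaks_k] <- seqn[ridx][j]
    }
    width <- pmax(50, round(stats::rlnorm(n_peaks, width_meanlog, width_sdlog)))
    left <- pmin(floor(stats::runif(n_peaks) * width), width - 1, summit0)
    start0 <- summit0 - left
    end0 <- start0 + width
    pu_ml <- if (length(pileup_meanlog) > 1) {
      unname(pileup_meanlog[feat])
    } else pileup_meanlog
    pu_sl <- if (length(pileup_sdlog) > 1) unname(pileup_sdlog[feat]) else pileup_sdlog
    pileup <- round(stats::rlnorm(n_peaks, pu_ml, pu_sl), 2)
    name <- sprintf("%s_peak_%06d", sample_id, seq_len(n_peaks))
    ps <- peak_set(sample_id, data.frame(
      chrom = chrom, start = start0, end = end0, name = name,
      score = round(pileup * 10), summit = summit0, pileup = pileup,
      stringsAsFactors = FALSE))
    truth <- list(seed = seed, n_redraws = n_redraws, rho = rho,
                  feature_weights = fw,
                  set_genes = if (is.null(gene_set)) character(0) else gene_set$gene_ids,
                  peaks = data.frame(name = name,
                                     gene_id = gene_ids[gene_i],
                                     feature = feat, stringsAsFactors = FALSE))
    list(peaks = ps, truth = truth)
  })
}

# default per-feature emission distributions over the 15-state vocabulary:
# promoters TssA-heavy, transcribed features Tx-heavy, unassociated distal
# space quiescent
default_emissions <- function() {
  list(Promoter = c(TssA = 0.60, TssAFlnk = 0.25, TssBiv = 0.05, Quies = 0.10),
       FivePrimeUTR = c(TssAFlnk = 0.40, TxFlnk = 0.30, Tx = 0.20, Quies = 0.10),
       ThreePrimeUTR = c(Tx = 0.50, TxWk = 0.30, Quies = 0.20),
       Exon = c(Tx = 0.50, TxWk = 0.30, EnhG = 0.10, Quies = 0.10),
       Intron = c(TxWk = 0.40, EnhG = 0.15, Enh = 0.20, Quies = 0.25),
       Downstream = c(TxWk = 0.30, Enh = 0.20, EnhG = 0.10, Quies = 0.40),
       DistalIntergenic = c(Quies = 0.60, Enh = 0.15, Het = 0.10,
                            ReprPCWk = 0.10, TssBiv = 0.05))
}

#' Generate a feature-dependent chromatin-state segmentation
#'
#' Covers every chromosome of the annotation with a full grid of
#' `bin_size` bp bins; each bin's state is drawn from the emission
#' distribution of the genomic feature at the bin centre (classified with
#' the same geometry as the analysis pipeline).
#'
#' @param annotation A [genome_annotation()].
#' @param emissions Named list (per feature class) of named emission
#'   probability vectors over the state vocabulary; see
#'   `peaksets:::default_emissions()` for the default shape.
#' @param bin_size Bin width in bp (default 200).
#' @param states State vocabulary (default [roadmap_states()]).
#' @param params [annotation_params()].
#' @param seed Integer seed.
#' @return List with `segmentation` (a [chromatin_segmentation()]) and
#'   `truth` (per-bin feature and state).
#' @export
generate_segmentation <- function(annotation, emissions = default_emissions(),
                                  bin_size = 200, states = roadmap_states(),
                                  params = annotation_params(), seed = 1) {
  for (f in .FEATURE_CLASSES) {
    if (is.null(emissions[[f]])) stop("missing emission distribution for ", f)
    e <- emissions[[f]]
    if (any(e < 0) || sum(e) <= 0) stop("invalid emission weights for ", f)
    if (!all(names(e) %in% states)) {
      stop("emission states for ", f, " outside the vocabulary")
    }
    emissions[[f]] <- e / sum(e)
  }
  map <- feature_map(annotation, params)
  with_seed(seed, {
    bins <- list()
    truth_rows <- list()
    for (ch in names(annotation$chrom_lengths)) {
      clen <- annotation$chrom_lengths[[ch]]
      n_bins <- as.integer(ceiling(clen / bin_size))
      centers <- (seq_len(n_bins) - 1) * bin_size + floor(bin_size / 2)
      cls <- classify_summits(rep(ch, n_bins), centers, map)
      code <- integer(n_bins)
      for (f in unique(cls$feature)) {
        sel <- which(cls$feature == f)
        e <- emissions[[f]]
        si <- match(names(e), states)
        code[sel] <- si[sample.int(length(e), length(sel), replace = TRUE,
                                   prob = e)]
      }
      bins[[ch]] <- code
      truth_rows[[ch]] <- data.frame(chrom = ch, bin = seq_len(n_bins) - 1,
                                     feature = cls$feature,
                                     state = states[code],
                                     stringsAsFactors = FALSE)
    }
    seg <- chromatin_segmentation(bins, states = states, bin_size = bin_size)
    list(segmentation = seg,
         truth = list(seed = seed, emissions = emissions,
                      bins = do.call(rbind, truth_rows)))
  })
}

#' Generate a two-block expression matrix with planted structure
#'
#' Emulates a cohort with two anti-correlated gene programs
#' (epithelial-like and mesenchymal-like blocks) realized through shared
#' latent factors, plus planted differentially expressed genes and null
#' genes for two sample groups.  With block loadings `l = sqrt(within_cor)`
#' on two factors correlated at `between_cor / within_cor`, within-block
#' gene-gene correlation is `within_cor` and cross-block correlation
#' `between_cor` in expectation.
#'
#' @param n_samples Number of samples (columns).
#' @param block_sizes Sizes of the two correlated blocks (default 45 and 54,
#'   the sizes of the epithelial/mesenchymal signature sets).
#' @param within_cor Within-block correlation in (0, 1].
#' @param between_cor Between-block correlation; requires
#'   `|between_cor| <= within_cor` to keep the factor model feasible.
#' @param n_de_genes,de_effect,de_sigma Planted differential expression:
#'   number of genes, log2 effect added to group 2, and noise SD.
#' @param n_null_genes Number of unperturbed noise genes.
#' @param groups Two-group sample split as `c(n1, n2)` (defaults to halves).
#' @param seed Integer seed.
#' @return List with `matrix` (log2 expression, genes x samples) and
#'   `truth` (block membership, DE genes, group labels, parameters).
#' @export
generate_expression <- function(n_samples = 60, block_sizes = c(45, 54),
                                within_cor = 0.8, between_cor = -0.8,
                                n_de_genes = 0, de_effect = 2, de_sigma = 0.25,
                                n_null_genes = 0, groups = NULL, seed = 1) {
  stopifnot(n_samples >= 2, within_cor > 0, within_cor <= 1, de_sigma >= 0)
  if (abs(between_cor) > within_cor + 1e-12) {
    stop("infeasible correlation targets: need |between_cor| <= within_cor")
  }
  if (is.null(groups)) {
    groups <- c(floor(n_samples / 2), n_samples - floor(n_samples / 2))
  }
  if (length(groups) != 2 || sum(groups) != n_samples) {
    stop("'groups' must be two sizes summing to n_samples")
  }
  with_seed(seed, {
    group_labels <- rep(c("g1", "g2"), groups)
    l <- sqrt(within_cor)
    c12 <- between_cor / within_cor
    f1 <- stats::rnorm(n_samples)
    f2 <- c12 * f1 + sqrt(max(1 - c12^2, 0)) * stats::rnorm(n_samples)
    rows <- list()
    ids <- character(0)
    blocks <- character(0)
    nA <- block_sizes[1]
    nB <- block_sizes[2]
    if (nA > 0) {
      noise <- matrix(stats::rnorm(nA * n_samples, sd = sqrt(1 - l^2)), nA)
      baseA <- stats::runif(nA, 6, 10)
      rows$A <- baseA + l * matrix(f1, nA, n_samples, byrow = TRUE) + noise
      ids <- c(ids, sprintf("EPI%03d", seq_len(nA)))
      blocks <- c(blocks, rep("epithelial-like", nA))
    }
    if (nB > 0) {
      noise <- matrix(stats::rnorm(nB * n_samples, sd = sqrt(1 - l^2)), nB)
      baseB <- stats::runif(nB, 6, 10)
      rows$B <- baseB + l * matrix(f2, nB, n_samples, byrow = TRUE) + noise
      ids <- c(ids, sprintf("MES%03d", seq_len(nB)))
      blocks <- c(blocks, rep("mesenchymal-like", nB))
    }
    if (n_de_genes > 0) {
      noise <- matrix(stats::rnorm(n_de_genes * n_samples, sd = de_sigma),
                      n_de_genes)
      baseD <- stats::runif(n_de_genes, 6, 10)
      shift <- matrix(ifelse(group_labels == "g2", de_effect, 0),
                      n_de_genes, n_samples, byrow = TRUE)
      rows$D <- baseD + noise + shift
      ids <- c(ids, sprintf("DEG%03d", seq_len(n_de_genes)))
      blocks <- c(blocks, rep("de", n_de_genes))
    }
    if (n_null_genes > 0) {
      noise <- matrix(stats::rnorm(n_null_genes * n_samples, sd = de_sigma),
                      n_null_genes)
      baseN <- stats::runif(n_null_genes, 6, 10)
      rows$N <- baseN + noise
      ids <- c(ids, sprintf("BG%04d", seq_len(n_null_genes)))
      blocks <- c(blocks, rep("null", n_null_genes))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    colnames(m) <- sprintf("S%02d", seq_len(n_samples))
    truth <- list(seed = seed, blocks = stats::setNames(blocks, ids),
                  de_genes = ids[blocks == "de"], de_effect = de_effect,
                  de_sigma = de_sigma, group_labels = group_labels,
                  within_cor = within_cor, between_cor = between_cor)
    list(matrix = m, truth = truth)
  })
}
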