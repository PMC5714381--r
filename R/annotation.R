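# Gene models and genomic-feature classification of peak summits.
#
# All user-facing coordinates are BED-style: 0-based, half-open intervals;
# summits and TSSs are single 0-based offsets.  Internally interval algebra
# is done on 1-based closed IRanges/GRanges.

#' Annotation parameters
#'
#' Window sizes controlling feature classification.  The promoter is the
#' region up to `promoter_window` bp upstream and downstream of a TSS;
#' "downstream" is the `downstream_window` bp past the gene end in gene
#' orientation.
#'
#' @param promoter_window Promoter half-width in bp (default 3000).
#' @param downstream_window Downstream window in bp (default 3000).
#' @return An object of class `"annotation_params"`.
#' @export
annotation_params <- function(promoter_window = 3000, downstream_window = 3000) {
  assert_scalar_number(promoter_window, "promoter_window", positive = TRUE)
  assert_scalar_number(downstream_window, "downstream_window", positive = TRUE)
  structure(list(promoter_window = as.integer(promoter_window),
                 downstream_window = as.integer(downstream_window)),
            class = "annotation_params")
}

#' Construct a genome annotation from gene and exon tables
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), and optionally `symbol`,
#'   `cds_start`, `cds_end` (NA for non-coding genes).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   exons of each gene must be non-overlapping and lie within the gene span.
#' @param chrom_lengths Optional named vector of chromosome extents; defaults
#'   to the largest annotated end plus 10 kb per chromosome.
#' @return An object of class `"genome_annotation"` with elements `genes`
#'   (including a computed `tss` column), `exons` and `chrom_lengths`.
#' @export
genome_annotation <- function(genes, exons, chrom_lengths = NULL) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("'genes' must have columns: ", paste(req, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    bad <- which(genes$start < 0 | genes$start >= genes$end)[1]
    stop(sprintf("gene '%s': invalid span [%d, %d)", genes$gene_id[bad],
                 genes$start[bad], genes$end[bad]))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$cds_start)) genes$cds_start <- NA_real_
  if (is.null(genes$cds_end)) genes$cds_end <- NA_real_
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)

  # exon sanity: within span, non-overlapping per gene
  gi <- match(exons$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("exon rows refer to unknown gene_ids")
  if (any(exons$start < genes$start[gi]) || any(exons$end > genes$end[gi])) {
    stop("exons must lie within their gene span")
  }
  o <- order(gi, exons$start)
  exons <- exons[o, , drop = FALSE]
  gi <- gi[o]
  same <- gi[-1] == gi[-length(gi)]
  if (length(gi) > 1 && any(same & exons$start[-1] < exons$end[-length(gi)])) {
    stop("exons of a gene must be non-overlapping")
  }
  cds_ok <- is.na(genes$cds_start) |
    (genes$cds_start >= genes$start & genes$cds_end <= genes$end &
       genes$cds_start <= genes$cds_end)
  if (!all(cds_ok)) stop("CDS bounds must lie within the gene span")
  # empty CDS (thickStart == thickEnd) means non-coding
  empty_cds <- !is.na(genes$cds_start) & genes$cds_start == genes$cds_end
  genes$cds_start[empty_cds] <- NA_real_
  genes$cds_end[empty_cds] <- NA_real_

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max) + 10000
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons,
                 chrom_lengths = chrom_lengths, cache = new.env(parent = emptyenv())),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("Genome annotation: %d genes (%d coding), %d exons, %d chromosome(s)\n",
              nrow(x$genes), sum(!is.na(x$genes$cds_start)), nrow(x$exons),
              length(x$chrom_lengths)))
  invisible(x)
}

#' Read gene models from a BED12 file
#'
#' Parses tab-separated BED12 (track/browser/comment lines skipped), using
#' the name field as `gene_id`, thickStart/thickEnd as CDS bounds (equal
#' values mean non-coding) and the block fields as exons.
#'
#' @param path Path to a BED12 file.
#' @return A [genome_annotation()] object.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("no gene records in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop(sprintf("line %d: expected >= 12 tab-separated fields, found %d",
                 idx[which(nf < 12)[1]], nf[which(nf < 12)[1]]))
  }
  genes_list <- vector("list", length(fields))
  exons_list <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ln <- idx[i]
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-numeric start/end", ln))
    }
    if (start >= end) stop(sprintf("line %d: start >= end", ln))
    strand <- f[6]
    if (!strand %in% c("+", "-")) {
      stop(sprintf("line %d: strand must be '+' or '-'", ln))
    }
    thick_start <- suppressWarnings(as.numeric(f[7]))
    thick_end <- suppressWarnings(as.numeric(f[8]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1]]))
    offsets <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1]]))
    if (is.na(n_blocks) || length(sizes) != n_blocks ||
        length(offsets) != n_blocks || anyNA(sizes) || anyNA(offsets)) {
      stop(sprintf("line %d: inconsistent blockCount/blockSizes/blockStarts", ln))
    }
    ex_start <- start + offsets
    ex_end <- ex_start + sizes
    if (any(ex_end > end) || any(diff(ex_start) < 0) ||
        (n_blocks > 1 && any(ex_start[-1] < ex_end[-n_blocks]))) {
      stop(sprintf("line %d: blocks inconsistent with span", ln))
    }
    genes_list[[i]] <- data.frame(
      gene_id = f[4], chrom = f[1], start = start, end = end, strand = strand,
      cds_start = thick_start, cds_end = thick_end,
      stringsAsFactors = FALSE)
    exons_list[[i]] <- data.frame(gene_id = f[4], chrom = f[1],
                                  start = ex_start, end = ex_end,
                                  stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_list)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_ids in ", path, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  genome_annotation(genes, do.call(rbind, exons_list))
}

#' Write a genome annotation as BED12
#'
#' @param annotation A [genome_annotation()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed12 <- function(annotation, path) {
  g <- annotation$genes
  ex <- annotation$exons
  ex <- ex[order(match(ex$gene_id, g$gene_id), ex$start), , drop = FALSE]
  sp <- split(seq_len(nrow(ex)), factor(ex$gene_id, levels = g$gene_id))
  sizes <- vapply(sp, function(i) paste0(ex$end[i] - ex$start[i], collapse = ","),
                  character(1))
  offs <- vapply(seq_along(sp), function(k) {
    i <- sp[[k]]
    paste0(ex$start[i] - g$start[k], collapse = ",")
  }, character(1))
  thick_start <- ifelse(is.na(g$cds_start), g$start, g$cds_start)
  thick_end <- ifelse(is.na(g$cds_end), g$start, g$cds_end)
  out <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                 g$chrom, as.integer(g$start), as.integer(g$end), g$gene_id,
                 g$strand, as.integer(thick_start), as.integer(thick_end),
                 lengths(sp), sizes, offs)
  writeLines(out, path)
  invisible(path)
}

# ---- feature geometry -------------------------------------------------------

# Candidate (gene, feature) regions as one GRanges with metadata columns
# feature/rank/gene_id/tss/gstrand, plus a per-chromosome TSS lookup table.
# Cached on the annotation, keyed by the window parameters.
feature_map <- function(annotation, params = annotation_params()) {
  key <- sprintf("map_%d_%d", params$promoter_window, params$downstream_window)
  if (!is.null(annotation$cache[[key]])) return(annotation$cache[[key]])
  g <- annotation$genes
  ex <- annotation$exons
  w_p <- params$promoter_window
  w_d <- params$downstream_window

  mk <- function(chrom, start0, end0, gene_idx, feature) {
    keep <- end0 > start0 & end0 > 0
    start0 <- pmax(start0[keep], 0)
    gr <- gr0(chrom[keep], start0, end0[keep])
    S4Vectors::mcols(gr)$feature <- feature
    S4Vectors::mcols(gr)$gene_id <- g$gene_id[gene_idx[keep]]
    S4Vectors::mcols(gr)$tss <- g$tss[gene_idx[keep]]
    S4Vectors::mcols(gr)$gstrand <- g$strand[gene_idx[keep]]
    gr
  }
  gidx <- seq_len(nrow(g))
  # promoter: summits s with |s - tss| <= w_p, i.e. 0-based [tss-w, tss+w+1)
  prom <- mk(g$chrom, g$tss - w_p, g$tss + w_p + 1, gidx, "Promoter")
  # downstream: w_d bp past the gene end in gene orientation
  dw_start <- ifelse(g$strand == "+", g$end, g$start - w_d)
  dw_end <- ifelse(g$strand == "+", g$end + w_d, g$start)
  down <- mk(g$chrom, dw_start, dw_end, gidx, "Downstream")

  ei <- match(ex$gene_id, g$gene_id)
  exon <- mk(ex$chrom, ex$start, ex$end, ei, "Exon")
  # UTRs: exonic sequence outside the CDS on the 5'/3' side (coding genes)
  cs <- g$cds_start[ei]
  ce <- g$cds_end[ei]
  coding <- !is.na(cs)
  plus <- g$strand[ei] == "+"
  u5_s <- ifelse(plus, ex$start, pmax(ex$start, ce))
  u5_e <- ifelse(plus, pmin(ex$end, cs), ex$end)
  u3_s <- ifelse(plus, pmax(ex$start, ce), ex$start)
  u3_e <- ifelse(plus, ex$end, pmin(ex$end, cs))
  u5_keep <- coding & u5_e > u5_s
  u3_keep <- coding & u3_e > u3_s
  utr5 <- mk(ex$chrom[u5_keep], u5_s[u5_keep], u5_e[u5_keep], ei[u5_keep],
             "FivePrimeUTR")
  utr3 <- mk(ex$chrom[u3_keep], u3_s[u3_keep], u3_e[u3_keep], ei[u3_keep],
             "ThreePrimeUTR")
  # introns: gene span minus exons
  span_gr <- gr0(g$chrom, g$start, g$end)
  ex_grl <- GenomicRanges::GRangesList(lapply(split(
    gr0(ex$chrom, ex$start, ex$end), factor(ei, levels = gidx)), identity))
  intr_grl <- IRanges::psetdiff(span_gr, ex_grl)
  intr <- unlist(intr_grl, use.names = FALSE)
  iidx <- rep(gidx, S4Vectors::elementNROWS(intr_grl))
  S4Vectors::mcols(intr)$feature <- if (length(intr)) "Intron" else character(0)
  S4Vectors::mcols(intr)$gene_id <- g$gene_id[iidx]
  S4Vectors::mcols(intr)$tss <- g$tss[iidx]
  S4Vectors::mcols(intr)$gstrand <- g$strand[iidx]

  cand <- c(prom, utr5, utr3, exon, intr, down)
  S4Vectors::mcols(cand)$rank <- match(S4Vectors::mcols(cand)$feature,
                                       .FEATURE_CLASSES)

  # per-chromosome TSS lookup: unique sorted positions; at shared positions
  # keep the lexicographically smallest gene_id (global tie-break rule)
  og <- g[order(g$chrom, g$tss, g$gene_id), , drop = FALSE]
  first <- !duplicated(paste(og$chrom, og$tss))
  tss_tab <- split(og[first, c("tss", "gene_id", "strand")], og$chrom[first])

  map <- list(params = params, cand = cand, tss_tab = tss_tab)
  annotation$cache[[key]] <- map
  map
}

# nearest-TSS assignment for positions with no candidate feature hit
nearest_tss <- function(chrom, pos, tss_tab) {
  out_gene <- character(length(pos))
  out_d <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    tab <- tss_tab[[ch]]
    if (is.null(tab) || nrow(tab) == 0) {
      stop("unassignable chromosome (no genes): ", ch)
    }
    u <- tab$tss
    p <- pos[sel]
    i <- findInterval(p, u)
    dl <- ifelse(i >= 1, p - u[pmax(i, 1)], Inf)
    dr <- ifelse(i < length(u), u[pmin(i + 1, length(u))] - p, Inf)
    use_left <- dl < dr
    tie <- dl == dr
    gid_l <- tab$gene_id[pmax(i, 1)]
    gid_r <- tab$gene_id[pmin(i + 1, length(u))]
    gid <- ifelse(use_left, gid_l, gid_r)
    gid[tie] <- pmin(gid_l[tie], gid_r[tie])
    str_sel <- ifelse(gid == gid_l, tab$strand[pmax(i, 1)],
                      tab$strand[pmin(i + 1, length(u))])
    tss_sel <- ifelse(gid == gid_l, u[pmax(i, 1)], u[pmin(i + 1, length(u))])
    out_gene[sel] <- gid
    # signed distance in gene orientation (negative = upstream)
    out_d[sel] <- ifelse(str_sel == "+", p - tss_sel, tss_sel - p)
  }
  list(gene_id = out_gene, dist = out_d)
}

# vectorized summit classification; returns data.frame(feature, gene_id,
# dist_to_tss) parallel to the inputs
classify_summits <- function(chrom, summit, map) {
  n <- length(summit)
  feature <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  q <- points_gr0(chrom, summit)
  hits <- GenomicRanges::findOverlaps(q, map$cand, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    mc <- S4Vectors::mcols(map$cand)
    d <- ifelse(mc$gstrand[sh] == "+", summit[qh] - mc$tss[sh],
                mc$tss[sh] - summit[qh])
    # precedence, then |distance to TSS|, then gene_id
    o <- order(qh, mc$rank[sh], abs(d), mc$gene_id[sh])
    pick <- o[!duplicated(qh[o])]
    feature[qh[pick]] <- mc$feature[sh[pick]]
    gene_id[qh[pick]] <- mc$gene_id[sh[pick]]
    dist[qh[pick]] <- d[pick]
  }
  miss <- which(is.na(feature))
  if (length(miss)) {
    nt <- nearest_tss(chrom[miss], summit[miss], map$tss_tab)
    feature[miss] <- "DistalIntergenic"
    gene_id[miss] <- nt$gene_id
    dist[miss] <- nt$dist
  }
  data.frame(feature = feature, gene_id = gene_id, dist_to_tss = dist,
             stringsAsFactors = FALSE)
}

#' Classify peak summits into the seven genomic features
#'
#' Each summit is assigned exactly one feature by the precedence
#' Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream > DistalIntergenic,
#' with ties between genes offering the same winning class broken by smaller
#' |distance to TSS|, then lexicographic gene id.  Summits inside no
#' candidate region are distal intergenic and assigned the nearest-TSS gene.
#'
#' @param peaks A `peak_set` (see [read_narrowpeak()]) or a data.frame with
#'   columns `chrom`, `start`, `end`, `summit` (0-based).
#' @param annotation A [genome_annotation()] object.
#' @param params [annotation_params()].
#' @return A data.frame of class `"annotated_peaks"`: the peak columns plus
#'   `feature`, `gene_id` and signed `dist_to_tss` (negative = upstream of
#'   the assigned gene's TSS in gene orientation).
#' @export
classify_peaks <- function(peaks, annotation, params = annotation_params()) {
  df <- if (inherits(peaks, "peak_set")) peaks$peaks else as.data.frame(peaks)
  if (!all(c("chrom", "summit") %in% names(df))) {
    stop("'peaks' must have columns 'chrom' and 'summit'")
  }
  if (nrow(df) == 0) stop("no peaks to classify")
  map <- feature_map(annotation, params)
  missing_chr <- setdiff(unique(df$chrom), unique(annotation$genes$chrom))
  if (length(missing_chr)) {
    stop("unassignable chromosome (no genes): ",
         paste(missing_chr, collapse = ", "))
  }
  cls <- classify_summits(df$chrom, df$summit, map)
  out <- cbind(df, cls)
  class(out) <- c("annotated_peaks", "data.frame")
  out
}

#' Classify a single peak
#'
#' Convenience wrapper around [classify_peaks()] for one peak.
#'
#' @param peak A one-row data.frame (or list) with `chrom` and `summit`.
#' @inheritParams classify_peaks
#' @return A one-row `"annotated_peaks"` data.frame.
#' @export
classify_peak <- function(peak, annotation, params = annotation_params()) {
  df <- as.data.frame(peak, stringsAsFactors = FALSE)
  classify_peaks(df, annotation, params)
}

#' Feature distribution of annotated peaks
#'
#' Per-feature counts and fractions of a set of annotated peaks, optionally
#' restricted to peaks assigned to genes of a gene set.
#'
#' @param annotated An `"annotated_peaks"` data.frame from [classify_peaks()].
#' @param restrict_to Optional [gene_set()]; keeps peaks whose assigned gene
#'   is in the set.
#' @return An object of class `"feature_distribution"`: list with `counts`
#'   and `fractions` (named over the seven features) and `total`.
#' @export
feature_distribution <- function(annotated, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    annotated <- annotated[annotated$gene_id %in% restrict_to$gene_ids, ,
                           drop = FALSE]
    if (nrow(annotated) == 0) {
      stop("no peaks associated with gene set '", restrict_to$name, "'")
    }
  }
  counts <- table(factor(annotated$feature, levels = .FEATURE_CLASSES))
  counts <- stats::setNames(as.integer(counts), .FEATURE_CLASSES)
  total <- sum(counts)
  structure(list(counts = counts, fractions = counts / total, total = total),
            class = "feature_distribution")
}

#' @export
print.feature_distribution <- function(x, ...) {
  cat(sprintf("Feature distribution of %d peaks\n", x$total))
  df <- data.frame(feature = names(x$counts), count = x$counts,
                   fraction = round(x$fractions, 4), row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Write annotated peaks as TSV
#'
#' Columns: chrom, start, end, summit, feature, gene_id, dist_to_tss.
#'
#' @param annotated An `"annotated_peaks"` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotated_peaks <- function(annotated, path) {
  cols <- c("chrom", "start", "end", "summit", "feature", "gene_id",
            "dist_to_tss")
  utils::write.table(annotated[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
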