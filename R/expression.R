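# Expression-side analyses: probe collapse, gene-wise scaling, pairwise
# correlation, complete-linkage clustering, two-group differential
# expression and directed/undirected gene-set perturbation tests.
#
# Expression matrices are log2-scale, genes (or probes) in rows, samples in
# columns.  Normalization is upstream; matrices arrive normalized.

#' Read an expression matrix from TSV
#'
#' Header row holds sample ids; the first column holds probe or gene ids.
#' Rows containing any missing value are dropped (their number is
#' messaged) — downstream statistics assume complete rows.
#'
#' @param path Input TSV.
#' @return Numeric matrix with id rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- rowSums(!is.finite(m)) > 0
  if (any(bad)) {
    message(sprintf("dropped %d row(s) with missing values", sum(bad)))
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix with rownames (ids) and colnames (samples).
#' @param path Output path.
#' @param id_column Name of the id column (default `"gene_id"`).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe rows to one row per gene by largest IQR
#'
#' When several probes map to the same gene, the probe whose values have
#' the largest interquartile range across samples is retained; ties break
#' by lexicographically smaller probe id.  Probes without a mapping are
#' dropped (count messaged).
#'
#' @param m Numeric matrix with probe rownames.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; each
#'   probe may map to at most one gene.
#' @return Numeric matrix with gene rownames; attribute `"probe_ids"` holds
#'   the retained probe per gene.
#' @export
collapse_probes <- function(m, probe_map) {
  if (nrow(probe_map) == 0) stop("empty probe-to-gene mapping")
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop("'probe_map' needs columns probe_id and gene_id")
  }
  probe_map <- unique(probe_map[, c("probe_id", "gene_id")])
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probes mapping to more than one gene: ",
         paste(utils::head(unique(
           probe_map$probe_id[duplicated(probe_map$probe_id)]), 5),
           collapse = ", "))
  }
  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)
  mapped <- rownames(m) %in% names(gene_of)
  if (sum(!mapped) > 0) {
    message(sprintf("dropped %d unmapped probe(s)", sum(!mapped)))
  }
  m <- m[mapped, , drop = FALSE]
  if (nrow(m) == 0) stop("no probe of the matrix is mapped")
  iqr <- apply(m, 1, stats::IQR)
  cand <- data.frame(probe_id = rownames(m),
                     gene_id = unname(gene_of[rownames(m)]),
                     iqr = iqr, stringsAsFactors = FALSE)
  cand <- cand[order(cand$gene_id, -cand$iqr, cand$probe_id), , drop = FALSE]
  keep <- cand[!duplicated(cand$gene_id), , drop = FALSE]
  out <- m[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  attr(out, "probe_ids") <- stats::setNames(keep$probe_id, keep$gene_id)
  out
}

#' Scale each gene to zero mean and unit variance across samples
#'
#' Rows with zero variance become all-zeros, with a warning.
#'
#' @param m Numeric matrix (genes x samples, >= 2 samples).
#' @return Matrix of the same shape.
#' @export
zscale_genes <- function(m) {
  if (ncol(m) < 2) stop("need >= 2 samples to scale")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance row(s) set to 0", sum(zero)))
    s[zero] <- 1
  }
  out <- (m - mu) / s
  out[zero, ] <- 0
  out
}

#' Pairwise Pearson correlation of selected genes
#'
#' @param m Numeric expression matrix (genes x samples, >= 3 samples).
#' @param gene_subset Character vector of rownames to correlate; all must
#'   be present.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(m, gene_subset = rownames(m)) {
  missing <- setdiff(gene_subset, rownames(m))
  if (length(missing)) {
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
  }
  if (ncol(m) < 3) stop("need >= 3 samples for correlation")
  r <- stats::cor(t(m[gene_subset, , drop = FALSE]))
  diag(r) <- 1
  r
}

#' Complete-linkage hierarchical clustering
#'
#' For expression input the distance is Euclidean on gene-wise z-scaled
#' rows; for a correlation matrix the distance is `1 - r`.
#'
#' @param x Expression matrix (genes x samples) or a symmetric correlation
#'   matrix.
#' @param input Either `"expression"` or `"correlation"`.
#' @param k Optional number of flat clusters to cut.
#' @return An object of class `"hcluster_result"`: list with the `hclust`
#'   tree, `order` (leaf order), and `clusters` (named cut at `k`, or NULL).
#' @export
hier_cluster <- function(x, input = c("expression", "correlation"), k = NULL) {
  input <- match.arg(input)
  if (nrow(x) < 2) stop("need >= 2 items to cluster")
  d <- if (input == "expression") {
    stats::dist(zscale_genes(x))
  } else {
    if (nrow(x) != ncol(x)) stop("correlation input must be square")
    stats::as.dist(1 - x)
  }
  if (any(!is.finite(d))) stop("non-finite distances")
  hc <- stats::hclust(d, method = "complete")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, order = hc$order, clusters = clusters),
            class = "hcluster_result")
}

#' @export
print.hcluster_result <- function(x, ...) {
  cat(sprintf("Complete-linkage clustering of %d items\n",
              length(x$hclust$order)))
  if (!is.null(x$clusters)) {
    cat("  cluster sizes:", paste(table(x$clusters), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-group differential expression
#'
#' Per gene: log2 fold change (mean of group 2 minus mean of group 1 on the
#' log2 matrix), a t statistic with p-value, Benjamini-Hochberg adjusted
#' p-value, and a significance flag at `adjusted p < alpha` and
#' `|log2FC| > lfc_threshold` (defaults 0.05 and 1.5).
#'
#' The default `"moderated"` method uses limma's empirical-Bayes moderated
#' t statistic, which stabilizes the per-gene variance estimate by shrinking
#' it toward a common prior — essential for power in small designs such as
#' three replicates per group.  `"welch"` performs a plain gene-wise Welch
#' t-test instead (no information sharing across genes).
#'
#' @param m Log2 expression matrix (genes x samples).
#' @param group_labels Factor/character vector over columns with exactly two
#'   levels; each group needs >= 2 samples.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1.5).
#' @param method `"moderated"` (limma eBayes, default) or `"welch"`.
#' @return A data.frame of class `"de_table"`: gene_id, log2fc, t, df,
#'   p_value, p_adjusted, significant.
#' @export
differential_expression <- function(m, group_labels, alpha = 0.05,
                                    lfc_threshold = 1.5,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  group_labels <- as.factor(group_labels)
  if (length(group_labels) != ncol(m)) {
    stop("'group_labels' must have one label per sample column")
  }
  if (nlevels(group_labels) != 2) stop("exactly two groups required")
  g1 <- which(group_labels == levels(group_labels)[1])
  g2 <- which(group_labels == levels(group_labels)[2])
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group needs at least 2 samples")
  }
  if (method == "moderated") {
    design <- stats::model.matrix(~group_labels)
    fit <- limma::eBayes(limma::lmFit(m, design))
    lfc <- fit$coefficients[, 2]
    tstat <- fit$t[, 2]
    df <- rep_len(fit$df.total, nrow(m))
    p <- fit$p.value[, 2]
  } else {
    n1 <- length(g1)
    n2 <- length(g2)
    m1 <- rowMeans(m[, g1, drop = FALSE])
    m2 <- rowMeans(m[, g2, drop = FALSE])
    v1 <- rowSums((m[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
    v2 <- rowSums((m[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
    lfc <- m2 - m1
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, lfc / sqrt(se2),
                    ifelse(lfc == 0, 0, sign(lfc) * Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
    p <- ifelse(is.finite(tstat),
                2 * stats::pt(abs(tstat), df, lower.tail = FALSE), 0)
    p[tstat == 0 & se2 == 0] <- 1
  }
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(m), log2fc = unname(lfc),
                    t = unname(tstat), df = unname(df),
                    p_value = unname(p), p_adjusted = padj,
                    significant = padj < alpha & abs(lfc) > lfc_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Gene-set perturbation test on differential-expression statistics
#'
#' Tests whether a gene set is perturbed relative to all measured genes by a
#' one-sided Welch two-sample t-test of the set's per-gene statistics
#' against all genes' statistics.  In `"directed"` mode the statistic is the
#' log2 fold change (alternative: set mean greater, i.e. set upregulated);
#' in `"undirected"` mode it is the absolute log2 fold change (alternative:
#' set more perturbed in either direction).  Only sets whose overlap with
#' the measured genes is strictly between `min_size` and `max_size` are
#' tested.
#'
#' @param de A `"de_table"` from [differential_expression()].
#' @param set A [gene_set()].
#' @param mode `"directed"` or `"undirected"`.
#' @param min_size,max_size Exclusive size bounds on the measured overlap
#'   (defaults 5 and 500).
#' @return An object of class `"geneset_test"`: list with `set_name`,
#'   `mode`, `t`, `df`, `p_value`, `n_set`, `n_background`.
#' @export
geneset_perturbation_test <- function(de, set, mode = c("directed", "undirected"),
                                      min_size = 5, max_size = 500) {
  mode <- match.arg(mode)
  stat_all <- if (mode == "directed") de$log2fc else abs(de$log2fc)
  in_set <- de$gene_id %in% set$gene_ids
  n_set <- sum(in_set)
  if (!(n_set > min_size && n_set < max_size)) {
    stop(sprintf("gene set '%s': %d measured genes, outside the (%d, %d) size bounds",
                 set$name, n_set, min_size, max_size))
  }
  tt <- stats::t.test(stat_all[in_set], stat_all, alternative = "greater")
  structure(list(set_name = set$name, mode = mode,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_set = n_set,
                 n_background = length(stat_all)),
            class = "geneset_test")
}

#' @export
print.geneset_test <- function(x, ...) {
  cat(sprintf("Gene-set perturbation test (%s): '%s'\n", x$mode, x$set_name))
  cat(sprintf("  %d set genes vs %d measured genes\n", x$n_set,
              x$n_background))
  cat(sprintf("  t = %.3f (df = %.1f), one-sided p = %.4g\n", x$t, x$df,
              x$p_value))
  invisible(x)
}

#' Write a DE table as TSV
#'
#' @param de A `"de_table"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
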