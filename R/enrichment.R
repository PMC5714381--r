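# Gene sets, peak-gene association counts, hypergeometric feature-bias
# tests, and the bootstrap gene-set peak-count enrichment test with
# skew-normal tail fitting.

#' Construct a gene set
#'
#' @param name Set name.
#' @param gene_ids Character vector of gene identifiers; duplicates are
#'   removed with a message.
#' @return An object of class `"gene_set"` with elements `name`, `gene_ids`.
#' @export
gene_set <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    message(sprintf("gene set '%s': dropped %d duplicate id(s)", name,
                    sum(duplicated(gene_ids))))
    gene_ids <- unique(gene_ids)
  }
  if (length(gene_ids) < 1) stop("a gene set needs at least one gene")
  structure(list(name = name, gene_ids = gene_ids), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$gene_ids)

#' Read a gene set from a plain-text id list
#'
#' One gene id per line; `#` starts a comment; blank lines are skipped.
#'
#' @param path Input file.
#' @param name Set name (defaults to the file name without extension).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no gene ids in ", path)
  gene_set(name, lines)
}

#' Write a gene set to a plain-text id list
#'
#' @param x A [gene_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_set <- function(x, path) {
  writeLines(x$gene_ids, path)
  invisible(path)
}

#' Count associated peaks per gene
#'
#' A peak is associated with the gene assigned to it during classification
#' (all seven features, distal intergenic via nearest TSS).  Every gene of
#' the annotation universe appears in the count vector, genes without peaks
#' with count 0 — the universe for the bootstrap is the full annotated gene
#' list, not just genes with peaks.
#'
#' @param annotated An `"annotated_peaks"` data.frame from [classify_peaks()].
#' @param annotation The [genome_annotation()] defining the gene universe.
#' @return An object of class `"peak_gene_association"`: list with `counts`
#'   (named integer vector over all genes), `n_genes`, `n_peaks`.
#' @export
associate_peaks <- function(annotated, annotation) {
  if (!"gene_id" %in% names(annotated) || anyNA(annotated$gene_id)) {
    stop("peaks carry no gene assignment; run classify_peaks() first")
  }
  universe <- annotation$genes$gene_id
  outside <- setdiff(unique(annotated$gene_id), universe)
  if (length(outside)) {
    stop("peaks assigned to genes outside the annotation: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  counts <- table(factor(annotated$gene_id, levels = universe))
  counts <- stats::setNames(as.integer(counts), universe)
  structure(list(counts = counts, n_genes = length(universe),
                 n_peaks = nrow(annotated)),
            class = "peak_gene_association")
}

#' @export
print.peak_gene_association <- function(x, ...) {
  cat(sprintf("Peak-gene association: %d peaks over %d genes (%d genes with >= 1 peak)\n",
              x$n_peaks, x$n_genes, sum(x$counts > 0)))
  invisible(x)
}

#' Hypergeometric test of feature bias
#'
#' Tests whether gene-set-associated peaks fall into a genomic feature more
#' (or less) often than expected when drawing without replacement from the
#' background peak population.  With `X ~ Hypergeometric(N_pop, K, n)`,
#' where `n` is the number of set peaks, `K` the background peaks in the
#' feature and `N_pop` all background peaks, the enrichment p-value is
#' `P[X >= k]` and the depletion p-value `P[X <= k]` for `k` observed set
#' peaks in the feature.
#'
#' @param set_dist [feature_distribution()] of the gene-set-associated peaks.
#' @param bg_dist [feature_distribution()] of the background (all peaks);
#'   the set must be a subset of the background feature-wise.
#' @param feature Feature label from [feature_classes()].
#' @return An object of class `"hypergeom_test"`: list with `feature`, `k`,
#'   `n`, `K`, `N_pop`, `p_enrich`, `p_deplete`.
#' @export
hypergeom_feature_test <- function(set_dist, bg_dist, feature) {
  feature <- match.arg(feature, .FEATURE_CLASSES)
  if (any(set_dist$counts > bg_dist$counts)) {
    stop("set is not a subset of the background (feature counts exceed background)")
  }
  k <- set_dist$counts[[feature]]
  n <- set_dist$total
  K <- bg_dist$counts[[feature]]
  N_pop <- bg_dist$total
  if (n > N_pop) stop("set total exceeds background total")
  p_enrich <- stats::phyper(k - 1, K, N_pop - K, n, lower.tail = FALSE)
  p_deplete <- stats::phyper(k, K, N_pop - K, n, lower.tail = TRUE)
  structure(list(feature = feature, k = k, n = n, K = K, N_pop = N_pop,
                 p_enrich = p_enrich, p_deplete = p_deplete),
            class = "hypergeom_test")
}

#' @export
print.hypergeom_test <- function(x, ...) {
  cat(sprintf("Hypergeometric feature test: %s\n", x$feature))
  cat(sprintf("  set: %d of %d peaks in feature; background: %d of %d\n",
              x$k, x$n, x$K, x$N_pop))
  cat(sprintf("  p(enrich) = %.4g, p(deplete) = %.4g\n", x$p_enrich,
              x$p_deplete))
  invisible(x)
}

#' Hypergeometric feature tests for all seven features
#'
#' @inheritParams hypergeom_feature_test
#' @return data.frame with one row per feature (k, n, K, N_pop, p_enrich,
#'   p_deplete).
#' @export
hypergeom_feature_tests <- function(set_dist, bg_dist) {
  rows <- lapply(.FEATURE_CLASSES, function(f) {
    h <- hypergeom_feature_test(set_dist, bg_dist, f)
    data.frame(feature = f, k = h$k, n = h$n, K = h$K, N_pop = h$N_pop,
               p_enrich = h$p_enrich, p_deplete = h$p_deplete,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bootstrap null distribution of gene-set peak counts
#'
#' Each trial samples `set_size` distinct genes uniformly without
#' replacement from the full gene universe and records the summed peak
#' count; trials are independent and driven by a single root seed, so an
#' identical seed reproduces the null exactly.
#'
#' @param assoc A [associate_peaks()] result.
#' @param set_size Number of genes drawn per trial.
#' @param B Number of trials (default 10000).
#' @param seed Integer seed for reproducibility.
#' @return Integer vector of `B` null counts.
#' @export
bootstrap_null <- function(assoc, set_size, B = 10000, seed = 1) {
  G <- assoc$n_genes
  if (set_size > G) stop("set_size exceeds the gene universe (", G, " genes)")
  if (B < 1) stop("B must be >= 1")
  counts <- assoc$counts
  with_seed(seed, {
    vapply(seq_len(B),
           function(i) sum(counts[sample.int(G, set_size)]),
           numeric(1))
  })
}

#' Tail probabilities for an observed gene-set peak count
#'
#' Combines a skew-normal fit of the bootstrap null with the observed count:
#' `p_high = 1 - F(observed)` and `p_low = F(observed)` under the fitted
#' CDF, plus empirical companions with add-one correction,
#' `p_high_emp = (1 + #{null >= observed}) / (B + 1)` (ties count toward
#' both tails).  For a degenerate null the fitted tails are `NA` and only
#' the empirical ones are reported.
#'
#' @param observed Observed summed peak count of the query gene set.
#' @param fit A `"skewnorm_fit"` from [fit_skew_normal()] (or `NULL` to fit
#'   here from `null_counts`).
#' @param null_counts Numeric vector of bootstrap null counts.
#' @return An object of class `"bootstrap_result"`: list with `observed`,
#'   `B`, `null_counts`, `fit`, `p_high`, `p_low`, `p_high_emp`, `p_low_emp`.
#' @export
bootstrap_p <- function(observed, fit = NULL, null_counts) {
  B <- length(null_counts)
  if (is.null(fit)) fit <- fit_skew_normal(null_counts)
  if (fit$degenerate) {
    p_high <- NA_real_
    p_low <- NA_real_
  } else {
    p_low <- pskewnorm(observed, fit$xi, fit$omega, fit$alpha)
    p_high <- 1 - p_low
  }
  structure(list(observed = observed, B = B, null_counts = null_counts,
                 fit = fit, p_high = p_high, p_low = p_low,
                 p_high_emp = (1 + sum(null_counts >= observed)) / (B + 1),
                 p_low_emp = (1 + sum(null_counts <= observed)) / (B + 1)),
            class = "bootstrap_result")
}

#' Bootstrap gene-set peak-count enrichment test
#'
#' Tests whether the number of peaks associated with a gene set is
#' significantly high or low compared to equally sized random gene groups:
#' the observed count is the summed per-gene peak count over the set; the
#' null repeatedly draws `|set|` genes at random from all annotated genes
#' and sums their counts; one-sided p-values come from a skew-normal fit to
#' the null histogram (both tails are always reported; no automatic
#' two-siding).
#'
#' @param assoc A [associate_peaks()] result.
#' @param set A [gene_set()]; ids absent from the universe are dropped with
#'   a warning and the trial size shrinks accordingly.
#' @param B Number of bootstrap trials (default 10000).
#' @param seed Integer seed.
#' @return A `"bootstrap_result"` (see [bootstrap_p()]) with additional
#'   elements `set_name`, `set_size`, `seed`.
#' @examples
#' genome <- generate_genome(n_genes = 50, seed = 1)
#' peaks <- generate_peaks(genome$annotation, n_peaks = 300, seed = 2)
#' ann <- classify_peaks(peaks$peaks, genome$annotation)
#' assoc <- associate_peaks(ann, genome$annotation)
#' qs <- gene_set("query", genome$annotation$genes$gene_id[1:10])
#' bootstrap_enrichment(assoc, qs, B = 200, seed = 3)
#' @export
bootstrap_enrichment <- function(assoc, set, B = 10000, seed = 1) {
  ids <- intersect(set$gene_ids, names(assoc$counts))
  dropped <- length(set$gene_ids) - length(ids)
  if (dropped > 0) {
    warning(sprintf("gene set '%s': %d id(s) not in the annotation universe dropped",
                    set$name, dropped))
  }
  if (length(ids) == 0) stop("no gene of the set is in the annotation universe")
  observed <- sum(assoc$counts[ids])
  null_counts <- bootstrap_null(assoc, set_size = length(ids), B = B,
                                seed = seed)
  fit <- if (length(null_counts) < 10 || stats::var(null_counts) == 0) {
    structure(list(xi = NA_real_, omega = NA_real_, alpha = NA_real_,
                   loglik = NA_real_, n = length(null_counts),
                   model = NA_character_, degenerate = TRUE,
                   converged = FALSE, init = NULL),
              class = "skewnorm_fit")
  } else {
    fit_skew_normal(null_counts)
  }
  res <- bootstrap_p(observed, fit, null_counts)
  res$set_name <- set$name
  res$set_size <- length(ids)
  res$seed <- seed
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap gene-set peak-count enrichment\n")
  if (!is.null(x$set_name)) {
    cat(sprintf("  set '%s' (%d genes)\n", x$set_name, x$set_size))
  }
  cat(sprintf("  observed peaks = %g; null: B = %d, mean = %.2f, sd = %.2f\n",
              x$observed, x$B, mean(x$null_counts), stats::sd(x$null_counts)))
  if (x$fit$degenerate) {
    cat("  degenerate null (zero variance); fitted tails unavailable\n")
  } else {
    cat(sprintf("  skew-normal fit: xi = %.2f, omega = %.2f, alpha = %.2f\n",
                x$fit$xi, x$fit$omega, x$fit$alpha))
    cat(sprintf("  fitted   p(high) = %.4g, p(low) = %.4g\n", x$p_high, x$p_low))
  }
  cat(sprintf("  empirical p(high) = %.4g, p(low) = %.4g\n", x$p_high_emp,
              x$p_low_emp))
  invisible(x)
}
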