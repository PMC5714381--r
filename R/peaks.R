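# Peak files, cross-sample overlap (Venn) tables and pileup comparisons.

#' Construct a peak set
#'
#' @param sample_id Non-empty sample label (e.g. cell line + factor).
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `summit` (0-based, `start <= summit < end`) and optionally
#'   `name`, `score`, `pileup` (>= 0).
#' @return An object of class `"peak_set"`: list with `sample_id` and the
#'   validated `peaks` data.frame sorted by (chrom, start).
#' @export
peak_set <- function(sample_id, peaks) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("'sample_id' must be a non-empty string")
  }
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "summit")
  if (!all(req %in% names(peaks))) {
    stop("'peaks' must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(peaks$name)) peaks$name <- sprintf("peak_%06d", seq_len(nrow(peaks)))
  if (is.null(peaks$score)) peaks$score <- 0
  if (is.null(peaks$pileup)) peaks$pileup <- 0
  if (any(peaks$start < 0 | peaks$start >= peaks$end)) {
    stop("invalid peak interval (need 0 <= start < end)")
  }
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
    stop("summit must satisfy start <= summit < end")
  }
  if (any(peaks$pileup < 0)) stop("pileup must be >= 0")
  o <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[o, c("chrom", "start", "end", "name", "score", "summit",
                      "pileup"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sample_id = sample_id, peaks = peaks), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s': %d peaks on %d chromosome(s)\n", x$sample_id,
              nrow(x$peaks), length(unique(x$peaks$chrom))))
  invisible(x)
}

#' Read peaks from a narrowPeak or BED file
#'
#' Ten-column ENCODE narrowPeak files carry the summit as an offset in
#' column 10 (`-1` falls back to the interval midpoint) and the signalValue
#' (column 7) is stored as the pileup.  Plain BED (3-9 columns) uses the
#' interval midpoint as summit and pileup 0.
#'
#' @param path Input file; track/browser/comment lines are skipped.
#' @param sample_id Sample label for the resulting set.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("no peak records in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("line %d: expected >= 3 tab-separated fields", idx[which(nf < 3)[1]]))
  }
  get_col <- function(j, default = NA) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else as.character(default),
           character(1))
  }
  chrom <- get_col(1)
  start <- as.numeric(get_col(2))
  end <- as.numeric(get_col(3))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("line %d: non-numeric coordinates",
                 idx[which(is.na(start) | is.na(end))[1]]))
  }
  bad <- which(start >= end)
  if (length(bad)) stop(sprintf("line %d: start >= end", idx[bad[1]]))
  name <- get_col(4, default = "")
  name[!nzchar(name) | is.na(name)] <-
    sprintf("peak_%06d", which(!nzchar(name) | is.na(name)))
  score <- suppressWarnings(as.numeric(get_col(5, default = "0")))
  score[is.na(score)] <- 0
  mid <- floor((start + end) / 2)
  if (all(nf >= 10)) {
    pileup <- suppressWarnings(as.numeric(get_col(7, default = "0")))
    pileup[is.na(pileup)] <- 0
    off <- suppressWarnings(as.numeric(get_col(10)))
    if (anyNA(off)) stop(sprintf("line %d: non-numeric summit offset",
                                 idx[which(is.na(off))[1]]))
    too_big <- which(off >= end - start)
    if (length(too_big)) {
      stop(sprintf("line %d: summit offset %d >= peak length %d",
                   idx[too_big[1]], off[too_big[1]],
                   (end - start)[too_big[1]]))
    }
    summit <- ifelse(off < 0, mid, start + off)
  } else {
    pileup <- rep(0, length(start))
    summit <- mid
  }
  peak_set(sample_id, data.frame(chrom = chrom, start = start, end = end,
                                 name = name, score = score, summit = summit,
                                 pileup = pileup, stringsAsFactors = FALSE))
}

#' Write a peak set in narrowPeak format
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(x, path) {
  p <- x$peaks
  fmt_num <- function(v) {
    ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
           sub("0+$", "", sprintf("%.10f", v)))
  }
  out <- paste(p$chrom, as.integer(p$start), as.integer(p$end), p$name,
               fmt_num(p$score), ".", fmt_num(p$pileup), "-1", "-1",
               as.integer(p$summit - p$start), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Cross-sample peak overlap (Venn) table
#'
#' Merges the peaks of all samples by single-linkage closure: two peaks are
#' linked if their intervals intersect or are separated by a gap of less
#' than `max_gap` bp.  Each merged region contributes to exactly one Venn
#' cell, keyed by the set of samples with at least one peak in the region.
#'
#' @param peak_sets List of two or more [peak_set()] objects.
#' @param max_gap Maximum gap in bp; peaks strictly closer than this merge
#'   (default 1000).
#' @return An object of class `"overlap_table"`: list with `sample_ids`,
#'   `max_gap`, `cells` (data.frame membership/n_samples/count), `n_regions`
#'   and `frac_common` (fraction of regions shared by all samples).
#' @export
cluster_overlapping <- function(peak_sets, max_gap = 1000) {
  if (length(peak_sets) < 2) stop("need at least two peak sets")
  ids <- vapply(peak_sets, function(s) s$sample_id, character(1))
  empty <- vapply(peak_sets, function(s) nrow(s$peaks) == 0, logical(1))
  if (any(empty)) stop("empty peak set: ", paste(ids[empty], collapse = ", "))
  grs <- lapply(peak_sets, function(s) gr0(s$peaks$chrom, s$peaks$start,
                                           s$peaks$end))
  all_gr <- do.call(c, grs)
  sample_of <- rep(ids, vapply(grs, length, integer(1)))
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = max_gap)
  # every peak lies inside exactly one merged region
  direct <- GenomicRanges::findOverlaps(all_gr, merged)
  region_of <- S4Vectors::subjectHits(direct)
  membership <- vapply(split(sample_of, region_of), function(s) {
    paste(sort(unique(s)), collapse = "&")
  }, character(1))
  tab <- table(membership)
  cells <- data.frame(membership = names(tab),
                      n_samples = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                      count = as.integer(tab), row.names = NULL,
                      stringsAsFactors = FALSE)
  cells <- cells[order(-cells$n_samples, cells$membership), , drop = FALSE]
  rownames(cells) <- NULL
  n_regions <- length(merged)
  all_key <- paste(sort(ids), collapse = "&")
  n_common <- if (all_key %in% cells$membership) {
    cells$count[cells$membership == all_key]
  } else 0L
  structure(list(sample_ids = ids, max_gap = max_gap, cells = cells,
                 n_regions = n_regions, frac_common = n_common / n_regions),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("Peak overlap table (%d samples, max gap %d bp): %d merged regions\n",
              length(x$sample_ids), x$max_gap, x$n_regions))
  cat(sprintf("  common to all samples: %.1f%%\n", 100 * x$frac_common))
  print(x$cells, ...)
  invisible(x)
}

#' Write an overlap table as TSV (and optionally JSON)
#'
#' @param x An `"overlap_table"`.
#' @param path TSV output path.
#' @param json_path Optional JSON output path.
#' @return Invisibly, `path`.
#' @export
write_overlap_table <- function(x, path, json_path = NULL) {
  utils::write.table(x$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(sample_ids = x$sample_ids, max_gap = x$max_gap,
                              n_regions = x$n_regions,
                              frac_common = x$frac_common, cells = x$cells),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Compare pileup values between two peak groups
#'
#' Two-sample Wilcoxon rank-sum comparison of peak pileup values (or any
#' numeric summaries), reporting medians, interquartile ranges, the rank-sum
#' statistic and two-sided plus one-sided (group A greater) p-values.  Small
#' untied samples are tested exactly; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param group_a,group_b Numeric vectors, or [peak_set()] objects /
#'   data.frames with a `pileup` column.
#' @return An object of class `"rank_test_result"`.
#' @export
pileup_rank_test <- function(group_a, group_b) {
  pull <- function(g) {
    if (inherits(g, "peak_set")) return(g$peaks$pileup)
    if (is.data.frame(g)) {
      if (!"pileup" %in% names(g)) stop("data.frame input needs a 'pileup' column")
      return(g$pileup)
    }
    as.numeric(g)
  }
  a <- pull(group_a)
  b <- pull(group_b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  res <- list(n_a = length(a), n_b = length(b),
              median_a = stats::median(a), median_b = stats::median(b),
              iqr_a = stats::IQR(a), iqr_b = stats::IQR(b))
  if (stats::var(c(a, b)) == 0) {
    res <- c(res, list(statistic = length(a) * length(b) / 2,
                       p_two_sided = 1, p_greater = 1, degenerate = TRUE))
  } else {
    two <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    gt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater"))
    res <- c(res, list(statistic = unname(two$statistic),
                       p_two_sided = two$p.value, p_greater = gt$p.value,
                       degenerate = FALSE))
  }
  structure(res, class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat("Wilcoxon rank-sum comparison of pileup values\n")
  cat(sprintf("  group A: n = %d, median = %.3f, IQR = %.3f\n", x$n_a,
              x$median_a, x$iqr_a))
  cat(sprintf("  group B: n = %d, median = %.3f, IQR = %.3f\n", x$n_b,
              x$median_b, x$iqr_b))
  if (x$degenerate) cat("  degenerate: all values identical\n")
  cat(sprintf("  W = %.1f, two-sided p = %.4g, one-sided (A > B) p = %.4g\n",
              x$statistic, x$p_two_sided, x$p_greater))
  invisible(x)
}
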