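# Fixed-bin chromatin-state segmentations: reading, summit-bin state
# assignment and state-abundance profiles of peak subsets.
#
# The genome is discretized into bins of `bin_size` bp (200 bp by default);
# each bin carries the most likely state of a multivariate HMM segmentation
# (hard labels; posterior files are upstream and out of scope).  Bins not
# covered by any record carry the sentinel state "unannotated".

#' Construct a chromatin segmentation
#'
#' @param bins Named list (per chromosome) of integer vectors; each element
#'   codes the state of one bin as an index into `states`, 0 meaning
#'   unannotated.
#' @param states Character vocabulary of state labels (default the Roadmap
#'   15-state set, [roadmap_states()]).
#' @param bin_size Bin width in bp (default 200).
#' @return An object of class `"chromatin_segmentation"`.
#' @export
chromatin_segmentation <- function(bins, states = roadmap_states(),
                                   bin_size = 200) {
  assert_scalar_number(bin_size, "bin_size", positive = TRUE)
  if (!is.list(bins) || is.null(names(bins)) || any(!nzchar(names(bins)))) {
    stop("'bins' must be a named list of per-chromosome state-code vectors")
  }
  if (anyDuplicated(states)) stop("duplicate state labels")
  for (ch in names(bins)) {
    codes <- bins[[ch]]
    if (any(codes < 0 | codes > length(states))) {
      stop("state codes on ", ch, " outside 0..", length(states))
    }
    bins[[ch]] <- as.integer(codes)
  }
  structure(list(bins = bins, states = states,
                 bin_size = as.integer(bin_size)),
            class = "chromatin_segmentation")
}

#' @export
print.chromatin_segmentation <- function(x, ...) {
  nb <- sum(lengths(x$bins))
  cat(sprintf("Chromatin segmentation: %d chromosome(s), %d bins of %d bp, %d-state vocabulary\n",
              length(x$bins), nb, x$bin_size, length(x$states)))
  cat(sprintf("  unannotated bins: %d\n", sum(unlist(x$bins) == 0L)))
  invisible(x)
}

#' Read a chromatin-state segmentation from 4-column BED
#'
#' Each record is `chrom start end state` with start/end on the fixed
#' `bin_size` grid.  Several files covering disjoint regions may be given;
#' overlapping records are an error.
#'
#' @param paths One or more BED file paths.
#' @param bin_size Grid size in bp (default 200).
#' @param states State vocabulary; labels in the files outside it are an
#'   error.  Pass `NULL` to take the sorted set of labels found.
#' @return A [chromatin_segmentation()].
#' @export
read_segmentation <- function(paths, bin_size = 200, states = roadmap_states()) {
  recs <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0) next
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4)) {
      stop(sprintf("%s line %d: expected >= 4 tab-separated fields", path,
                   idx[which(nf < 4)[1]]))
    }
    chrom <- vapply(fields, `[`, character(1), 1)
    start <- as.numeric(vapply(fields, `[`, character(1), 2))
    end <- as.numeric(vapply(fields, `[`, character(1), 3))
    lab <- vapply(fields, `[`, character(1), 4)
    if (anyNA(start) || anyNA(end)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path,
                   idx[which(is.na(start) | is.na(end))[1]]))
    }
    off <- which(start %% bin_size != 0 | end %% bin_size != 0 | start >= end)
    if (length(off)) {
      stop(sprintf("%s line %d: record [%d, %d) off the %d bp grid", path,
                   idx[off[1]], start[off[1]], end[off[1]], bin_size))
    }
    recs[[length(recs) + 1L]] <- data.frame(chrom = chrom, start = start,
                                            end = end, state = lab,
                                            stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) stop("no segmentation records found")
  recs <- do.call(rbind, recs)
  if (is.null(states)) states <- sort(unique(recs$state))
  unknown <- setdiff(unique(recs$state), states)
  if (length(unknown)) {
    stop("state labels outside the vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  code <- match(recs$state, states)
  bins <- list()
  for (ch in unique(recs$chrom)) {
    sel <- recs$chrom == ch
    n_bins <- max(recs$end[sel]) / bin_size
    v <- integer(n_bins)
    s_bin <- recs$start[sel] / bin_size + 1
    e_bin <- recs$end[sel] / bin_size
    idxs <- unlist(Map(seq.int, s_bin, e_bin))
    if (anyDuplicated(idxs)) {
      stop("overlapping segmentation records on ", ch)
    }
    v[idxs] <- rep(code[sel], e_bin - s_bin + 1)
    bins[[ch]] <- v
  }
  chromatin_segmentation(bins, states = states, bin_size = bin_size)
}

#' Write a segmentation as 4-column BED
#'
#' Runs of equal states are merged into single records; unannotated bins
#' are omitted.
#'
#' @param seg A [chromatin_segmentation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segmentation <- function(seg, path) {
  out <- character(0)
  for (ch in names(seg$bins)) {
    r <- rle(seg$bins[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0L
    if (!any(keep)) next
    out <- c(out, sprintf("%s\t%d\t%d\t%s", ch,
                          as.integer(starts[keep] * seg$bin_size),
                          as.integer(ends[keep] * seg$bin_size),
                          seg$states[r$values[keep]]))
  }
  writeLines(out, path)
  invisible(path)
}

# vectorized summit -> state lookup
assign_states_at <- function(chrom, summit, seg) {
  out <- character(length(summit))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    v <- seg$bins[[ch]]
    if (is.null(v)) stop("chromosome absent from segmentation: ", ch)
    bin <- summit[sel] %/% seg$bin_size + 1
    code <- ifelse(bin >= 1 & bin <= length(v), v[pmin(pmax(bin, 1), length(v))], 0L)
    out[sel] <- ifelse(code == 0L, .UNANNOTATED, seg$states[pmax(code, 1L)])
  }
  out
}

#' State of the bin containing a peak summit
#'
#' The summit at 0-based position `s` falls into bin `floor(s / bin_size)`;
#' the peak is assigned that bin's state.  Summits past the annotated
#' extent yield `"unannotated"`.
#'
#' @param peak A one-row data.frame/list with `chrom` and `summit`, or a
#'   [peak_set()] (all peaks assigned).
#' @param seg A [chromatin_segmentation()].
#' @return Character vector of state labels.
#' @export
assign_state <- function(peak, seg) {
  df <- if (inherits(peak, "peak_set")) peak$peaks else as.data.frame(peak)
  assign_states_at(df$chrom, df$summit, seg)
}

#' Chromatin-state abundance profile of a peak subset
#'
#' Counts peak summits per chromatin state, optionally after restricting to
#' one genomic feature (e.g. distal intergenic peaks) and/or to peaks
#' assigned to a gene set, and reports relative abundance in percent.
#' Unannotated summits are excluded from the denominator unless
#' `include_unannotated = TRUE`.
#'
#' @param annotated An `"annotated_peaks"` data.frame from [classify_peaks()].
#' @param seg A [chromatin_segmentation()].
#' @param feature_filter Optional feature label from [feature_classes()].
#' @param gene_set Optional [gene_set()] restriction on assigned genes.
#' @param include_unannotated Keep unannotated summits in the profile?
#' @return An object of class `"state_profile"`: data.frame `profile`
#'   (state, count, percent, ordered by the vocabulary), `n_peaks`, and
#'   `states_represented`.
#' @export
state_abundance <- function(annotated, seg, feature_filter = NULL,
                            gene_set = NULL, include_unannotated = FALSE) {
  if (!is.null(feature_filter)) {
    feature_filter <- match.arg(feature_filter, .FEATURE_CLASSES)
    annotated <- annotated[annotated$feature == feature_filter, , drop = FALSE]
    if (nrow(annotated) == 0) {
      stop("feature filter '", feature_filter, "' removed all peaks")
    }
  }
  if (!is.null(gene_set)) {
    annotated <- annotated[annotated$gene_id %in% gene_set$gene_ids, , drop = FALSE]
    if (nrow(annotated) == 0) {
      stop("gene-set filter '", gene_set$name, "' removed all peaks")
    }
  }
  st <- assign_states_at(annotated$chrom, annotated$summit, seg)
  levels <- seg$states
  if (include_unannotated) levels <- c(levels, .UNANNOTATED)
  st <- st[st %in% levels]
  if (length(st) == 0) {
    stop("all remaining summits are unannotated; set include_unannotated = TRUE")
  }
  counts <- table(factor(st, levels = levels))
  n <- sum(counts)
  profile <- data.frame(state = levels, count = as.integer(counts),
                        percent = 100 * as.integer(counts) / n,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(profile = profile, n_peaks = n,
                 states_represented = sum(counts > 0)),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf("Chromatin-state profile of %d peaks (%d states represented)\n",
              x$n_peaks, x$states_represented))
  df <- x$profile[x$profile$count > 0, , drop = FALSE]
  df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Write a state profile as TSV
#'
#' @param x A `"state_profile"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_state_profile <- function(x, path) {
  utils::write.table(x$profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
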