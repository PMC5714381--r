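# shared constants and small helpers

.FEATURE_CLASSES <- c("Promoter", "FivePrimeUTR", "ThreePrimeUTR", "Exon",
                      "Intron", "Downstream", "DistalIntergenic")

.ROADMAP15 <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
                "ZNF/Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC",
                "ReprPCWk", "Quies")

.UNANNOTATED <- "unannotated"

#' The seven genomic feature classes
#'
#' Peak summits are classified into exactly one of seven genomic features:
#' promoter (a window around the TSS), 5' UTR, 3' UTR, exon, intron,
#' downstream (a window past the gene end in gene orientation), and distal
#' intergenic.  The order returned here is also the precedence order used to
#' resolve overlaps during classification.
#'
#' @return Character vector of the seven feature labels, in precedence order.
#' @export
feature_classes <- function() .FEATURE_CLASSES

#' The default 15-state chromatin vocabulary
#'
#' State labels of the Roadmap Epigenomics consolidated 15-state model
#' (core 5-mark ChromHMM segmentation), ordered from active TSS states to
#' quiescent chromatin.
#'
#' @return Character vector of 15 state labels.
#' @export
roadmap_states <- function() .ROADMAP15

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this, so they are pure
# functions of their parameters (seed included).
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# 0-based half-open intervals -> GRanges (1-based closed).
gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

# single 0-based positions -> width-1 GRanges
points_gr0 <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
}

# strict scalar checks used by constructors
assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
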