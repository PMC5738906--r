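# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based
# half-open [start, end), the BED convention. Conversions to the 1-based
# closed convention happen only at file boundaries (GTF) and when building
# IRanges/GRanges objects for interval arithmetic.

# log2 with pseudocount; default matches the co-expression module.
log2p <- function(x, pseudocount = 0.1) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)
  log2(x + pseudocount)
}

# 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

peaks_to_granges <- function(peaks) {
  intervals_to_granges(peaks$chrom, peaks$start, peaks$end)
}

# TSS points (0-based positions) -> width-1 GRanges.
points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
}

# Minimal gap (bp) from each query interval to the nearest subject
# interval/point; 0 when overlapping, Inf when no subject shares the
# chromosome. Matches GenomicRanges::distance semantics.
min_gap_to_nearest <- function(query_gr, subject_gr) {
  out <- rep(Inf, length(query_gr))
  if (length(subject_gr) == 0L || length(query_gr) == 0L) return(out)
  hits <- GenomicRanges::distanceToNearest(query_gr, subject_gr, ignore.strand = TRUE)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

# Deterministic sub-seed derivation; keeps values in [0, 2^31 - 2].
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 1000003 * k) %% (.Machine$integer.max - 1))
}

# Run an expression with a locally-set RNG seed, restoring RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Canonical number formatting used by all writers so that read -> write
# round-trips are byte-identical for canonical inputs.
format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
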