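#' Promoter windows around transcription start sites
#'
#' Symmetric windows of +/- `flank` bp around each gene's TSS, clipped at
#' the chromosome start. The extent is strand-independent (the +/- notation
#' refers to both sides of the TSS), so only the center depends on strand
#' via the TSS definition.
#'
#' @param models A `gene_models` object.
#' @param flank Half-width in bp (default 2000).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `tss`,
#'   `strand` (0-based half-open windows).
#' @export
promoter_windows <- function(models, flank = 2000) {
  stopifnot(flank > 0)
  g <- models$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(g$tss - flank, 0), end = g$tss + flank,
             tss = g$tss, strand = g$strand, stringsAsFactors = FALSE)
}

#' Call promoter-bound genes from TF peaks
#'
#' A gene is bound when at least one base of its promoter window overlaps
#' any peak (half-open semantics: a peak starting exactly at the window end
#' shares no base and does not count).
#'
#' @param windows Output of [promoter_windows()].
#' @param tf_peaks A `peak_set` of TF binding peaks.
#' @return data.frame with `gene_id`, `bound` (logical), `n_peaks`.
#' @export
call_bound_genes <- function(windows, tf_peaks) {
  n_peaks <- integer(nrow(windows))
  if (nrow(tf_peaks) && nrow(windows)) {
    wg <- intervals_to_granges(windows$chrom, windows$start, windows$end)
    pg <- peaks_to_granges(tf_peaks)
    hits <- GenomicRanges::findOverlaps(wg, pg, minoverlap = 1L)
    tab <- table(S4Vectors::queryHits(hits))
    n_peaks[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(gene_id = windows$gene_id, bound = n_peaks > 0,
             n_peaks = n_peaks, stringsAsFactors = FALSE)
}

#' Summarize promoter binding over a gene list
#'
#' @param bound Output of [call_bound_genes()].
#' @param gene_ids Gene list to summarize over.
#' @return List with `gene_ids` (bound subset), `count`, `fraction`.
#' @export
summarize_bound <- function(bound, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  b <- intersect(gene_ids, bound$gene_id[bound$bound])
  list(gene_ids = sort(b), count = length(b),
       fraction = if (length(gene_ids)) length(b) / length(gene_ids)
                  else NA_real_)
}

#' Retain peaks with strong binding intensity
#'
#' Keeps the peaks whose intensity is strictly above the `q`-quantile of
#' all peak intensities, computed with linear interpolation of the
#' empirical distribution (R quantile type 7). With `strict = FALSE` the
#' comparison is `>=`.
#'
#' @param peaks A `peak_set` with intensities in `score`.
#' @param q Quantile level in \[0, 1\] (default 0.25).
#' @param strict Use strict `>` (default) or `>=`.
#' @return The retained subset, a `peak_set`.
#' @export
strong_peaks <- function(peaks, q = 0.25, strict = TRUE) {
  stopifnot(q >= 0, q <= 1)
  if (!nrow(peaks)) return(peaks)
  if (all(is.na(peaks$score))) stop("all peak intensities missing")
  cut <- stats::quantile(peaks$score, q, na.rm = TRUE, names = FALSE, type = 7)
  keep <- if (strict) peaks$score > cut else peaks$score >= cut
  keep[is.na(keep)] <- FALSE
  peak_set(as.data.frame(peaks)[keep, , drop = FALSE],
           mark = attr(peaks, "mark"), tissue = attr(peaks, "tissue"))
}

#' Aggregate TSS-centered binding profile
#'
#' Average peak-occupancy profile around a set of TSSs: for each gene, each
#' base in `[tss - half_window, tss + half_window)` gets an indicator of
#' overlap with any peak; bases are averaged within `bin`-bp bins and the
#' per-gene bin vectors are averaged across genes. Profiles of `-` strand
#' genes are flipped so bins always run 5' to 3'.
#'
#' @param peaks A `peak_set`.
#' @param tss data.frame with `chrom`, `tss`, `strand`.
#' @param half_window Half-width in bp (default 2000).
#' @param bin Bin width in bp; must divide `2 * half_window`.
#' @return Numeric vector of per-bin mean occupancy, named by the bin start
#'   offset relative to the TSS (5'->3').
#' @export
tss_profile <- function(peaks, tss, half_window = 2000, bin = 50) {
  stopifnot(nrow(tss) >= 1L, bin >= 1, (2 * half_window) %% bin == 0)
  nbins <- as.integer(2 * half_window / bin)
  acc <- numeric(nbins)
  for (i in seq_len(nrow(tss))) {
    w_start <- tss$tss[i] - half_window
    pk <- peaks[peaks$chrom == tss$chrom[i] &
                  peaks$end > w_start &
                  peaks$start < w_start + 2 * half_window, , drop = FALSE]
    cov <- numeric(nbins)
    if (nrow(pk)) {
      # covered fraction of each bin, by interval intersection
      bin_starts <- w_start + (seq_len(nbins) - 1L) * bin
      for (j in seq_len(nrow(pk))) {
        lo <- pmax(bin_starts, pk$start[j])
        hi <- pmin(bin_starts + bin, pk$end[j])
        cov <- pmax(cov, pmax(hi - lo, 0) / bin)
      }
      # overlapping peaks: indicator is union coverage; recompute exactly
      if (nrow(pk) > 1L) {
        covered <- rep(FALSE, 2 * half_window)
        for (j in seq_len(nrow(pk))) {
          lo <- max(pk$start[j] - w_start, 0)
          hi <- min(pk$end[j] - w_start, 2 * half_window)
          if (hi > lo) covered[(lo + 1):hi] <- TRUE
        }
        cov <- colMeans(matrix(covered, nrow = bin))
      }
    }
    if (tss$strand[i] == "-") cov <- rev(cov)
    acc <- acc + cov
  }
  prof <- acc / nrow(tss)
  names(prof) <- seq(-half_window, half_window - bin, by = bin)
  prof
}
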