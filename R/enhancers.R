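#' Classify distal active-enhancer peaks
#'
#' Retains each H3K27ac peak whose minimal gap to every transcription start
#' site and to every H3K4me3 (active-promoter) peak is strictly greater than
#' `tss_min_dist` (default 3000 bp; a peak overlapping either has gap 0 and
#' is removed). This is the operational definition of an active enhancer:
#' H3K27ac signal away from active promoters.
#'
#' @param h3k27ac A `peak_set` of H3K27ac peaks.
#' @param tss data.frame with columns `chrom`, `tss` (0-based TSS
#'   positions), e.g. `models$genes`.
#' @param h3k4me3 A `peak_set` of H3K4me3 peaks (may have zero rows).
#' @param tss_min_dist Minimum gap in bp (strict inequality).
#' @return The retained peaks as a `peak_set`.
#' @export
classify_active_enhancers <- function(h3k27ac, tss, h3k4me3,
                                      tss_min_dist = 3000) {
  stopifnot(tss_min_dist >= 0)
  if (!nrow(h3k27ac)) return(h3k27ac)
  q <- peaks_to_granges(h3k27ac)
  gap_tss <- min_gap_to_nearest(q, points_to_granges(tss$chrom, tss$tss))
  gap_k4 <- if (nrow(h3k4me3)) min_gap_to_nearest(q, peaks_to_granges(h3k4me3))
            else rep(Inf, nrow(h3k27ac))
  keep <- gap_tss > tss_min_dist & gap_k4 > tss_min_dist
  peak_set(as.data.frame(h3k27ac)[keep, , drop = FALSE],
           mark = attr(h3k27ac, "mark"), tissue = attr(h3k27ac, "tissue"))
}

#' Merge nearby enhancer peaks
#'
#' Merges peaks whose gap is at most `merge_gap` bp (inclusive,
#' transitively), so a merged enhancer spans from the minimum start to the
#' maximum end of its constituent peaks. Source peak names are preserved as
#' comma-joined provenance.
#'
#' @param peaks A `peak_set` (typically the output of
#'   [classify_active_enhancers()]).
#' @param merge_gap Maximum gap merged across (default 1000 bp).
#' @return An `enhancer_set`: data.frame `chrom`, `start`, `end`, `name`,
#'   `n_peaks`, `source_peaks`, with attribute `tissue`.
#' @export
merge_enhancers <- function(peaks, merge_gap = 1000) {
  stopifnot(merge_gap >= 0)
  tissue <- attr(peaks, "tissue") %||% "unknown"
  if (!nrow(peaks)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), n_peaks = integer(),
                      source_peaks = character())
    return(structure(out, tissue = tissue,
                     class = c("enhancer_set", "data.frame")))
  }
  gr <- peaks_to_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE)
  out$n_peaks <- lengths(revmap)
  out$source_peaks <- vapply(revmap, function(i)
    paste(sort(peaks$name[i]), collapse = ","), character(1))
  out <- out[order(out$chrom, out$start, out$end), ]
  out$name <- sprintf("%s_enh%d", tissue, seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("chrom", "start", "end", "name", "n_peaks", "source_peaks")]
  structure(out, tissue = tissue, class = c("enhancer_set", "data.frame"))
}

#' Tissue-unique enhancers
#'
#' Retains the target tissue's enhancers that have zero base-pair overlap
#' with every other tissue's enhancer set ("only detected in the target
#' tissue"). All sets should have been built with identical parameters.
#'
#' @param target An `enhancer_set`.
#' @param others List of `enhancer_set` objects from the other tissues (an
#'   empty list returns `target` unchanged).
#' @return The unique subset of `target`, same class.
#' @export
tissue_unique <- function(target, others) {
  if (!length(others) || !nrow(target)) return(target)
  tg <- intervals_to_granges(target$chrom, target$start, target$end)
  keep <- rep(TRUE, nrow(target))
  for (o in others) {
    if (!nrow(o)) next
    og <- intervals_to_granges(o$chrom, o$start, o$end)
    hits <- GenomicRanges::findOverlaps(tg, og, minoverlap = 1L)
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  out <- target[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, tissue = attr(target, "tissue"),
            class = c("enhancer_set", "data.frame"))
}

#' Associate enhancers with genes by regulatory domain
#'
#' Links an enhancer to every protein-coding gene whose basal-plus-extension
#' regulatory domain (see [regulatory_domains()]) contains the enhancer
#' midpoint.
#'
#' @param enhancers An `enhancer_set`.
#' @param models A `gene_models` object.
#' @inheritParams regulatory_domains
#' @return data.frame with `enhancer`, `gene_id`, `distance` (signed,
#'   strand-oriented midpoint-to-TSS distance).
#' @export
associate_enhancers_to_genes <- function(enhancers, models, basal_up = 5000,
                                         basal_down = 1000,
                                         max_extension = 1e6) {
  dom <- regulatory_domains(models, basal_up, basal_down, max_extension)
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    mid <- floor((enhancers$start[i] + enhancers$end[i]) / 2)
    hit <- dom[dom$chrom == enhancers$chrom[i] & dom$domain_start <= mid &
                 mid < dom$domain_end, , drop = FALSE]
    if (nrow(hit)) {
      d <- ifelse(hit$strand == "+", mid - hit$tss, hit$tss - mid)
      out[[length(out) + 1L]] <- data.frame(
        enhancer = enhancers$name[i], gene_id = hit$gene_id, distance = d,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(enhancer = character(), gene_id = character(),
               distance = numeric())
  rownames(res) <- NULL
  res
}

#' Count genes flanked by at least one associated enhancer
#'
#' @param gene_ids Gene list to summarize over (e.g. the tissue-selective
#'   genes).
#' @param associations Output of [associate_enhancers_to_genes()].
#' @return List with `gene_ids` (flanked subset), `count`, `fraction`.
#' @export
genes_with_enhancers <- function(gene_ids, associations) {
  gene_ids <- unique(as.character(gene_ids))
  flanked <- intersect(gene_ids, unique(associations$gene_id))
  list(gene_ids = sort(flanked), count = length(flanked),
       fraction = if (length(gene_ids)) length(flanked) / length(gene_ids)
                  else NA_real_)
}
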