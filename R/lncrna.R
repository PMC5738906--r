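#' Flag sense-strand exonic overlap with expressed coding genes
#'
#' TRUE when at least one base of any exon of the lncRNA overlaps an exon of
#' a protein-coding gene on the same strand whose id is in `expressed_ids`
#' (typically: mean FPKM >= 1 in at least one tissue). Antisense overlap is
#' exempt, as is overlap with non-expressed coding genes.
#'
#' @param lnc_id A lncRNA gene id present in `models`.
#' @param models A `gene_models` object holding the lncRNA and the coding
#'   genes.
#' @param expressed_ids Character vector of expressed protein-coding gene
#'   ids.
#' @return Logical scalar.
#' @export
flag_sense_exonic_overlap <- function(lnc_id, models, expressed_ids) {
  g <- models$genes
  li <- match(lnc_id, g$gene_id)
  if (is.na(li)) stop("unknown lncRNA id: ", lnc_id)
  cod <- g[g$biotype == "protein_coding" &
             g$gene_id %in% expressed_ids &
             g$strand == g$strand[li] &
             g$chrom == g$chrom[li], , drop = FALSE]
  if (!nrow(cod)) return(FALSE)
  le <- models$exons[[lnc_id]]
  for (cid in cod$gene_id) {
    ce <- models$exons[[cid]]
    for (i in seq_len(nrow(le))) {
      if (any(pmin(le[i, 2L], ce[, 2L]) > pmax(le[i, 1L], ce[, 1L])))
        return(TRUE)
    }
  }
  FALSE
}

#' Flag intron embedding and host-intron retention
#'
#' A lncRNA is intron-embedded when its whole gene span lies inside a single
#' intron of a protein-coding gene. Whether that intron is retained in
#' mature host transcripts is looked up in `retention`, a data.frame with
#' columns `gene_id`, `intron_index` (1-based, in genomic order) and
#' `retained` (logical). A missing entry for an embedding intron is treated
#' as not retained, with a warning.
#'
#' @inheritParams flag_sense_exonic_overlap
#' @param retention Retention table (may be `NULL`: nothing retained).
#' @return List with logical scalars `intron_embedded` and
#'   `host_intron_retained`.
#' @export
flag_intronic_retained <- function(lnc_id, models, retention = NULL) {
  g <- models$genes
  li <- match(lnc_id, g$gene_id)
  if (is.na(li)) stop("unknown lncRNA id: ", lnc_id)
  span <- c(g$start[li], g$end[li])
  cod <- g[g$biotype == "protein_coding" & g$chrom == g$chrom[li], , drop = FALSE]
  embedded <- FALSE; retained <- FALSE
  for (cid in cod$gene_id) {
    ci <- models$introns[[cid]]
    if (!nrow(ci)) next
    hit <- which(ci[, 1L] <= span[1L] & span[2L] <= ci[, 2L])
    for (k in hit) {
      embedded <- TRUE
      if (is.null(retention)) next
      row <- retention$gene_id == cid & retention$intron_index == k
      if (!any(row)) {
        warning(sprintf("no retention entry for %s intron %d; treated as not retained",
                        cid, k))
      } else if (any(retention$retained[row])) {
        retained <- TRUE
      }
    }
  }
  list(intron_embedded = embedded, host_intron_retained = retained)
}

#' Apply the lncRNA exclusion filters
#'
#' Excludes a lncRNA when it has sense-strand exonic overlap with an
#' expressed protein-coding gene, or when it is embedded in a coding-gene
#' intron that shows intron retention. These are the false-positive guards
#' applied on top of the selectivity call before reporting tissue-selective
#' lncRNAs.
#'
#' @param lnc_ids Character vector of lncRNA gene ids to assess.
#' @inheritParams flag_intronic_retained
#' @param expressed_ids Expressed protein-coding gene ids.
#' @return data.frame with columns `gene_id`, `sense_exonic_overlap`,
#'   `intron_embedded`, `host_intron_retained`, `excluded`.
#' @export
filter_lncrnas <- function(lnc_ids, models, expressed_ids, retention = NULL) {
  rows <- lapply(lnc_ids, function(id) {
    seo <- flag_sense_exonic_overlap(id, models, expressed_ids)
    ir <- flag_intronic_retained(id, models, retention)
    data.frame(gene_id = id, sense_exonic_overlap = seo,
               intron_embedded = ir$intron_embedded,
               host_intron_retained = ir$host_intron_retained,
               excluded = seo || (ir$intron_embedded && ir$host_intron_retained),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame(
    gene_id = character(), sense_exonic_overlap = logical(),
    intron_embedded = logical(), host_intron_retained = logical(),
    excluded = logical())
  rownames(out) <- NULL
  out
}

#' Compute intron retention calls from per-base coverage
#'
#' Helper that turns a coverage table into the boolean retention table
#' consumed by [flag_intronic_retained()]. An intron is called retained when
#' its median per-base coverage is at least `min_ratio` (default 0.25) of
#' the median coverage over its two flanking exons.
#'
#' @param models A `gene_models` object.
#' @param coverage data.frame with columns `chrom`, `pos` (0-based) and
#'   `depth`; positions absent from the table count as depth 0.
#' @param min_ratio Retention threshold on the intron/exon median-coverage
#'   ratio.
#' @return Retention data.frame (`gene_id`, `intron_index`, `retained`).
#' @export
intron_retention_from_coverage <- function(models, coverage, min_ratio = 0.25) {
  depth_at <- function(chrom, start, end) {
    sel <- coverage$chrom == chrom & coverage$pos >= start & coverage$pos < end
    d <- numeric(end - start)
    if (any(sel)) d[coverage$pos[sel] - start + 1L] <- coverage$depth[sel]
    d
  }
  out <- list()
  for (gid in models$genes$gene_id) {
    intr <- models$introns[[gid]]
    if (!nrow(intr)) next
    ex <- models$exons[[gid]]
    chrom <- models$genes$chrom[models$genes$gene_id == gid]
    for (k in seq_len(nrow(intr))) {
      flank <- c(depth_at(chrom, ex[k, 1L], ex[k, 2L]),
                 depth_at(chrom, ex[k + 1L, 1L], ex[k + 1L, 2L]))
      intron_med <- stats::median(depth_at(chrom, intr[k, 1L], intr[k, 2L]))
      exon_med <- stats::median(flank)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, intron_index = k,
        retained = exon_med > 0 && intron_med >= min_ratio * exon_med)
    }
  }
  do.call(rbind, out) %||%
    data.frame(gene_id = character(), intron_index = integer(),
               retained = logical())
}

# ---- regulatory domains (basal + extension) --------------------------------

#' Basal-plus-extension regulatory domains
#'
#' Assigns each protein-coding gene a regulatory domain following the
#' conventional basal-plus-extension association geometry used by
#' region-to-gene annotation tools: a strand-oriented basal region
#' (`basal_up` bp upstream and `basal_down` bp downstream of the TSS),
#' extended in both directions up to the nearest other gene's basal region
#' boundary, capped at `max_extension` bp from the TSS, and clipped at the
#' chromosome start. Basal regions of different genes may overlap, so a
#' position can fall in more than one domain.
#'
#' @param models A `gene_models` object; only `protein_coding` genes get
#'   domains.
#' @param basal_up,basal_down Basal region extents upstream/downstream of
#'   the TSS (defaults 5000 and 1000 bp).
#' @param max_extension Cap on the extension distance from the TSS
#'   (default 1e6 bp).
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `domain_start`, `domain_end` (0-based half-open).
#' @export
regulatory_domains <- function(models, basal_up = 5000, basal_down = 1000,
                               max_extension = 1e6) {
  g <- models$genes[models$genes$biotype == "protein_coding", , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = numeric(),
                      domain_start = numeric(), domain_end = numeric()))
  basal_start <- ifelse(g$strand == "+", g$tss - basal_up, g$tss + 1 - basal_down)
  basal_end <- ifelse(g$strand == "+", g$tss + basal_down, g$tss + 1 + basal_up)
  basal_start <- pmax(basal_start, 0)
  dom_start <- dom_end <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    same <- which(g$chrom == g$chrom[i])
    others <- setdiff(same, i)
    left_lim <- suppressWarnings(
      max(basal_end[others][basal_end[others] <= basal_start[i]], 0))
    right_lim <- suppressWarnings(
      min(basal_start[others][basal_start[others] >= basal_end[i]], Inf))
    ds <- max(g$tss[i] - max_extension, left_lim, 0)
    de <- min(g$tss[i] + 1 + max_extension, right_lim)
    dom_start[i] <- min(basal_start[i], ds)
    dom_end[i] <- max(basal_end[i], de)
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = g$tss, domain_start = dom_start, domain_end = dom_end,
             stringsAsFactors = FALSE)
}

#' Protein-coding neighbors of lncRNA loci
#'
#' Reports, for each lncRNA, the protein-coding genes whose regulatory
#' domain (see [regulatory_domains()]) contains the midpoint of the lncRNA
#' locus, with the signed, strand-oriented distance from the neighbor's TSS
#' to that midpoint (positive downstream of the neighbor).
#'
#' @param lnc_ids lncRNA gene ids present in `models`.
#' @inheritParams regulatory_domains
#' @return data.frame with `lnc_id`, `gene_id`, `distance`.
#' @export
neighboring_genes <- function(lnc_ids, models, basal_up = 5000,
                              basal_down = 1000, max_extension = 1e6) {
  dom <- regulatory_domains(models, basal_up, basal_down, max_extension)
  g <- models$genes
  out <- list()
  for (id in lnc_ids) {
    li <- match(id, g$gene_id)
    if (is.na(li)) stop("unknown lncRNA id: ", id)
    mid <- floor((g$start[li] + g$end[li]) / 2)
    hit <- dom[dom$chrom == g$chrom[li] & dom$domain_start <= mid &
                 mid < dom$domain_end, , drop = FALSE]
    if (nrow(hit)) {
      d <- ifelse(hit$strand == "+", mid - hit$tss, hit$tss - mid)
      out[[length(out) + 1L]] <- data.frame(
        lnc_id = id, gene_id = hit$gene_id, distance = d,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(lnc_id = character(), gene_id = character(),
               distance = numeric())
  res <- res[order(res$lnc_id, abs(res$distance), res$gene_id), ]
  rownames(res) <- NULL
  res
}
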