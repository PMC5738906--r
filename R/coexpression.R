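#' Sample-sample correlation matrix for data quality control
#'
#' Pearson correlation between all pairs of samples, computed on
#' `log2(FPKM + pseudocount)` and restricted to genes with FPKM strictly
#' above `fpkm_min` in at least one sample. Closely related samples should
#' show high correlations and cluster together; the matrix is the input for
#' the usual QC heatmap/dendrogram.
#'
#' @param x An `expression_set` or numeric matrix (genes x samples).
#' @param pseudocount Added before the log2 transform (default 0.1).
#' @param fpkm_min Gene inclusion threshold (strict `>`, default 1).
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   `constant` naming samples with constant log-expression (their
#'   off-diagonal entries are `NA`).
#' @export
sample_correlation_matrix <- function(x, pseudocount = 0.1, fpkm_min = 1) {
  if (inherits(x, "expression_set")) x <- x$values
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  keep <- apply(x, 1L, max) > fpkm_min
  lx <- log2p(x[keep, , drop = FALSE], pseudocount)
  const <- apply(lx, 2L, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  r <- suppressWarnings(stats::cor(lx, method = "pearson"))
  diag(r) <- 1
  structure(r, constant = colnames(x)[const])
}

#' Cross-tissue correlation of a gene pair
#'
#' Pearson correlation between the `log2(FPKM + pseudocount)` tissue
#' profiles of two genes, reported both over all tissues (`r_all`) and over
#' the tissues where the conditioning gene is expressed at
#' `FPKM >= fpkm_min` (`r_expressed`). The conditioned correlation mirrors
#' the common practice of asking whether two genes covary where the driver
#' gene is actually on. Correlations over fewer than 3 tissues, or with a
#' constant vector, are flagged undefined (`NA`).
#'
#' @param profile Genes x tissues FPKM matrix.
#' @param gene_a,gene_b Gene ids (rows of `profile`).
#' @param condition_gene Gene whose expression defines the conditioned
#'   tissue subset (default `gene_a`).
#' @param fpkm_min Expression condition threshold (inclusive, default 1).
#' @param pseudocount log2 pseudocount (default 0.1).
#' @return A `correlation_report`: list with `gene_a`, `gene_b`, `r_all`,
#'   `r_expressed`, `n_all`, `n_expressed`, `expressed_tissues`.
#' @export
gene_pair_correlation <- function(profile, gene_a, gene_b,
                                  condition_gene = gene_a, fpkm_min = 1,
                                  pseudocount = 0.1) {
  for (g in unique(c(gene_a, gene_b, condition_gene)))
    if (!g %in% rownames(profile)) stop("gene not in profile: ", g)
  la <- log2p(profile[gene_a, ], pseudocount)
  lb <- log2p(profile[gene_b, ], pseudocount)
  safe_cor <- function(u, v) {
    if (length(u) < 3L || stats::sd(u) == 0 || stats::sd(v) == 0)
      return(NA_real_)
    stats::cor(u, v, method = "pearson")
  }
  keep <- profile[condition_gene, ] >= fpkm_min
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 r_all = safe_cor(la, lb),
                 r_expressed = safe_cor(la[keep], lb[keep]),
                 n_all = length(la), n_expressed = sum(keep),
                 expressed_tissues = colnames(profile)[keep],
                 condition_gene = condition_gene, fpkm_min = fpkm_min),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %s vs %s\n", x$gene_a, x$gene_b))
  cat(sprintf("  r (all %d tissues):        %s\n", x$n_all,
              formatC(x$r_all, digits = 3, format = "f")))
  cat(sprintf("  r (%d tissues, %s FPKM >= %g): %s\n", x$n_expressed,
              x$condition_gene, x$fpkm_min,
              formatC(x$r_expressed, digits = 3, format = "f")))
  invisible(x)
}

#' Rank all genes by correlation with a query gene
#'
#' Pearson correlation of every gene's `log2(FPKM + pseudocount)` profile
#' against the query gene's, sorted by descending correlation with
#' lexicographic tie-breaking. The query itself is always ranked first
#' (its self-correlation is 1); genes with undefined correlation (constant
#' profiles) sort last with `NA`.
#'
#' @inheritParams gene_pair_correlation
#' @param query_gene Query gene id.
#' @return data.frame with `gene_id`, `r`, `rank`.
#' @export
rank_correlated_genes <- function(profile, query_gene, pseudocount = 0.1) {
  if (!query_gene %in% rownames(profile))
    stop("gene not in profile: ", query_gene)
  lx <- log2p(profile, pseudocount)
  q <- lx[query_gene, ]
  sds <- apply(lx, 1L, stats::sd)
  r <- rep(NA_real_, nrow(profile))
  names(r) <- rownames(profile)
  if (stats::sd(q) > 0) {
    ok <- sds > 0
    r[ok] <- suppressWarnings(as.vector(stats::cor(t(lx[ok, , drop = FALSE]), q)))
  }
  r[query_gene] <- 1
  is_query <- rownames(profile) == query_gene
  ord <- order(!is_query, -ifelse(is.na(r), -Inf, r), rownames(profile))
  out <- data.frame(gene_id = rownames(profile)[ord], r = r[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
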