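#' Average expression samples by tissue
#'
#' Collapses a gene x sample FPKM matrix to a gene x tissue profile by taking
#' the arithmetic mean of the replicates within each tissue. Tissue columns
#' are sorted lexicographically so the output is deterministic regardless of
#' sample order.
#'
#' @param x An `expression_set` (see [read_expression()]), or a numeric
#'   matrix with sample-id colnames.
#' @param samples When `x` is a matrix, a data.frame with `sample_id`,
#'   `tissue` covering every column.
#' @return Numeric matrix of replicate-averaged FPKM, genes x tissues.
#' @export
average_by_tissue <- function(x, samples = NULL) {
  if (inherits(x, "expression_set")) {
    samples <- x$samples
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(samples))
  miss <- setdiff(colnames(x), samples$sample_id)
  if (length(miss))
    stop("sample(s) without tissue assignment: ", paste(miss, collapse = ", "))
  tissue_of <- samples$tissue[match(colnames(x), samples$sample_id)]
  tissues <- sort(unique(samples$tissue))
  cols <- lapply(tissues, function(t) which(tissue_of == t))
  empty <- tissues[lengths(cols) == 0L]
  if (length(empty))
    stop("empty tissue group(s): ", paste(empty, collapse = ", "))
  out <- vapply(cols, function(j) rowMeans(x[, j, drop = FALSE]),
                numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), tissues))
  out
}

#' Drop low-abundance genes from a tissue profile
#'
#' Retains genes whose maximum tissue-averaged FPKM is at least `fpkm_min`
#' (inclusive), mirroring the usual "FPKM < 1 filtered before downstream
#' analysis" pre-processing step.
#'
#' @param profile Genes x tissues FPKM matrix.
#' @param fpkm_min Abundance threshold (default 1).
#' @return The filtered profile matrix.
#' @export
filter_low_abundance <- function(profile, fpkm_min = 1) {
  stopifnot(is.matrix(profile), fpkm_min >= 0)
  keep <- apply(profile, 1L, max) >= fpkm_min
  profile[keep, , drop = FALSE]
}

#' Compute the SPM tissue-specificity measure
#'
#' For gene g and tissue t with tissue-averaged expression `m[g, t]`,
#' `SPM[g, t] = m[g, t] / sqrt(sum_t' m[g, t']^2)`: the cosine similarity
#' between the gene's cross-tissue expression vector and the indicator
#' vector of tissue t. SPM lies in \[0, 1\]; 1 means the gene is expressed in
#' that tissue only, and the squares across tissues sum to 1 for any gene
#' with a nonzero expression vector.
#'
#' Genes whose expression is zero in every tissue have no defined direction;
#' their SPM rows are set to `NA` and flagged in the `undefined` field rather
#' than propagating `NaN`.
#'
#' @param profile Genes x tissues FPKM matrix (typically replicate-averaged
#'   and abundance-filtered).
#' @return An `spm_table`: list with `spm` (matrix, same dimnames as
#'   `profile`) and `undefined` (named logical, TRUE for all-zero genes).
#' @export
compute_spm <- function(profile) {
  stopifnot(is.matrix(profile), is.numeric(profile))
  if (any(profile < 0)) stop("negative expression in profile")
  norms <- sqrt(rowSums(profile^2))
  undefined <- norms == 0
  spm <- profile / norms
  spm[undefined, ] <- NA_real_
  structure(list(spm = spm,
                 undefined = stats::setNames(undefined, rownames(profile))),
            class = "spm_table")
}

#' @export
print.spm_table <- function(x, ...) {
  cat(sprintf("spm_table: %d genes x %d tissues (%d undefined)\n",
              nrow(x$spm), ncol(x$spm), sum(x$undefined)))
  invisible(x)
}

#' Call tissue-selective and tissue-preferential genes
#'
#' A gene is *selective* for the target tissue when its SPM there is at
#' least `spm_min` (default 0.9) and its mean FPKM there is at least
#' `fpkm_min` (default 1); both thresholds are inclusive. A gene whose SPM
#' falls in the half-open *preferential* band (default \[0.7, 0.9)) is
#' reported as preferential regardless of abundance; everything else,
#' including genes with undefined SPM, is class `none`. A gene at or above
#' `spm_min` that fails the abundance threshold is `none`, not preferential.
#'
#' @param spm An `spm_table` from [compute_spm()].
#' @param profile The matching genes x tissues FPKM matrix.
#' @param tissue Target tissue (must be a column of both).
#' @param spm_min Selectivity threshold on SPM (inclusive).
#' @param fpkm_min Abundance threshold on mean FPKM (inclusive).
#' @param preferential_band Numeric length-2, half-open SPM band
#'   `[lo, hi)` reported as preferential.
#' @return data.frame with columns `gene_id`, `tissue`, `spm`, `mean_fpkm`,
#'   `class` (`selective`/`preferential`/`none`), sorted by descending SPM
#'   then gene id (undefined-SPM genes last).
#' @export
call_selective <- function(spm, profile, tissue, spm_min = 0.9, fpkm_min = 1,
                           preferential_band = c(0.7, 0.9)) {
  stopifnot(inherits(spm, "spm_table"))
  if (!tissue %in% colnames(spm$spm))
    stop("unknown tissue: ", tissue)
  if (!identical(rownames(spm$spm), rownames(profile)))
    stop("spm table and profile gene sets differ")
  s <- spm$spm[, tissue]
  m <- profile[, tissue]
  cls <- rep("none", length(s))
  cls[!is.na(s) & s >= preferential_band[1L] & s < preferential_band[2L]] <- "preferential"
  cls[!is.na(s) & s >= spm_min & m >= fpkm_min] <- "selective"
  out <- data.frame(gene_id = rownames(profile), tissue = tissue,
                    spm = s, mean_fpkm = m, class = cls,
                    stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(out$spm), -Inf, out$spm), out$gene_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Compare two gene lists
#'
#' Set overlap report used for cross-platform/cross-study comparisons of
#' selective-gene lists.
#'
#' @param list_a,list_b Character vectors of gene identifiers (duplicates
#'   ignored).
#' @return List with `n_a`, `n_b`, `n_overlap`, `frac_a` (|A∩B|/|A|),
#'   `frac_b`, `a_only`, `b_only`, `shared`.
#' @export
compare_gene_lists <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  shared <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = length(shared),
       frac_a = if (length(a)) length(shared) / length(a) else NA_real_,
       frac_b = if (length(b)) length(shared) / length(b) else NA_real_,
       a_only = sort(setdiff(a, b)), b_only = sort(setdiff(b, a)),
       shared = shared)
}

#' One-call tissue-selectivity analysis
#'
#' Convenience wrapper chaining [average_by_tissue()],
#' [filter_low_abundance()], [compute_spm()] and [call_selective()].
#'
#' @inheritParams average_by_tissue
#' @inheritParams call_selective
#' @param x An `expression_set`.
#' @param tissue Target tissue.
#' @return List with `profile`, `spm` and `calls` (with class
#'   `selectivity_result`).
#' @export
tissue_selectivity <- function(x, tissue, spm_min = 0.9, fpkm_min = 1,
                               preferential_band = c(0.7, 0.9)) {
  profile <- average_by_tissue(x)
  profile <- filter_low_abundance(profile, fpkm_min)
  spm <- compute_spm(profile)
  calls <- call_selective(spm, profile, tissue, spm_min, fpkm_min,
                          preferential_band)
  structure(list(profile = profile, spm = spm, calls = calls,
                 tissue = tissue,
                 params = list(spm_min = spm_min, fpkm_min = fpkm_min,
                               preferential_band = preferential_band)),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("selectivity_result for '%s': %d genes after abundance filter\n",
              x$tissue, nrow(x$profile)))
  cat(sprintf("  selective:    %d (SPM >= %g & FPKM >= %g)\n",
              sum(x$calls$class == "selective"), x$params$spm_min,
              x$params$fpkm_min))
  cat(sprintf("  preferential: %d (SPM in [%g, %g))\n",
              sum(x$calls$class == "preferential"),
              x$params$preferential_band[1], x$params$preferential_band[2]))
  invisible(x)
}
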