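# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive each quantity from first principles, by loops over
# base definitions, so they share no code path with the implementation.

# SPM as a literal cosine similarity between the expression vector and the
# per-tissue indicator vector.
oracle_spm <- function(profile) {
  out <- matrix(NA_real_, nrow(profile), ncol(profile),
                dimnames = dimnames(profile))
  for (g in seq_len(nrow(profile))) {
    v <- profile[g, ]
    if (all(v == 0)) next
    for (t in seq_len(ncol(profile))) {
      e <- rep(0, length(v)); e[t] <- 1
      out[g, t] <- sum(v * e) / (sqrt(sum(v^2)) * sqrt(sum(e^2)))
    }
  }
  out
}

# Group means by explicit per-tissue loops.
oracle_group_means <- function(values, tissue_of) {
  tissues <- sort(unique(tissue_of))
  out <- matrix(0, nrow(values), length(tissues),
                dimnames = list(rownames(values), tissues))
  for (t in tissues) {
    cols <- which(tissue_of == t)
    for (g in seq_len(nrow(values))) out[g, t] <- mean(values[g, cols])
  }
  out
}

# Interval merging by union-find over the "gap <= merge_gap" relation.
oracle_merge <- function(start, end, merge_gap) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    gap <- max(start[i], start[j]) - min(end[i], end[j])
    if (gap <= merge_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  res <- t(vapply(comp, function(k) c(min(start[k]), max(end[k])),
                  numeric(2)))
  res[order(res[, 1L]), , drop = FALSE]
}

# Basal-plus-extension regulatory domains by a direct per-gene scan.
oracle_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                           max_ext = 1e6) {
  n <- nrow(genes)
  bs <- be <- ds <- de <- numeric(n)
  for (i in seq_len(n)) {
    if (genes$strand[i] == "+") {
      bs[i] <- max(genes$tss[i] - basal_up, 0)
      be[i] <- genes$tss[i] + basal_down
    } else {
      bs[i] <- max(genes$tss[i] + 1 - basal_down, 0)
      be[i] <- genes$tss[i] + 1 + basal_up
    }
  }
  for (i in seq_len(n)) {
    left <- 0; right <- Inf
    for (j in seq_len(n)) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      if (be[j] <= bs[i]) left <- max(left, be[j])
      if (bs[j] >= be[i]) right <- min(right, bs[j])
    }
    ds[i] <- min(bs[i], max(genes$tss[i] - max_ext, left))
    de[i] <- max(be[i], min(genes$tss[i] + 1 + max_ext, right))
  }
  data.frame(gene_id = genes$gene_id, domain_start = ds, domain_end = de)
}

# TSS-centered profile by per-base averaging then binning.
oracle_tss_profile <- function(peaks, tss, half_window, bin) {
  nb <- 2 * half_window / bin
  acc <- numeric(nb)
  for (i in seq_len(nrow(tss))) {
    base <- rep(0, 2 * half_window)
    for (k in seq_len(2 * half_window)) {
      pos <- tss$tss[i] - half_window + k - 1
      hit <- any(peaks$chrom == tss$chrom[i] & peaks$start <= pos &
                   pos < peaks$end)
      base[k] <- as.numeric(hit)
    }
    if (tss$strand[i] == "-") base <- rev(base)
    acc <- acc + colMeans(matrix(base, nrow = bin))
  }
  acc / nrow(tss)
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# ---- fixture builders -------------------------------------------------------

make_profile <- function(n_genes, n_tissues, seed = 1, max_val = 100) {
  set.seed(seed)
  matrix(stats::runif(n_genes * n_tissues, 0, max_val), n_genes, n_tissues,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("t%02d", seq_len(n_tissues))))
}

make_peaks <- function(start, end, score = NULL, chrom = "chr1",
                       mark = "H3K27ac", tissue = "cartilage") {
  peak_set(data.frame(chrom = rep_len(chrom, length(start)),
                      start = start, end = end,
                      score = score %||% rep(0, length(start))),
           mark = mark, tissue = tissue)
}

# Two coding genes and helpers for interval-rule tests.
make_models <- function(genes, exons) gene_models(genes, exons)

tiny_sim_config <- function(seed = 1, noise_sd_log2 = 0, ...) {
  sim_config(seed = seed, noise_sd_log2 = noise_sd_log2,
             n_background_genes = 50, n_coding_genes = 12, n_cs_coding = 8,
             replicates_per_tissue = 3,
             lncrna_classes = c(clean = 2L, sense_exonic_overlap = 2L,
                                intronic_retained = 2L,
                                intronic_not_retained = 2L),
             peak_tissues = c("muscle", "stomach"),
             n_shared_enhancers = 4, n_unique_enhancers = 3,
             n_decoy_promoter_peaks = 3, ...)
}

`%||%` <- tissel:::`%||%`
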