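# Synthetic multi-tissue study generator with planted, fully known truth.
#
# The generator emulates the shape of a fetal multi-tissue RNA-seq panel
# (22 tissues, ~5 replicates each) plus per-tissue histone-mark/TF peak
# tracks on a single long pseudo-chromosome, so that every pipeline stage
# can be exercised against a known answer.

.default_other_tissues <- c(
  "adrenal_gland", "brain", "cd4_t_cell", "cd8_t_cell", "heart",
  "intestine_large", "intestine_small", "kidney", "liver", "lung",
  "muscle", "ovary", "placenta", "skin", "spinal_cord", "spleen",
  "stomach", "testis", "thymus", "thyroid", "tongue")

.default_peak_tissues <- c("adrenal_gland", "intestine_large", "muscle",
                           "spinal_cord", "stomach", "thymus")

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by the `simulate_*`
#' generators. Defaults describe the study conditions the package is tested
#' under: 22 tissues with 5 replicates each, 50 planted target-selective
#' coding genes at controlled SPM over a background of non-selective genes,
#' lncRNAs planted in each overlap class, a 7-tissue enhancer panel, and
#' lognormal replicate noise (`noise_sd_log2` on the log2 scale).
#'
#' Background genes draw a per-gene baseline (log2 FPKM ~ N(`bg_mean_log2`,
#' `bg_sd_log2`)) plus per-tissue fold offsets truncated at
#' +/- `bg_tissue_max_log2` log2 units. The truncation bounds every
#' background gene's SPM strictly below 0.9, so the "background" truth class
#' is internally consistent: no background gene can satisfy the selective
#' rule by chance.
#'
#' @param n_tissues Number of tissues (default 22).
#' @param target_tissue Target tissue label (default `"cartilage"`).
#' @param replicates_per_tissue Replicates per tissue (default 5).
#' @param n_background_genes Background (non-planted) genes (default 500).
#' @param n_coding_genes,n_cs_coding Annotated coding genes and how many of
#'   them are planted target-selective.
#' @param planted_selective Optional data.frame (`gene_id`, `target_tissue`,
#'   `target_spm`, `mean_fpkm`) overriding the built-in planted set (used
#'   when simulating expression without annotation).
#' @param noise_sd_log2 Replicate noise SD on the log2 scale (default 0.25).
#' @param bg_mean_log2,bg_sd_log2 Background baseline distribution.
#' @param bg_tissue_sd_log2,bg_tissue_max_log2 Background per-tissue fold
#'   offset SD and truncation bound.
#' @param lncrna_classes Named integer vector of planted lncRNA counts per
#'   class (`clean`, `sense_exonic_overlap`, `intronic_retained`,
#'   `intronic_not_retained`).
#' @param lnc_target_spm,lnc_mean_fpkm Planted SPM and target-tissue FPKM of
#'   the lncRNAs.
#' @param coexpr_pairs data.frame (`gene_a`, `gene_b`, `latent_r`) of
#'   co-expressed gene pairs planted into the matrix, or `NULL`.
#' @param peak_tissues Character vector of non-target tissues with peak
#'   tracks (default: 6, giving a 7-tissue panel).
#' @param n_shared_enhancers Enhancers present in every panel tissue.
#' @param n_unique_enhancers Generic tissue-unique enhancers per tissue.
#' @param n_decoy_promoter_peaks Promoter-proximal H3K27ac decoys planted in
#'   the target tissue.
#' @param enhancer_gene_frac Fraction of planted selective coding genes
#'   given a flanking target-unique enhancer (default 0.53).
#' @param tf_bound_frac Fraction of planted selective coding genes given a
#'   promoter TF peak (default 0.744).
#' @param tf_mark TF mark label (default `"SOX9"`).
#' @param enhancer_width,k4me3_halfwidth Planted feature widths (bp).
#' @param gamma_shape,gamma_scale Peak-intensity gamma distribution.
#' @param chrom,chrom_length,gene_spacing Pseudo-chromosome geometry. The
#'   wide default spacing (2.4 Mb) keeps each gene's capped regulatory
#'   domain disjoint from its neighbors', so enhancer-gene association
#'   truth is unambiguous.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tissues = 22, target_tissue = "cartilage",
                       replicates_per_tissue = 5, n_background_genes = 500,
                       n_coding_genes = 60, n_cs_coding = 50,
                       planted_selective = NULL,
                       noise_sd_log2 = 0.25,
                       bg_mean_log2 = 3, bg_sd_log2 = 2,
                       bg_tissue_sd_log2 = 1, bg_tissue_max_log2 = 1.6,
                       lncrna_classes = c(clean = 6L,
                                          sense_exonic_overlap = 6L,
                                          intronic_retained = 6L,
                                          intronic_not_retained = 6L),
                       lnc_target_spm = 0.95, lnc_mean_fpkm = 20,
                       coexpr_pairs = data.frame(gene_a = "COEXA",
                                                 gene_b = "COEXB",
                                                 latent_r = 0.8),
                       peak_tissues = .default_peak_tissues,
                       n_shared_enhancers = 20, n_unique_enhancers = 15,
                       n_decoy_promoter_peaks = 10,
                       enhancer_gene_frac = 0.53, tf_bound_frac = 0.744,
                       tf_mark = "SOX9",
                       enhancer_width = 800, k4me3_halfwidth = 500,
                       gamma_shape = 2, gamma_scale = 20,
                       chrom = "chrS", chrom_length = 1.6e8,
                       gene_spacing = 2.4e6, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_tissues >= 2, replicates_per_tissue >= 1,
            n_background_genes >= 0, n_coding_genes >= 1,
            n_cs_coding >= 0, n_cs_coding <= n_coding_genes,
            noise_sd_log2 >= 0, bg_tissue_max_log2 > 0,
            all(lncrna_classes >= 0), length(lncrna_classes) == 4L,
            enhancer_gene_frac >= 0, enhancer_gene_frac <= 1,
            tf_bound_frac >= 0, tf_bound_frac <= 1,
            enhancer_width > 0, gamma_shape > 0, gamma_scale > 0,
            gene_spacing >= 2 * 1e6 + 4e5, chrom_length > 0)
  need <- c("clean", "sense_exonic_overlap", "intronic_retained",
            "intronic_not_retained")
  if (!all(need %in% names(lncrna_classes)))
    stop("lncrna_classes must name: ", paste(need, collapse = ", "))
  if (sum(lncrna_classes) > n_coding_genes)
    stop("not enough coding genes to host/anchor all planted lncRNAs")
  if (!is.null(coexpr_pairs))
    stopifnot(all(abs(coexpr_pairs$latent_r) <= 1))
  n_anchor <- sum(lncrna_classes)
  if (200000 + n_coding_genes * gene_spacing > chrom_length)
    stop("chrom_length too small for the configured gene count/spacing")
  if (lnc_target_spm <= 0 || lnc_target_spm > 1)
    stop("unsatisfiable lnc_target_spm (must be in (0, 1])")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d tissues x %d replicates, %d coding ",
                     "(%d selective), %d lncRNA, %d background genes, ",
                     "noise sd %.2f log2, seed %d\n"),
              x$n_tissues, x$replicates_per_tissue, x$n_coding_genes,
              x$n_cs_coding, sum(x$lncrna_classes), x$n_background_genes,
              x$noise_sd_log2, x$seed))
  invisible(x)
}

sim_tissues <- function(config) {
  others <- if (config$n_tissues - 1 <= length(.default_other_tissues)) {
    .default_other_tissues[seq_len(config$n_tissues - 1)]
  } else {
    c(.default_other_tissues,
      sprintf("tissue%02d",
              seq_len(config$n_tissues - 1 - length(.default_other_tissues))))
  }
  c(config$target_tissue, others)
}

#' Flat background level matching a target SPM
#'
#' Inverts the SPM definition for the planted-gene construction: with the
#' target tissue at mean `m` and every other of the `n_tissues - 1` tissues
#' at a common level `b`, `SPM = m / sqrt(m^2 + (n-1) b^2)`. Solving for `b`
#' gives `b = m * sqrt((1 - s^2) / (s^2 * (n - 1)))`; `s = 1` forces
#' `b = 0`.
#'
#' @param m Target-tissue mean FPKM (> 0).
#' @param s Target SPM in (0, 1].
#' @param n_tissues Number of tissues (>= 2).
#' @return The off-target mean FPKM `b`.
#' @export
spm_flat_background <- function(m, s, n_tissues) {
  if (any(m <= 0)) stop("unsatisfiable: target mean must be > 0")
  if (any(s <= 0 | s > 1)) stop("unsatisfiable target SPM (must be in (0, 1])")
  if (n_tissues < 2) stop("need >= 2 tissues")
  m * sqrt((1 - s^2) / (s^2 * (n_tissues - 1)))
}

# Truncated-normal draws by clipping; used where boundedness is structural
# (background/coexpr fold offsets must keep SPM < 0.9 by construction).
clipped_rnorm <- function(n, sd, max_abs) {
  pmin(pmax(stats::rnorm(n, 0, sd), -max_abs), max_abs)
}

#' Simulate gene models, planted lncRNA classes and a retention table
#'
#' Lays `n_coding_genes` three-exon coding genes (alternating strand) along
#' the pseudo-chromosome and plants lncRNAs of the four overlap classes:
#' `clean` (intergenic, 50 kb downstream of an anchor gene),
#' `sense_exonic_overlap` (exon overlapping a host exon on the same
#' strand), and `intronic_retained` / `intronic_not_retained` (single exon
#' embedded in host intron 1, whose retention flag differs). An internal
#' validator re-checks every planted lncRNA against its class definition
#' using the package's own filter predicates and errors on any violation.
#'
#' @param config A `sim_config`.
#' @return List with `models` (a `gene_models`), `coding_ids`,
#'   `cs_coding_ids`, `lnc_truth` (data.frame `gene_id`, `class`, `host`),
#'   `retention` (data.frame), `must_express` (coding ids guaranteed
#'   expressed).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_coding_genes
  p <- 200000 + (seq_len(n) - 1) * config$gene_spacing
  coding_ids <- sprintf("CG%03d", seq_len(n))
  genes <- data.frame(gene_id = coding_ids, biotype = "protein_coding",
                      chrom = config$chrom,
                      strand = ifelse(seq_len(n) %% 2L == 1L, "+", "-"),
                      stringsAsFactors = FALSE)
  exons <- lapply(p, function(pp)
    cbind(start = pp + c(0, 2300, 4600), end = pp + c(300, 2600, 4900)))
  names(exons) <- coding_ids

  cls <- config$lncrna_classes
  counts <- cls[c("sense_exonic_overlap", "intronic_retained",
                  "intronic_not_retained", "clean")]
  host_idx <- split(seq_len(sum(counts)),
                    rep(names(counts), counts))[names(counts)]
  lnc_rows <- list(); lnc_exons <- list(); truth <- list()
  k <- 0L
  for (class in names(counts)) {
    for (i in host_idx[[class]]) {
      k <- k + 1L
      id <- sprintf("LNC%03d", k)
      host <- coding_ids[i]
      pp <- p[i]
      iv <- switch(class,
        sense_exonic_overlap = c(pp + 2400, pp + 2900),
        intronic_retained = c(pp + 800, pp + 1300),
        intronic_not_retained = c(pp + 800, pp + 1300),
        clean = c(pp + 50000, pp + 50500))
      strand <- if (class == "clean") "+" else genes$strand[i]
      lnc_rows[[k]] <- data.frame(gene_id = id, biotype = "lncRNA",
                                  chrom = config$chrom, strand = strand,
                                  stringsAsFactors = FALSE)
      lnc_exons[[id]] <- cbind(start = iv[1L], end = iv[2L])
      truth[[k]] <- data.frame(gene_id = id, class = class,
                               host = if (class == "clean") NA_character_ else host,
                               anchor = host, stringsAsFactors = FALSE)
    }
  }
  genes <- rbind(genes, do.call(rbind, lnc_rows) %||% NULL)
  models <- gene_models(genes, c(exons, lnc_exons))
  lnc_truth <- do.call(rbind, truth) %||%
    data.frame(gene_id = character(), class = character(),
               host = character(), anchor = character())

  # retention table: FALSE everywhere except intron 1 of IR hosts
  ir_hosts <- lnc_truth$host[lnc_truth$class == "intronic_retained"]
  retention <- do.call(rbind, lapply(coding_ids, function(g)
    data.frame(gene_id = g, intron_index = 1:2,
               retained = c(g %in% ir_hosts, FALSE))))
  must_express <- unique(stats::na.omit(lnc_truth$host))

  validate_planted_annotation(models, lnc_truth, retention, must_express)
  list(models = models, coding_ids = coding_ids,
       cs_coding_ids = coding_ids[seq_len(config$n_cs_coding)],
       lnc_truth = lnc_truth, retention = retention,
       must_express = must_express)
}

# Class-purity validator: every planted lncRNA must satisfy its own class
# definition when re-checked with the package's filter predicates.
validate_planted_annotation <- function(models, lnc_truth, retention,
                                        must_express) {
  for (i in seq_len(nrow(lnc_truth))) {
    id <- lnc_truth$gene_id[i]; class <- lnc_truth$class[i]
    seo <- flag_sense_exonic_overlap(id, models, must_express)
    ir <- flag_intronic_retained(id, models, retention)
    ok <- switch(class,
      clean = !seo && !ir$intron_embedded,
      sense_exonic_overlap = seo,
      intronic_retained = !seo && ir$intron_embedded && ir$host_intron_retained,
      intronic_not_retained = !seo && ir$intron_embedded && !ir$host_intron_retained)
    if (!isTRUE(ok))
      stop(sprintf("planted lncRNA %s violates its class definition (%s)",
                   id, class))
  }
  invisible(TRUE)
}

#' Simulate a multi-tissue FPKM expression matrix with planted truth
#'
#' Planted selective genes get a noise-free tissue-mean vector whose SPM in
#' the target tissue equals `target_spm` exactly (target mean `m`, all other
#' tissues at the flat level given by [spm_flat_background()]). Background
#' genes draw a lognormal baseline with bounded per-tissue fold offsets (so
#' their SPM stays below 0.9 by construction); co-expressed pairs draw
#' correlated log2 tissue profiles. Replicates are drawn lognormally around
#' the tissue means with SD `noise_sd_log2` on the log2 scale; with zero
#' noise every replicate equals its tissue mean.
#'
#' @param config A `sim_config`.
#' @param annotation Optional output of [simulate_annotation()]; when given,
#'   the annotated coding genes and lncRNAs are included in the matrix
#'   (selective for the first `n_cs_coding` coding genes and all lncRNAs).
#' @return List with `expression` (an `expression_set`), `truth`
#'   (data.frame `gene_id`, `class`, `target_tissue`, `target_spm`,
#'   `mean_fpkm`, `biotype`) and `means` (the noise-free gene x tissue
#'   matrix).
#' @export
simulate_expression <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tissues <- sim_tissues(config)
  ti <- match(config$target_tissue, tissues)

  planted <- config$planted_selective
  bio <- character()
  if (!is.null(annotation)) {
    n_cs <- length(annotation$cs_coding_ids)
    lnc_ids <- annotation$lnc_truth$gene_id
    planted <- data.frame(
      gene_id = c(annotation$cs_coding_ids, lnc_ids),
      target_tissue = config$target_tissue,
      target_spm = c(seq(0.92, 1, length.out = max(n_cs, 1L))[seq_len(n_cs)],
                     rep(config$lnc_target_spm, length(lnc_ids))),
      mean_fpkm = c(10^seq(1, 3, length.out = max(n_cs, 1L))[seq_len(n_cs)],
                    rep(config$lnc_mean_fpkm, length(lnc_ids))),
      stringsAsFactors = FALSE)
    bg_ann <- setdiff(annotation$models$genes$gene_id, planted$gene_id)
  } else if (is.null(planted)) {
    planted <- data.frame(
      gene_id = sprintf("CS%03d", seq_len(50)),
      target_tissue = config$target_tissue,
      target_spm = seq(0.92, 1, length.out = 50),
      mean_fpkm = 10^seq(1, 3, length.out = 50),
      stringsAsFactors = FALSE)
    bg_ann <- character()
  } else {
    bg_ann <- character()
  }
  if (!all(planted$target_tissue %in% tissues))
    stop("planted target tissue not among simulated tissues")

  bg_ids <- c(bg_ann,
              if (config$n_background_genes > 0)
                sprintf("BG%05d", seq_len(config$n_background_genes)))
  pair_ids <- if (!is.null(config$coexpr_pairs))
    unique(c(config$coexpr_pairs$gene_a, config$coexpr_pairs$gene_b))
  else character()
  gene_ids <- c(planted$gene_id, bg_ids, pair_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids across classes")

  nT <- length(tissues)
  means <- matrix(0, nrow = length(gene_ids), ncol = nT,
                  dimnames = list(gene_ids, tissues))
  with_seed(derive_seed(config$seed, 1L), {
    # planted selective genes: exact SPM by construction
    for (i in seq_len(nrow(planted))) {
      m <- planted$mean_fpkm[i]; s <- planted$target_spm[i]
      b <- spm_flat_background(m, s, nT)
      row <- rep(b, nT)
      row[match(planted$target_tissue[i], tissues)] <- m
      means[planted$gene_id[i], ] <- row
    }
    # background genes: baseline + bounded per-tissue fold offsets
    if (length(bg_ids)) {
      mu <- stats::rnorm(length(bg_ids), config$bg_mean_log2, config$bg_sd_log2)
      names(mu) <- bg_ids
      if (!is.null(annotation)) {
        me <- intersect(annotation$must_express, bg_ids)
        mu[me] <- pmax(mu[me], 2)
      }
      delta <- matrix(clipped_rnorm(length(bg_ids) * nT,
                                    config$bg_tissue_sd_log2,
                                    config$bg_tissue_max_log2),
                      nrow = length(bg_ids))
      means[bg_ids, ] <- 2^(mu + delta)
    }
    # co-expressed pairs: correlated log2 profiles, offsets bounded as above
    if (!is.null(config$coexpr_pairs)) {
      for (i in seq_len(nrow(config$coexpr_pairs))) {
        r <- config$coexpr_pairs$latent_r[i]
        z1 <- stats::rnorm(nT); z2 <- stats::rnorm(nT)
        y <- r * z1 + sqrt(1 - r^2) * z2
        z1 <- pmin(pmax(z1, -2), 2); y <- pmin(pmax(y, -2), 2)
        means[config$coexpr_pairs$gene_a[i], ] <- 2^(2 + 0.8 * z1)
        means[config$coexpr_pairs$gene_b[i], ] <- 2^(2 + 0.8 * y)
      }
    }
    # replicates: lognormal noise around tissue means
    reps <- config$replicates_per_tissue
    sample_ids <- as.vector(t(outer(tissues, seq_len(reps),
                                    function(t, j) paste0(t, "_r", j))))
    values <- matrix(0, nrow = length(gene_ids), ncol = length(sample_ids),
                     dimnames = list(gene_ids, sample_ids))
    for (t in seq_len(nT)) {
      for (j in seq_len(reps)) {
        noise <- if (config$noise_sd_log2 > 0)
          2^stats::rnorm(length(gene_ids), 0, config$noise_sd_log2) else 1
        values[, (t - 1L) * reps + j] <- means[, t] * noise
      }
    }
    meta <- data.frame(sample_id = sample_ids,
                       tissue = rep(tissues, each = reps),
                       stringsAsFactors = FALSE)
    truth <- data.frame(
      gene_id = gene_ids,
      class = c(rep("selective", nrow(planted)),
                rep("background", length(bg_ids)),
                rep("coexpr_pair", length(pair_ids))),
      target_tissue = c(planted$target_tissue,
                        rep(NA_character_, length(bg_ids) + length(pair_ids))),
      target_spm = c(planted$target_spm,
                     rep(NA_real_, length(bg_ids) + length(pair_ids))),
      mean_fpkm = c(planted$mean_fpkm,
                    rep(NA_real_, length(bg_ids) + length(pair_ids))),
      stringsAsFactors = FALSE)
    if (!is.null(annotation)) {
      truth$biotype <- annotation$models$genes$biotype[
        match(truth$gene_id, annotation$models$genes$gene_id)]
    } else truth$biotype <- NA_character_
    list(expression = expression_set(values, meta), truth = truth,
         means = means)
  })
}

#' Simulate per-tissue peak tracks with planted enhancer truth
#'
#' For a panel of tissues (target + `peak_tissues`), plants:
#' H3K4me3 promoter peaks at every coding TSS; *true enhancers* (H3K27ac and
#' H3K4me1) placed > 3 kb from every TSS and every H3K4me3 peak, pairwise
#' more than 1 kb apart; *shared* enhancers present at identical coordinates
#' in all panel tissues; generic *tissue-unique* enhancers placed mid-gap
#' (outside every capped regulatory domain); *flanking* target-unique
#' enhancers 10-30 kb from a fraction of the planted selective coding genes;
#' promoter-proximal H3K27ac *decoys* (within 3 kb of a TSS, so the distance
#' rule must remove them); and promoter TF peaks for a fraction of the
#' planted selective genes. Intensities are gamma-distributed. An internal
#' validator re-checks every planted feature against its class definition.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @return List with `h3k27ac`, `h3k4me3`, `h3k4me1` (named lists of
#'   `peak_set` per tissue), `tf` (target-tissue TF `peak_set`), and `truth`
#'   (list: `enhancers` data.frame, `tf_bound_genes`, `unique_target`,
#'   `flank_genes`).
#' @export
simulate_peaks <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  tissues <- c(config$target_tissue, config$peak_tissues)
  models <- annotation$models
  g <- models$genes
  coding <- g[g$biotype == "protein_coding", , drop = FALSE]
  w <- config$enhancer_width
  with_seed(derive_seed(config$seed, 3L), {
    # H3K4me3 at every coding promoter, per tissue
    k4me3 <- lapply(tissues, function(t) {
      peak_set(data.frame(chrom = coding$chrom,
                          start = pmax(coding$tss - config$k4me3_halfwidth, 0),
                          end = coding$tss + config$k4me3_halfwidth,
                          name = paste0("k4me3_", coding$gene_id),
                          score = stats::rgamma(nrow(coding),
                                                config$gamma_shape,
                                                scale = config$gamma_scale)),
               mark = "H3K4me3", tissue = t)
    })
    names(k4me3) <- tissues

    # mid-gap slots: > 1 Mb from both flanking TSSs, 4 kb apart
    n_gaps <- nrow(coding) - 1L
    slot_pos <- unlist(lapply(seq_len(n_gaps), function(j)
      coding$start[j] - 0 + 1.2e6 + (0:24) * 4000))
    n_flank <- round(config$enhancer_gene_frac * length(annotation$cs_coding_ids))
    flank_genes <- annotation$cs_coding_ids[seq_len(n_flank)]
    n_need <- config$n_shared_enhancers +
      config$n_unique_enhancers * length(tissues)
    if (n_need > length(slot_pos))
      stop("not enough intergenic slots for the configured enhancer counts")
    slot_take <- function(n) {
      out <- slot_pos[seq_len(n)]
      slot_pos <<- slot_pos[-seq_len(n)]
      out
    }
    shared_start <- slot_take(config$n_shared_enhancers)
    unique_start <- lapply(tissues, function(t)
      slot_take(config$n_unique_enhancers))
    names(unique_start) <- tissues
    flank_start <- g$tss[match(flank_genes, g$gene_id)] + 10000 +
      round(stats::runif(n_flank, 0, 20000) / 100) * 100
    decoy_genes <- coding$gene_id[seq_len(config$n_decoy_promoter_peaks)]
    decoy_start <- coding$tss[match(decoy_genes, coding$gene_id)] + 1200

    enh_df <- function(start, tissue, class, shared, uniq, assoc) {
      if (!length(start))
        return(NULL)
      data.frame(tissue = tissue, chrom = config$chrom, start = start,
                 end = start + if (class == "decoy") 600 else w,
                 class = class, shared = shared, unique = uniq,
                 assoc_gene = assoc, stringsAsFactors = FALSE)
    }
    truth_enh <- list()
    for (t in tissues) {
      truth_enh[[length(truth_enh) + 1L]] <-
        enh_df(shared_start, t, "enhancer", TRUE, FALSE, NA_character_)
      truth_enh[[length(truth_enh) + 1L]] <-
        enh_df(unique_start[[t]], t, "enhancer", FALSE, TRUE, NA_character_)
    }
    truth_enh[[length(truth_enh) + 1L]] <-
      enh_df(flank_start, config$target_tissue, "enhancer", FALSE, TRUE,
             flank_genes)
    truth_enh[[length(truth_enh) + 1L]] <-
      enh_df(decoy_start, config$target_tissue, "decoy", FALSE, FALSE,
             NA_character_)
    truth_enh <- do.call(rbind, truth_enh)
    truth_enh$name <- sprintf("pk%04d", seq_len(nrow(truth_enh)))

    mk_peaks <- function(df, mark, tissue) {
      peak_set(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                          name = df$name,
                          score = stats::rgamma(nrow(df), config$gamma_shape,
                                                scale = config$gamma_scale)),
               mark = mark, tissue = tissue)
    }
    h3k27ac <- lapply(tissues, function(t)
      mk_peaks(truth_enh[truth_enh$tissue == t, ], "H3K27ac", t))
    names(h3k27ac) <- tissues
    h3k4me1 <- lapply(tissues, function(t)
      mk_peaks(truth_enh[truth_enh$tissue == t & truth_enh$class == "enhancer", ],
               "H3K4me1", t))
    names(h3k4me1) <- tissues

    n_bound <- round(config$tf_bound_frac * length(annotation$cs_coding_ids))
    tf_bound_genes <- annotation$cs_coding_ids[seq_len(n_bound)]
    tf_tss <- g$tss[match(tf_bound_genes, g$gene_id)]
    distal_idx <- seq_len(n_flank)[seq_len(n_flank) %% 3L == 1L]
    tf <- peak_set(data.frame(
      chrom = config$chrom,
      start = c(tf_tss - 300, flank_start[distal_idx]),
      end = c(tf_tss + 200, flank_start[distal_idx] + 400),
      name = c(paste0("tf_", tf_bound_genes),
               paste0("tfd_", seq_along(distal_idx))),
      score = stats::rgamma(n_bound + length(distal_idx), config$gamma_shape,
                            scale = config$gamma_scale)),
      mark = config$tf_mark, tissue = config$target_tissue)

    truth <- list(enhancers = truth_enh, tf_bound_genes = tf_bound_genes,
                  flank_genes = flank_genes,
                  unique_target = truth_enh[
                    truth_enh$tissue == config$target_tissue &
                      truth_enh$class == "enhancer" & truth_enh$unique, ,
                    drop = FALSE])
    validate_planted_peaks(truth_enh, models, k4me3, tissues)
    list(h3k27ac = h3k27ac, h3k4me3 = k4me3, h3k4me1 = h3k4me1, tf = tf,
         truth = truth)
  })
}

# Planted-feature validator: re-checks each planted peak class against the
# distance/uniqueness rules it is supposed to satisfy.
validate_planted_peaks <- function(truth_enh, models, k4me3, tissues,
                                   tss_min_dist = 3000, merge_gap = 1000) {
  tss_gr <- points_to_granges(models$genes$chrom, models$genes$tss)
  for (t in tissues) {
    te <- truth_enh[truth_enh$tissue == t, , drop = FALSE]
    enh <- te[te$class == "enhancer", , drop = FALSE]
    if (nrow(enh)) {
      eg <- intervals_to_granges(enh$chrom, enh$start, enh$end)
      if (any(min_gap_to_nearest(eg, tss_gr) <= tss_min_dist))
        stop("planted enhancer violates the TSS distance rule")
      if (any(min_gap_to_nearest(eg, peaks_to_granges(k4me3[[t]])) <= tss_min_dist))
        stop("planted enhancer violates the H3K4me3 distance rule")
      gaps <- diff(sort(enh$start))
      if (any(gaps <= max(enh$end - enh$start) + merge_gap))
        stop("planted enhancers closer than the merge gap")
      uq <- enh[enh$unique, , drop = FALSE]
      if (nrow(uq)) {
        other <- truth_enh[truth_enh$tissue != t &
                             truth_enh$class == "enhancer", , drop = FALSE]
        if (nrow(other)) {
          hits <- GenomicRanges::findOverlaps(
            intervals_to_granges(uq$chrom, uq$start, uq$end),
            intervals_to_granges(other$chrom, other$start, other$end))
          if (length(hits))
            stop("planted unique enhancer overlaps another tissue's enhancer")
        }
      }
    }
    dec <- te[te$class == "decoy", , drop = FALSE]
    if (nrow(dec)) {
      dg <- intervals_to_granges(dec$chrom, dec$start, dec$end)
      if (any(min_gap_to_nearest(dg, tss_gr) > tss_min_dist))
        stop("planted decoy is not promoter-proximal")
    }
  }
  invisible(TRUE)
}

#' Simulate a co-expressed gene pair across tissues
#'
#' Draws two log2-scale tissue vectors from a bivariate normal with the
#' given latent Pearson correlation and exponentiates to FPKM. With
#' `latent_r = 1` the two log2 vectors are affinely identical, so their
#' sample correlation is exactly 1.
#'
#' @param n_tissues Number of tissues (default 22).
#' @param latent_r Latent Pearson correlation on the log2 scale.
#' @param mean_log2,sd_log2 Marginal mean and SD of the log2 profiles.
#' @param seed RNG seed.
#' @return List with `fpkm` (2 x tissues matrix, rows `geneA`, `geneB`),
#'   `log2` (the latent log2 matrix) and `latent_r`.
#' @export
simulate_coexpressed_pair <- function(n_tissues = 22, latent_r = 0.8,
                                      mean_log2 = 2, sd_log2 = 2, seed = 1) {
  if (abs(latent_r) > 1) stop("|latent_r| must be <= 1")
  with_seed(seed, {
    z1 <- stats::rnorm(n_tissues)
    z2 <- stats::rnorm(n_tissues)
    la <- mean_log2 + sd_log2 * z1
    lb <- mean_log2 + sd_log2 * (latent_r * z1 + sqrt(1 - latent_r^2) * z2)
    l <- rbind(geneA = la, geneB = lb)
    colnames(l) <- sprintf("t%02d", seq_len(n_tissues))
    list(fpkm = 2^l, log2 = l, latent_r = latent_r)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_annotation()], [simulate_expression()] and
#' [simulate_peaks()] under one configuration and returns everything the
#' pipeline consumes, plus the planted truth.
#'
#' @param config A `sim_config`.
#' @return List with `config`, `annotation`, `expression`, `metadata` (via
#'   the `expression_set`), `expr_truth`, `means`, `peaks`.
#' @export
simulate_study <- function(config = sim_config()) {
  annotation <- simulate_annotation(config)
  expr <- simulate_expression(config, annotation)
  peaks <- simulate_peaks(config, annotation)
  list(config = config, annotation = annotation,
       expression = expr$expression, expr_truth = expr$truth,
       means = expr$means, peaks = peaks)
}

#' Write a simulated study to a directory of standard-format files
#'
#' Emits `expression.tsv`, `metadata.tsv`, `genes.gtf`, `retention.tsv`,
#' one `<mark>_<tissue>.bed` per peak track, and truth TSVs
#' (`truth_expression.tsv`, `truth_enhancers.tsv`, `truth_lncrna.tsv`).
#' Output bytes are a pure function of the configuration.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_expression(study$expression, fp("expression.tsv"), fp("metadata.tsv"))
  write_gene_models(study$annotation$models, fp("genes.gtf"))
  ret <- study$annotation$retention
  utils::write.table(ret, fp("retention.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mark_label <- c(h3k27ac = "H3K27ac", h3k4me3 = "H3K4me3",
                  h3k4me1 = "H3K4me1")
  for (mark in names(mark_label)) {
    for (t in names(study$peaks[[mark]]))
      write_peaks_bed(study$peaks[[mark]][[t]],
                      fp(sprintf("%s_%s.bed", mark_label[[mark]], t)))
  }
  write_peaks_bed(study$peaks$tf,
                  fp(sprintf("%s_%s.bed", study$config$tf_mark,
                             study$config$target_tissue)))
  utils::write.table(study$expr_truth, fp("truth_expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$peaks$truth$enhancers, fp("truth_enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotation$lnc_truth, fp("truth_lncrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
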