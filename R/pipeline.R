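# Pipeline orchestration: one validated configuration drives all stages and
# emits a structured results directory plus a machine-readable summary.
# Outputs are pure functions of (inputs, config): no timestamps, locale- or
# platform-dependent content is ever written.

.pipeline_defaults <- function() list(
  target_tissue = "cartilage",
  fpkm_min = 1, spm_min = 0.9, preferential_band = c(0.7, 0.9),
  tss_min_dist = 3000, merge_gap = 1000,
  promoter_flank = 2000, intensity_quantile = 0.25,
  pseudocount = 0.1,
  basal_up = 5000, basal_down = 1000, max_extension = 1e6,
  tf_mark = "SOX9",
  coexpr_pair = NULL, rank_query = NULL,
  expression = NULL, metadata = NULL, gtf = NULL, retention = NULL,
  peaks_dir = NULL, simulate = FALSE, seed = 1)

#' Build and validate a pipeline configuration
#'
#' Accepts either file inputs (`expression`, `metadata`, `gtf`, optional
#' `retention`, and `peaks_dir` containing `<mark>_<tissue>.bed` tracks) or
#' `simulate = TRUE`, in which case a synthetic study is generated from
#' `sim` (a [sim_config()]) and written under the run directory. Unknown
#' keys and out-of-domain thresholds are rejected before any computation.
#'
#' @param ... Named configuration entries; see `Details` and
#'   [run_pipeline()].
#' @param sim Optional [sim_config()] used when `simulate = TRUE`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., sim = NULL) {
  cfg <- .pipeline_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg[["sim"]] <- sim
  with(cfg, {
    stopifnot(fpkm_min >= 0, pseudocount >= 0, tss_min_dist >= 0,
              merge_gap >= 0, promoter_flank > 0,
              basal_up >= 0, basal_down >= 0, max_extension >= 0)
    if (spm_min < 0 || spm_min > 1)
      stop("spm_min must be in [0, 1]")
    if (intensity_quantile < 0 || intensity_quantile > 1)
      stop("intensity_quantile must be in [0, 1]")
    if (length(preferential_band) != 2L ||
        any(preferential_band < 0 | preferential_band > 1) ||
        preferential_band[1] >= preferential_band[2])
      stop("preferential_band must be [lo, hi) within [0, 1]")
  })
  if (isTRUE(cfg$simulate) && is.null(cfg[["sim"]]))
    cfg[["sim"]] <- sim_config(seed = cfg$seed,
                               target_tissue = cfg$target_tissue,
                               tf_mark = cfg$tf_mark)
  if (!isTRUE(cfg$simulate)) {
    for (k in c("expression", "metadata", "gtf", "peaks_dir"))
      if (is.null(cfg[[k]]))
        stop("config key '", k, "' required when simulate = FALSE")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a plain-text key = value file
#'
#' One `key = value` entry per line; `#` comments and `[section]` headers
#' are ignored; comma-separated values become vectors; `true`/`false`
#' become logicals; numeric-looking values become numbers. Unknown keys are
#' rejected.
#'
#' @param path Path to the config file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[.*\\]$", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- lapply(kv, function(x) {
    v <- trimws(strsplit(x[[3L]], ",", fixed = TRUE)[[1L]])
    if (all(tolower(v) %in% c("true", "false"))) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) return(num)
    v
  })
  names(vals) <- keys
  do.call(pipeline_config, vals)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_peaks_dir <- function(dir, mark, tissues) {
  out <- list()
  for (t in tissues) {
    f <- file.path(dir, sprintf("%s_%s.bed", mark, t))
    if (file.exists(f)) out[[t]] <- read_peaks_bed(f, mark, t)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order: tissue selectivity (replicate averaging, abundance
#' filter, SPM, selective/preferential calls), lncRNA exclusion filters and
#' coding-gene neighbors, active-enhancer prediction with tissue-unique
#' determination and enhancer-gene association, promoter TF occupancy with
#' intensity stratification and a TSS profile, and co-expression reports.
#' Each stage writes its tables under `outdir` and contributes record
#' counts to `summary.json`; any stage failure aborts with the stage name
#' and cause. Rerunning an identical configuration reproduces every output
#' byte for byte.
#'
#' @param config A `pipeline_config` (or arguments for one, via `...`).
#' @param outdir Output directory.
#' @param ... Passed to [pipeline_config()] when `config` is missing.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = NULL, outdir, ...) {
  if (is.null(config)) config <- pipeline_config(...)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  summary <- list(parameters = config[setdiff(names(config), "sim")],
                  seed = config$seed, stages = list())

  # ---- inputs ----
  inputs <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      study <- simulate_study(config[["sim"]])
      write_simulation(study, file.path(outdir, "inputs"))
      marks <- c("H3K27ac", "H3K4me3")
      list(expr = study$expression, models = study$annotation$models,
           retention = study$annotation$retention,
           h3k27ac = study$peaks$h3k27ac, h3k4me3 = study$peaks$h3k4me3,
           tf = study$peaks$tf, study = study)
    } else {
      expr <- read_expression(config$expression, config$metadata)
      models <- read_gene_models(config$gtf)
      retention <- if (!is.null(config$retention))
        utils::read.table(config$retention, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE) else NULL
      tissues <- unique(expr$samples$tissue)
      h3k27ac <- read_peaks_dir(config$peaks_dir, "H3K27ac", tissues)
      h3k4me3 <- read_peaks_dir(config$peaks_dir, "H3K4me3", tissues)
      tf_file <- file.path(config$peaks_dir,
                           sprintf("%s_%s.bed", config$tf_mark,
                                   config$target_tissue))
      tf <- if (file.exists(tf_file))
        read_peaks_bed(tf_file, config$tf_mark, config$target_tissue)
      else NULL
      list(expr = expr, models = models, retention = retention,
           h3k27ac = h3k27ac, h3k4me3 = h3k4me3, tf = tf, study = NULL)
    }
  })
  models <- inputs$models
  g <- models$genes

  # ---- stage 1: selectivity ----
  sel <- stage("selectivity", {
    res <- tissue_selectivity(inputs$expr, config$target_tissue,
                              spm_min = config$spm_min,
                              fpkm_min = config$fpkm_min,
                              preferential_band = config$preferential_band)
    write_tsv(res$calls, file.path(outdir, "selective_calls.tsv"))
    res
  })
  n_sel <- sum(sel$calls$class == "selective")
  summary$stages$selectivity <- list(
    genes_in = nrow(inputs$expr$values),
    genes_after_abundance_filter = nrow(sel$profile),
    selective = n_sel,
    preferential = sum(sel$calls$class == "preferential"))
  message(sprintf("[selectivity] %d genes in, %d pass abundance, %d selective",
                  nrow(inputs$expr$values), nrow(sel$profile), n_sel))

  # ---- stage 2: lncRNA filters ----
  lnc <- stage("lncrna", {
    sel_ids <- sel$calls$gene_id[sel$calls$class == "selective"]
    lnc_ids <- intersect(sel_ids, g$gene_id[g$biotype == "lncRNA"])
    full_profile <- average_by_tissue(inputs$expr)
    coding_ids <- intersect(g$gene_id[g$biotype == "protein_coding"],
                            rownames(full_profile))
    expressed <- coding_ids[apply(full_profile[coding_ids, , drop = FALSE],
                                  1L, max) >= config$fpkm_min]
    flags <- filter_lncrnas(lnc_ids, models, expressed, inputs$retention)
    kept <- flags$gene_id[!flags$excluded]
    nb <- neighboring_genes(kept, models, config$basal_up, config$basal_down,
                            config$max_extension)
    write_tsv(flags, file.path(outdir, "lncrna_filters.tsv"))
    write_tsv(nb, file.path(outdir, "lncrna_neighbors.tsv"))
    list(flags = flags, kept = kept, neighbors = nb)
  })
  summary$stages$lncrna <- list(
    selective_lncrna_in = nrow(lnc$flags),
    excluded = sum(lnc$flags$excluded),
    selective_lncrna_out = length(lnc$kept))
  message(sprintf("[lncrna] %d selective lncRNA in, %d excluded, %d kept",
                  nrow(lnc$flags), sum(lnc$flags$excluded), length(lnc$kept)))

  # ---- stage 3: enhancers ----
  enh <- stage("enhancers", {
    tissues <- names(inputs$h3k27ac)
    empty_k4 <- peak_set(data.frame(chrom = character(), start = integer(),
                                    end = integer()), "H3K4me3", "none")
    active <- lapply(tissues, function(t) {
      cls <- classify_active_enhancers(inputs$h3k27ac[[t]], g,
                                       inputs$h3k4me3[[t]] %||% empty_k4,
                                       config$tss_min_dist)
      merge_enhancers(cls, config$merge_gap)
    })
    names(active) <- tissues
    for (t in tissues)
      write_tsv(as.data.frame(active[[t]]),
                file.path(outdir, sprintf("active_enhancers_%s.tsv", t)))
    target <- config$target_tissue
    uniq <- if (target %in% tissues)
      tissue_unique(active[[target]], active[setdiff(tissues, target)])
    else NULL
    assoc <- flanked <- NULL
    if (!is.null(uniq)) {
      write_tsv(as.data.frame(uniq),
                file.path(outdir, "unique_enhancers.tsv"))
      assoc <- associate_enhancers_to_genes(uniq, models, config$basal_up,
                                            config$basal_down,
                                            config$max_extension)
      write_tsv(assoc, file.path(outdir, "enhancer_gene_associations.tsv"))
      cs_coding <- intersect(sel$calls$gene_id[sel$calls$class == "selective"],
                             g$gene_id[g$biotype == "protein_coding"])
      flanked <- genes_with_enhancers(cs_coding, assoc)
    }
    list(active = active, unique = uniq, assoc = assoc, flanked = flanked)
  })
  summary$stages$enhancers <- list(
    tissues = length(enh$active),
    active_target = if (!is.null(enh$unique))
      nrow(enh$active[[config$target_tissue]]) else 0L,
    unique_target = if (!is.null(enh$unique)) nrow(enh$unique) else 0L,
    cs_genes_flanked = enh$flanked$count %||% 0L,
    cs_genes_flanked_fraction = enh$flanked$fraction %||% NA_real_)
  message(sprintf("[enhancers] %d target-active, %d target-unique",
                  summary$stages$enhancers$active_target,
                  summary$stages$enhancers$unique_target))

  # ---- stage 4: promoter occupancy ----
  prom <- stage("promoters", {
    if (is.null(inputs$tf)) return(NULL)
    win <- promoter_windows(models, config$promoter_flank)
    bound <- call_bound_genes(win, inputs$tf)
    cs_coding <- intersect(sel$calls$gene_id[sel$calls$class == "selective"],
                           g$gene_id[g$biotype == "protein_coding"])
    summ <- summarize_bound(bound, cs_coding)
    strong <- strong_peaks(inputs$tf, config$intensity_quantile)
    cs_tss <- g[g$gene_id %in% cs_coding, c("chrom", "tss", "strand")]
    profile <- if (nrow(cs_tss))
      tss_profile(inputs$tf, cs_tss, config$promoter_flank) else NULL
    write_tsv(bound, file.path(outdir, "promoter_bound.tsv"))
    write_tsv(as.data.frame(strong), file.path(outdir, "strong_tf_peaks.tsv"))
    if (!is.null(profile))
      write_tsv(data.frame(offset = as.integer(names(profile)),
                           occupancy = profile),
                file.path(outdir, "tss_profile.tsv"))
    list(bound = bound, summary = summ, strong = strong, profile = profile)
  })
  summary$stages$promoters <- if (is.null(prom)) list(skipped = TRUE) else list(
    cs_genes_bound = prom$summary$count,
    cs_genes_bound_fraction = prom$summary$fraction,
    strong_peaks = nrow(prom$strong),
    tf_peaks = nrow(inputs$tf))
  if (!is.null(prom))
    message(sprintf("[promoters] %d/%s CS genes TF-bound",
                    prom$summary$count,
                    format(prom$summary$fraction, digits = 3)))

  # ---- stage 5: co-expression ----
  cox <- stage("coexpr", {
    full_profile <- average_by_tissue(inputs$expr)
    pair_rep <- NULL
    pair <- config$coexpr_pair
    if (is.null(pair) && isTRUE(config$simulate) &&
        !is.null(config[["sim"]]$coexpr_pairs) && nrow(config[["sim"]]$coexpr_pairs))
      pair <- c(config[["sim"]]$coexpr_pairs$gene_a[1L],
                config[["sim"]]$coexpr_pairs$gene_b[1L])
    if (!is.null(pair) && all(pair %in% rownames(full_profile))) {
      pair_rep <- gene_pair_correlation(full_profile, pair[1L], pair[2L],
                                        fpkm_min = config$fpkm_min,
                                        pseudocount = config$pseudocount)
      write_tsv(data.frame(gene_a = pair_rep$gene_a, gene_b = pair_rep$gene_b,
                           r_all = pair_rep$r_all,
                           r_expressed = pair_rep$r_expressed,
                           n_all = pair_rep$n_all,
                           n_expressed = pair_rep$n_expressed),
                file.path(outdir, "coexpression_pair.tsv"))
    }
    ranked <- NULL
    query <- config$rank_query %||% (if (!is.null(pair)) pair[2L])
    if (!is.null(query) && query %in% rownames(full_profile)) {
      ranked <- rank_correlated_genes(full_profile, query,
                                      config$pseudocount)
      write_tsv(ranked, file.path(outdir, "rank_correlated.tsv"))
    }
    qc <- sample_correlation_matrix(inputs$expr, config$pseudocount,
                                    config$fpkm_min)
    write_tsv(data.frame(sample_id = rownames(qc),
                         as.data.frame(unclass(qc), check.names = FALSE)),
              file.path(outdir, "sample_correlation.tsv"))
    list(pair = pair_rep, ranked = ranked, qc = qc)
  })
  summary$stages$coexpr <- list(
    pair_r_all = cox$pair$r_all %||% NA_real_,
    pair_r_expressed = cox$pair$r_expressed %||% NA_real_,
    pair_n_expressed = cox$pair$n_expressed %||% NA_integer_,
    qc_min_r = min(cox$qc, na.rm = TRUE))

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
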