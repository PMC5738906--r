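#' Read a gene x sample FPKM expression table with sample metadata
#'
#' The expression table is a TSV whose header row names the samples and whose
#' first column holds gene identifiers; values are FPKM (fragments per
#' kilobase of exon per million mapped fragments) and must be non-negative.
#' The metadata table is a TSV with columns `sample_id` and `tissue`; it must
#' list every sample exactly once, and every listed sample must be present in
#' the expression table.
#'
#' @param table_path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An object of class `expression_set`: a list with `values` (numeric
#'   matrix, genes x samples) and `samples` (data.frame with `sample_id`,
#'   `tissue`, ordered as the matrix columns).
#' @export
read_expression <- function(table_path, metadata_path) {
  tab <- utils::read.table(table_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("expression table needs a gene-id column plus >=1 sample column")
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric expression value(s) in table")
  if (anyNA(values))
    stop("missing expression value(s) in table")
  if (any(values < 0))
    stop("negative expression value(s): FPKM must be >= 0")
  rownames(values) <- gene_ids
  sample_ids <- colnames(values)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in expression table header")

  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  if (!all(c("sample_id", "tissue") %in% colnames(meta)))
    stop("metadata must have columns 'sample_id' and 'tissue'")
  meta$sample_id <- as.character(meta$sample_id)
  meta$tissue <- as.character(meta$tissue)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id(s) in metadata")
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta))
    stop("sample(s) lacking metadata: ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(meta$sample_id, sample_ids)
  if (length(extra_meta))
    stop("metadata lists sample(s) absent from the table: ",
         paste(extra_meta, collapse = ", "))
  meta <- meta[match(sample_ids, meta$sample_id), c("sample_id", "tissue")]
  rownames(meta) <- NULL
  expression_set(values, meta)
}

#' Construct an expression set from a matrix and metadata
#'
#' @param values Numeric non-negative matrix with gene-id rownames and
#'   sample-id colnames.
#' @param samples data.frame with columns `sample_id`, `tissue` covering every
#'   column of `values` exactly once.
#' @return An `expression_set` object.
#' @export
expression_set <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("FPKM values must be >= 0")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!setequal(samples$sample_id, colnames(values)) ||
      nrow(samples) != ncol(values))
    stop("metadata sample_ids must match matrix columns exactly once each")
  samples <- samples[match(colnames(values), samples$sample_id),
                     c("sample_id", "tissue")]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (%d tissues)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$tissue))))
  invisible(x)
}

#' Write an expression set back to TSV
#'
#' Inverse of [read_expression()]; writing what was read reproduces a
#' canonical-form input byte for byte.
#'
#' @param x An `expression_set`.
#' @param table_path Output path for the expression TSV.
#' @param metadata_path Optional output path for the metadata TSV.
#' @return Invisibly, `table_path`.
#' @export
write_expression <- function(x, table_path, metadata_path = NULL) {
  stopifnot(inherits(x, "expression_set"))
  header <- paste(c("gene_id", colnames(x$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i], format_num(x$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), table_path)
  if (!is.null(metadata_path)) {
    writeLines(c("sample_id\ttissue",
                 paste(x$samples$sample_id, x$samples$tissue, sep = "\t")),
               metadata_path)
  }
  invisible(table_path)
}

#' Read a BED file of peaks into a peak set
#'
#' BED coordinates are 0-based half-open and are kept that way internally.
#' Column 4 (name) defaults to `peak<i>`; column 5 (score) is read as the
#' binding intensity and defaults to 0 when absent.
#'
#' @param path Path to a BED file with >= 3 columns.
#' @param mark Label for the assayed mark (e.g. `"H3K27ac"`, a TF name).
#' @param tissue Tissue/cell-type label.
#' @return A `peak_set`: data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, sorted by (chrom, start, end), with attributes `mark`
#'   and `tissue`.
#' @export
read_peaks_bed <- function(path, mark, tissue) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), name = character(),
                               score = numeric()), mark, tissue))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad[1L]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d: non-integer coordinate", bad[1L]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("malformed BED line %d: start >= end", bad[1L]))
  name <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                 character(1)),
                 paste0("peak", seq_along(fields)))
  score <- rep(0, length(fields))
  has5 <- n >= 5L
  if (any(has5)) {
    raw <- vapply(fields[has5], `[[`, character(1), 5L)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(has5)[is.na(val)]
    if (length(bad))
      stop(sprintf("malformed BED line %d: non-numeric score", bad[1L]))
    score[has5] <- val
  }
  if (any(score < 0)) stop("negative peak intensity")
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      name = name, score = score,
                      stringsAsFactors = FALSE), mark, tissue)
}

#' Construct a peak set
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`; 0-based half-open coordinates.
#' @param mark,tissue Labels carried as attributes.
#' @return A sorted `peak_set` data.frame.
#' @export
peak_set <- function(df, mark = "peak", tissue = "unknown") {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
  if (is.null(df$name)) df$name <- if (nrow(df)) paste0("peak", seq_len(nrow(df))) else character()
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  if (any(df$start >= df$end)) stop("peak with start >= end")
  if (any(df$score < 0, na.rm = TRUE)) stop("negative peak intensity")
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end", "name", "score")]
  rownames(df) <- NULL
  structure(df, mark = mark, tissue = tissue,
            class = c("peak_set", "data.frame"))
}

#' Write a peak set as BED5
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- if (nrow(peaks)) {
    paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
          format_num(peaks$score), sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Construct gene models from per-gene exon intervals
#'
#' Exons (0-based half-open) are unioned per gene, so overlapping transcript
#' exons collapse; introns are the gaps between consecutive exons. The TSS is
#' the leftmost exon start for `+` strand genes and the rightmost exon end
#' minus one (the last transcribed base) for `-` strand genes.
#'
#' @param genes data.frame with columns `gene_id`, `biotype`
#'   (`protein_coding` or `lncRNA`), `chrom`, `strand` (`+`/`-`).
#' @param exons Named list (by gene_id) of two-column matrices of exon
#'   `start`, `end`.
#' @return A `gene_models` object: list with `genes` (data.frame adding
#'   `start`, `end`, `tss`, `n_exons`), `exons` and `introns` (named lists of
#'   matrices).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "biotype", "chrom", "strand") %in% colnames(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene models")
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand: ", paste(setdiff(genes$strand, c("+", "-")), collapse = ","))
  miss <- setdiff(genes$gene_id, names(exons))
  if (length(miss)) stop("gene with zero exons: ", miss[1L])
  exons <- exons[genes$gene_id]
  exons <- lapply(exons, function(e) {
    e <- matrix(as.numeric(e), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    if (!nrow(e)) stop("gene with zero exons")
    if (any(e[, 1L] >= e[, 2L])) stop("exon with start >= end")
    e <- e[order(e[, 1L]), , drop = FALSE]
    # union of possibly-overlapping transcript exons
    merged <- e[1L, , drop = FALSE]
    for (i in seq_len(nrow(e))[-1L]) {
      if (e[i, 1L] <= merged[nrow(merged), 2L]) {
        merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], e[i, 2L])
      } else merged <- rbind(merged, e[i, , drop = FALSE])
    }
    merged
  })
  introns <- lapply(exons, function(e) {
    if (nrow(e) < 2L)
      return(matrix(numeric(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
    cbind(start = unname(e[-nrow(e), 2L]), end = unname(e[-1L, 1L]))
  })
  genes$start <- vapply(exons, function(e) e[1L, 1L], numeric(1))
  genes$end <- vapply(exons, function(e) e[nrow(e), 2L], numeric(1))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$n_exons <- vapply(exons, nrow, integer(1))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d protein_coding, %d lncRNA)\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              sum(x$genes$biotype == "lncRNA")))
  invisible(x)
}

#' Read gene models from a GTF-like annotation
#'
#' Only `gene`/`transcript`/`exon` features are consumed; attributes must
#' include `gene_id` and a biotype key (`gene_biotype`, `gene_type` or
#' `biotype`). GTF 1-based closed coordinates are converted to the internal
#' 0-based half-open convention on read.
#'
#' @param path Path to the GTF file.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) stop(sprintf("malformed GTF line %d", bad[1L]))
  feat <- vapply(fields, `[[`, character(1), 3L)
  keep <- feat %in% c("gene", "transcript", "exon")
  fields <- fields[keep]; feat <- feat[keep]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1))
  }
  attrs <- vapply(fields, `[[`, character(1), 9L)
  gid <- attr_get(attrs, "gene_id")
  if (anyNA(gid)) stop("GTF feature without gene_id attribute")
  biot <- attr_get(attrs, "gene_biotype")
  biot[is.na(biot)] <- attr_get(attrs[is.na(biot)], "gene_type")
  biot[is.na(biot)] <- attr_get(attrs[is.na(biot)], "biotype")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start1 <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  end1 <- as.numeric(vapply(fields, `[[`, character(1), 5L))
  strand <- vapply(fields, `[[`, character(1), 7L)
  if (anyNA(start1) || anyNA(end1)) stop("malformed GTF coordinates")

  ids <- unique(gid)
  gene_rows <- lapply(ids, function(g) {
    sel <- gid == g
    bt <- stats::na.omit(unique(biot[sel]))
    if (!length(bt)) stop("gene without biotype attribute: ", g)
    st <- unique(strand[sel])
    if (length(st) != 1L || !st %in% c("+", "-"))
      stop("unknown or inconsistent strand for gene ", g)
    data.frame(gene_id = g, biotype = bt[1L], chrom = chrom[sel][1L],
               strand = st, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_rows)
  exons <- lapply(ids, function(g) {
    sel <- gid == g & feat == "exon"
    if (!any(sel)) stop("gene with zero exons: ", g)
    cbind(start = start1[sel] - 1, end = end1[sel])  # to 0-based half-open
  })
  names(exons) <- ids
  gene_models(genes, exons)
}

#' Write gene models as GTF
#'
#' Emits one `gene` line and per-exon `exon` lines per gene, converting the
#' internal 0-based half-open coordinates to GTF 1-based closed.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  out <- character()
  for (i in seq_len(nrow(g))) {
    a <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id[i], g$biotype[i])
    out <- c(out, paste(g$chrom[i], "tissel", "gene", g$start[i] + 1, g$end[i],
                        ".", g$strand[i], ".", a, sep = "\t"))
    e <- models$exons[[g$gene_id[i]]]
    for (j in seq_len(nrow(e))) {
      out <- c(out, paste(g$chrom[i], "tissel", "exon", e[j, 1L] + 1, e[j, 2L],
                          ".", g$strand[i], ".", a, sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}
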