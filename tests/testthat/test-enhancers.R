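simple_tss <- function(pos) data.frame(chrom = "chr1", tss = pos)
empty_k4 <- function() make_peaks(integer(), integer(), mark = "H3K4me3")

test_that("distal classification applies the strict >3 kb rule", {
  pk <- make_peaks(10000, 10500)
  expect_equal(nrow(classify_active_enhancers(pk, simple_tss(20000),
                                              empty_k4())), 1L)  # gap 9500
  expect_equal(nrow(classify_active_enhancers(pk, simple_tss(12000),
                                              empty_k4())), 0L)  # gap 1500
  # gap of exactly 3000 bp fails the strict inequality
  pk <- make_peaks(10000, 10500)
  expect_equal(nrow(classify_active_enhancers(pk, simple_tss(13500),
                                              empty_k4())), 0L)
  expect_equal(nrow(classify_active_enhancers(pk, simple_tss(13501),
                                              empty_k4())), 1L)
  # H3K4me3 peaks exclude symmetrically
  k4 <- make_peaks(12000, 12800, mark = "H3K4me3")
  expect_equal(nrow(classify_active_enhancers(pk, simple_tss(1e6), k4)), 0L)
  k4far <- make_peaks(13501, 14000, mark = "H3K4me3")
  expect_equal(nrow(classify_active_enhancers(pk, simple_tss(1e6), k4far)), 1L)
})

test_that("merging uses an inclusive 1 kb gap and transitive closure", {
  m <- merge_enhancers(make_peaks(c(0, 1400), c(500, 1600)))
  expect_equal(nrow(m), 1L)           # gap 900 <= 1000
  expect_equal(c(m$start, m$end), c(0, 1600))
  m <- merge_enhancers(make_peaks(c(0, 1600), c(500, 1700)))
  expect_equal(nrow(m), 2L)           # gap 1100 > 1000
  m <- merge_enhancers(make_peaks(c(0, 1500, 3000), c(500, 2000, 3400)))
  expect_equal(nrow(m), 1L)           # chained: 0-500 .. 1500-2000 .. 3000-3400
})

test_that("merge agrees with a union-find oracle and is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    start <- sample.int(100000, n)
    end <- start + sample.int(800, n, replace = TRUE)
    pk <- make_peaks(start, end)
    m <- merge_enhancers(pk)
    oracle <- oracle_merge(start, end, 1000)
    expect_equal(cbind(m$start, m$end), unname(oracle))
    # idempotence
    pk2 <- peak_set(data.frame(chrom = m$chrom, start = m$start, end = m$end))
    m2 <- merge_enhancers(pk2)
    expect_equal(cbind(m2$start, m2$end), cbind(m$start, m$end))
    # permutation invariance
    perm <- sample.int(n)
    mp <- merge_enhancers(make_peaks(start[perm], end[perm]))
    expect_equal(cbind(mp$start, mp$end), cbind(m$start, m$end))
  }
})

test_that("tissue-unique selection removes any base-pair overlap", {
  t1 <- merge_enhancers(make_peaks(c(1000, 50000), c(2000, 51000)))
  only <- merge_enhancers(make_peaks(50999, 60000, tissue = "other"))
  u <- tissue_unique(t1, list(only))  # 1 bp overlap with the second enhancer
  expect_equal(u$start, 1000)
  adjacent <- merge_enhancers(make_peaks(51000, 60000, tissue = "other"))
  u2 <- tissue_unique(t1, list(adjacent))  # half-open: no shared base
  expect_equal(nrow(u2), 2L)
  # identity with no comparison tissues; subset and anti-monotone
  expect_equal(nrow(tissue_unique(t1, list())), nrow(t1))
  u3 <- tissue_unique(t1, list(only, adjacent))
  expect_true(all(u3$start %in% t1$start))
  expect_lte(nrow(u3), nrow(u))
})

test_that("classification and merge commute with chromosome restriction", {
  set.seed(21)
  pk <- peak_set(data.frame(
    chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
    start = s <- sample.int(200000, 100), end = s + 500))
  tss <- data.frame(chrom = c("chr1", "chr2"), tss = c(50000, 120000))
  k4 <- empty_k4()
  full <- merge_enhancers(classify_active_enhancers(pk, tss, k4))
  per_chrom <- do.call(rbind, lapply(c("chr1", "chr2"), function(cc) {
    sub <- peak_set(as.data.frame(pk)[pk$chrom == cc, ])
    as.data.frame(merge_enhancers(classify_active_enhancers(
      sub, tss[tss$chrom == cc, , drop = FALSE], k4)))[, c("chrom", "start", "end")]
  }))
  expect_equal(as.data.frame(full)[, c("chrom", "start", "end")], per_chrom)
})

test_that("planted 7-tissue panel returns exactly the planted unique set", {
  cfg <- sim_config(seed = 17)
  st <- simulate_study(cfg)
  g <- st$annotation$models$genes
  tissues <- names(st$peaks$h3k27ac)
  active <- lapply(tissues, function(t)
    merge_enhancers(classify_active_enhancers(
      st$peaks$h3k27ac[[t]], g, st$peaks$h3k4me3[[t]])))
  names(active) <- tissues
  truth <- st$peaks$truth$enhancers
  # active set equals planted enhancers exactly; decoys never survive
  for (t in tissues) {
    planted <- truth[truth$tissue == t & truth$class == "enhancer", ]
    planted <- planted[order(planted$start), ]
    expect_equal(active[[t]]$start, planted$start)
    expect_equal(active[[t]]$end, planted$end)
  }
  uq <- tissue_unique(active$cartilage, active[setdiff(tissues, "cartilage")])
  planted_uq <- st$peaks$truth$unique_target
  expect_setequal(uq$start, planted_uq$start)
})

test_that("enhancer-gene association respects domains and the 1 Mb cap", {
  g <- data.frame(gene_id = "P1", biotype = "protein_coding",
                  chrom = "chr1", strand = "+")
  m <- gene_models(g, list(P1 = cbind(2000000, 2005000)))
  near <- merge_enhancers(make_peaks(2049800, 2050600))   # midpoint 50 kb away
  far <- merge_enhancers(make_peaks(3200000, 3200600))    # beyond the cap
  expect_equal(associate_enhancers_to_genes(near, m)$gene_id, "P1")
  expect_equal(associate_enhancers_to_genes(near, m)$distance, 50200)
  expect_equal(nrow(associate_enhancers_to_genes(far, m)), 0L)
})

test_that("flanked-gene fraction counts planted associations", {
  # 10 far-spaced genes; enhancers planted 20 kb from 6 of them
  n <- 10
  tss <- 1e6 + (0:(n - 1)) * 3e6
  g <- data.frame(gene_id = sprintf("G%02d", 1:n),
                  biotype = "protein_coding", chrom = "chr1", strand = "+")
  ex <- lapply(tss, function(p) cbind(p, p + 5000))
  names(ex) <- g$gene_id
  m <- gene_models(g, ex)
  enh <- merge_enhancers(make_peaks(tss[1:6] + 20000, tss[1:6] + 20800))
  assoc <- associate_enhancers_to_genes(enh, m)
  res <- genes_with_enhancers(g$gene_id, assoc)
  expect_equal(res$count, 6L)
  expect_equal(res$fraction, 0.6)
})
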