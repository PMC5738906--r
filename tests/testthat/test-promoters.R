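four_gene_models <- function(tss = c(10000, 50000, 90000, 130000),
                             strand = rep("+", 4)) {
  g <- data.frame(gene_id = sprintf("G%d", 1:4), biotype = "protein_coding",
                  chrom = "chr1", strand = strand)
  ex <- lapply(seq_along(tss), function(i) {
    if (strand[i] == "+") cbind(tss[i], tss[i] + 3000)
    else cbind(tss[i] - 3000, tss[i] + 1)
  })
  names(ex) <- g$gene_id
  gene_models(g, ex)
}

test_that("promoter windows are symmetric, clipped and strand-agnostic", {
  m <- four_gene_models()
  w <- promoter_windows(m)
  expect_equal(unlist(w[1, c("start", "end")], use.names = FALSE),
               c(8000, 12000))
  m2 <- four_gene_models(tss = c(500, 50000, 90000, 130000))
  w2 <- promoter_windows(m2)
  expect_equal(unlist(w2[1, c("start", "end")], use.names = FALSE), c(0, 2500))
  m3 <- four_gene_models(strand = c("-", "+", "+", "+"),
                         tss = c(10000, 50000, 90000, 130000))
  w3 <- promoter_windows(m3)
  expect_equal(unlist(w3[1, c("start", "end")], use.names = FALSE),
               c(8000, 12000))
})

test_that("bound calls use half-open overlap and summarize fractions", {
  m <- four_gene_models()
  w <- promoter_windows(m)
  expect_true(call_bound_genes(w, make_peaks(11500, 11800))$bound[1])
  # peak starting exactly at the window end shares no base
  expect_false(call_bound_genes(w, make_peaks(12000, 12300))$bound[1])
  expect_true(call_bound_genes(w, make_peaks(11999, 12300))$bound[1])
  # 3 of 4 genes bound -> fraction 0.75
  pk <- make_peaks(c(10000, 50000, 90000), c(10100, 50100, 90100))
  bound <- call_bound_genes(w, pk)
  s <- summarize_bound(bound, m$genes$gene_id)
  expect_equal(s$count, 3L)
  expect_equal(s$fraction, 0.75)
})

test_that("bound calls are monotone in the promoter flank", {
  m <- four_gene_models()
  pk <- make_peaks(c(7000, 52100), c(7500, 52600))
  for (flank in c(500, 1000, 2000, 4000)) {
    b_small <- call_bound_genes(promoter_windows(m, flank), pk)$bound
    b_big <- call_bound_genes(promoter_windows(m, flank * 2), pk)$bound
    expect_true(all(b_big[b_small]))  # widening never loses a call
  }
})

test_that("strong-peak stratification follows the interpolated quantile", {
  pk <- make_peaks(c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
                   score = c(1, 2, 3, 4))
  s <- strong_peaks(pk, 0.25)
  expect_setequal(s$score, c(2, 3, 4))  # quantile(0.25) = 1.75
  # all-equal intensities: strict > empties the set
  pk_eq <- make_peaks(c(0, 1000), c(500, 1500), score = c(5, 5))
  expect_equal(nrow(strong_peaks(pk_eq, 0.25)), 0L)
  # q = 0 keeps everything above the minimum
  expect_setequal(strong_peaks(pk, 0)$score, c(2, 3, 4))
  expect_equal(nrow(strong_peaks(pk, 1)), 0L)
  # subset, non-increasing in q
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                  function(q) nrow(strong_peaks(pk, q)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(strong_peaks(pk, 0.5)$score %in% pk$score))
  pk_na <- make_peaks(0, 500, score = NA_real_)
  expect_error(strong_peaks(pk_na), "intensities missing")
})

test_that("TSS profiles equal base-resolution averaging", {
  tss <- data.frame(chrom = "chr1", tss = 10000, strand = "+")
  pk <- make_peaks(9950, 10050)
  prof <- tss_profile(pk, tss, half_window = 2000, bin = 50)
  expect_equal(length(prof), 80L)
  expect_equal(sum(prof > 0), 2L)  # covers exactly bins [-50,0) and [0,50)
  expect_equal(unname(prof[c("-50", "0")]), c(1, 1))
  # no peaks: all-zero
  expect_equal(unname(tss_profile(make_peaks(integer(), integer()), tss)),
               rep(0, 80))
  # random instances vs the per-base oracle, with strand flipping
  for (seed in 1:3) {
    set.seed(seed)
    tssr <- data.frame(chrom = "chr1",
                       tss = sample(5000:20000, 4),
                       strand = sample(c("+", "-"), 4, replace = TRUE))
    st <- sample(3000:22000, 15)
    pkr <- make_peaks(st, st + sample(100:800, 15, replace = TRUE))
    expect_equal(unname(tss_profile(pkr, tssr, 2000, 50)),
                 oracle_tss_profile(pkr, tssr, 2000, 50), tolerance = 1e-12)
  }
})

test_that("profile mass is conserved under TSS relabelling", {
  set.seed(5)
  tssr <- data.frame(chrom = "chr1", tss = sample(5000:20000, 6),
                     strand = "+")
  st <- sample(3000:22000, 20)
  pkr <- make_peaks(st, st + 300)
  p1 <- tss_profile(pkr, tssr)
  p2 <- tss_profile(pkr, tssr[sample(1:6), ])
  expect_equal(sum(p1), sum(p2), tolerance = 1e-12)
})
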