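lnc_fixture <- function(lnc_strand = "+", coding_strand = "+",
                        lnc_iv = c(100, 200),
                        coding_exons = cbind(c(150, 400), c(250, 500))) {
  g <- data.frame(gene_id = c("LNC1", "PC1"),
                  biotype = c("lncRNA", "protein_coding"),
                  chrom = "chr1", strand = c(lnc_strand, coding_strand))
  gene_models(g, list(LNC1 = cbind(lnc_iv[1], lnc_iv[2]),
                      PC1 = coding_exons))
}

test_that("sense exonic overlap needs same strand and expression", {
  m <- lnc_fixture()
  expect_true(flag_sense_exonic_overlap("LNC1", m, "PC1"))
  expect_false(flag_sense_exonic_overlap("LNC1", m, character()))  # not expressed
  m2 <- lnc_fixture(coding_strand = "-")
  expect_false(flag_sense_exonic_overlap("LNC1", m2, "PC1"))  # antisense exempt
  m3 <- lnc_fixture(lnc_iv = c(260, 300))  # falls in the intron, no exon overlap
  expect_false(flag_sense_exonic_overlap("LNC1", m3, "PC1"))
})

test_that("intron embedding requires full containment; retention decides", {
  # coding intron is (250, 400)
  m <- lnc_fixture(lnc_iv = c(300, 350))
  ret_t <- data.frame(gene_id = "PC1", intron_index = 1L, retained = TRUE)
  ret_f <- data.frame(gene_id = "PC1", intron_index = 1L, retained = FALSE)
  r <- flag_intronic_retained("LNC1", m, ret_t)
  expect_true(r$intron_embedded); expect_true(r$host_intron_retained)
  r <- flag_intronic_retained("LNC1", m, ret_f)
  expect_true(r$intron_embedded); expect_false(r$host_intron_retained)
  # straddling the exon-intron boundary is not embedded
  m2 <- lnc_fixture(lnc_iv = c(200, 350))
  expect_false(flag_intronic_retained("LNC1", m2, ret_t)$intron_embedded)
  # missing retention entry: warn, treat as not retained
  ret_miss <- data.frame(gene_id = "PC1", intron_index = 2L, retained = TRUE)
  expect_warning(r <- flag_intronic_retained("LNC1", m, ret_miss),
                 "no retention entry")
  expect_false(r$host_intron_retained)
})

test_that("exclusion combines the two filters as an OR with conjunction", {
  m <- lnc_fixture(lnc_iv = c(300, 350))
  ret_t <- data.frame(gene_id = "PC1", intron_index = 1L, retained = TRUE)
  ret_f <- data.frame(gene_id = "PC1", intron_index = 1L, retained = FALSE)
  expect_true(filter_lncrnas("LNC1", m, "PC1", ret_t)$excluded)
  expect_false(filter_lncrnas("LNC1", m, "PC1", ret_f)$excluded)
  m2 <- lnc_fixture()  # exonic overlap, not embedded
  expect_true(filter_lncrnas("LNC1", m2, "PC1", ret_f)$excluded)
})

test_that("exclusion is monotone in the coding gene set", {
  set.seed(11)
  for (rep in 1:10) {
    n_cod <- 4L
    starts <- sort(sample.int(50000, n_cod)) + (0:(n_cod - 1)) * 30000
    g <- data.frame(gene_id = c("L", paste0("P", seq_len(n_cod))),
                    biotype = c("lncRNA", rep("protein_coding", n_cod)),
                    chrom = "chr1",
                    strand = "+")
    off <- sample(0:900, 1)
    ex <- c(list(L = cbind(starts[1] + off, starts[1] + off + 70)),
            lapply(starts, function(s) cbind(c(s, s + 500), c(s + 300, s + 800))))
    names(ex) <- g$gene_id
    m_small <- gene_models(g[1:2, ], ex[1:2])
    m_big <- gene_models(g, ex)
    expressed <- g$gene_id[-1]
    small <- filter_lncrnas("L", m_small, expressed)$excluded
    big <- filter_lncrnas("L", m_big, expressed)$excluded
    expect_true(!small || big)  # adding genes can only keep or grow exclusion
  }
})

test_that("planted lncRNA classes are filtered exactly at zero noise", {
  cfg <- tiny_sim_config(seed = 13, noise_sd_log2 = 0)
  st <- simulate_study(cfg)
  prof <- average_by_tissue(st$expression)
  coding <- st$annotation$coding_ids
  expressed <- coding[apply(prof[coding, ], 1, max) >= 1]
  flags <- filter_lncrnas(st$annotation$lnc_truth$gene_id,
                          st$annotation$models, expressed,
                          st$annotation$retention)
  truth <- st$annotation$lnc_truth
  should_exclude <- truth$class %in% c("sense_exonic_overlap",
                                       "intronic_retained")
  expect_equal(flags$excluded[match(truth$gene_id, flags$gene_id)],
               should_exclude)
})

test_that("regulatory domains and neighbors match the brute-force rule", {
  # single gene on an empty chromosome: lnc 10 kb away is its neighbor
  g <- data.frame(gene_id = c("P1", "L1"),
                  biotype = c("protein_coding", "lncRNA"),
                  chrom = "chr1", strand = "+")
  m <- gene_models(g, list(P1 = cbind(100000, 105000),
                           L1 = cbind(109950, 110050)))
  nb <- neighboring_genes("L1", m)
  expect_equal(nb$gene_id, "P1")
  expect_equal(nb$distance, 10000)
  # beyond the 1 Mb cap: no neighbors
  m2 <- gene_models(g, list(P1 = cbind(100000, 105000),
                            L1 = cbind(2099950, 2100050)))
  expect_equal(nrow(neighboring_genes("L1", m2)), 0L)

  # random multi-gene instances against the independent domain oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6L
    tss0 <- sort(sample.int(3e6, n))
    g <- data.frame(gene_id = sprintf("P%d", 1:n),
                    biotype = "protein_coding", chrom = "chr1",
                    strand = sample(c("+", "-"), n, replace = TRUE))
    ex <- lapply(seq_len(n), function(i) {
      if (g$strand[i] == "+") cbind(tss0[i], tss0[i] + 2000)
      else cbind(tss0[i] - 2000, tss0[i] + 1)
    })
    names(ex) <- g$gene_id
    m <- gene_models(g, ex)
    dom <- regulatory_domains(m)
    oracle <- oracle_domains(m$genes[m$genes$biotype == "protein_coding", ])
    expect_equal(dom$domain_start, oracle$domain_start)
    expect_equal(dom$domain_end, oracle$domain_end)
  }
})

test_that("coverage-based retention calls use the 25% flanking-exon rule", {
  g <- data.frame(gene_id = "PC1", biotype = "protein_coding",
                  chrom = "chr1", strand = "+")
  m <- gene_models(g, list(PC1 = cbind(c(0, 20), c(10, 30))))
  # exons covered at depth 10; intron (10,20) at depth 4 (40% >= 25%)
  cov <- data.frame(chrom = "chr1", pos = 0:29,
                    depth = c(rep(10, 10), rep(4, 10), rep(10, 10)))
  ret <- intron_retention_from_coverage(m, cov)
  expect_true(ret$retained)
  cov$depth[11:20] <- 1  # 10% < 25%
  expect_false(intron_retention_from_coverage(m, cov)$retained)
})
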