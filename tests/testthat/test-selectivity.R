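test_that("replicate averaging matches brute-force group means", {
  v <- matrix(c(2, 4, 1, 3, 5, 7), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     tissue = rep(c("t1", "t2", "t3"), each = 2))
  expect_equal(average_by_tissue(v, meta)[1, ], c(t1 = 3, t2 = 2, t3 = 6))

  set.seed(42)
  v <- matrix(runif(60), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  prof <- average_by_tissue(v, meta)
  oracle <- oracle_group_means(v, rep(c("t1", "t2", "t3"), each = 2))
  expect_equal(prof, oracle, tolerance = 1e-15)

  # one sample per tissue: identity up to column naming
  meta1 <- data.frame(sample_id = paste0("s", 1:6),
                      tissue = paste0("u", 1:6))
  expect_equal(unname(average_by_tissue(v, meta1)), unname(v))
  expect_error(average_by_tissue(v, meta[1:3, ]), "without tissue")
})

test_that("low-abundance filter keeps genes at the threshold", {
  p <- rbind(low = rep(0.5, 4), edge = c(1, 0, 0, 0), high = rep(2, 4))
  colnames(p) <- paste0("t", 1:4)
  f <- filter_low_abundance(p, 1)
  expect_setequal(rownames(f), c("edge", "high"))
  set.seed(7)
  p <- make_profile(50, 6, seed = 7, max_val = 3)
  f <- filter_low_abundance(p, 1)
  expect_setequal(rownames(f),
                  rownames(p)[vapply(seq_len(nrow(p)),
                                     function(i) max(p[i, ]) >= 1, logical(1))])
})

test_that("SPM matches its cosine-similarity definition", {
  p <- rbind(single = c(100, rep(0, 21)),
             uniform = rep(5, 22),
             dual = c(10, 10, rep(0, 20)))
  colnames(p) <- sprintf("t%02d", 1:22)
  s <- compute_spm(p)
  expect_equal(s$spm["single", 1], 1)
  expect_equal(unname(s$spm["single", 2:22]), rep(0, 21))
  expect_equal(unname(s$spm["uniform", ]), rep(1 / sqrt(22), 22))
  expect_equal(s$spm["dual", 1], 1 / sqrt(2), tolerance = 1e-12)

  for (seed in 1:50) {
    p <- make_profile(20, 8, seed = seed)
    expect_equal(compute_spm(p)$spm, oracle_spm(p), tolerance = 1e-12)
  }
})

test_that("SPM rows are unit vectors, scale-invariant and monotone", {
  p <- make_profile(100, 22, seed = 3)
  s <- compute_spm(p)$spm
  expect_true(all(abs(rowSums(s^2) - 1) < 1e-10))
  expect_equal(compute_spm(3.7 * p)$spm, s, tolerance = 1e-12)
  # raising one tissue raises its SPM and lowers every other tissue's
  p2 <- p; p2[1, 3] <- p2[1, 3] + 50
  s2 <- compute_spm(p2)$spm
  expect_gt(s2[1, 3], s[1, 3])
  expect_true(all(s2[1, -3] < s[1, -3]))
})

test_that("all-zero genes are flagged undefined, not NaN-propagated", {
  p <- rbind(ok = c(1, 2), zero = c(0, 0))
  colnames(p) <- c("t1", "t2")
  s <- compute_spm(p)
  expect_true(s$undefined["zero"])
  expect_false(s$undefined["ok"])
  expect_true(all(is.na(s$spm["zero", ])))
  calls <- call_selective(s, p, "t1", fpkm_min = 0)
  expect_equal(calls$class[calls$gene_id == "zero"], "none")
  expect_false(anyNA(calls$class))
})

test_that("selective calls apply inclusive thresholds and the band", {
  p <- rbind(a = c(0.8, 0), b = c(1, 0.484), c = c(5, 5), d = c(10, 1))
  colnames(p) <- c("target", "other")
  s <- compute_spm(p)
  calls <- call_selective(s, p, "target")
  cls <- setNames(calls$class, calls$gene_id)
  # a: SPM 1.0 but FPKM 0.8 -> none (conjunction, and not preferential)
  expect_equal(unname(cls["a"]), "none")
  # b: SPM ~0.9002 >= 0.9 and FPKM 1 -> selective at both boundaries
  expect_gte(s$spm["b", "target"], 0.9)
  expect_equal(unname(cls["b"]), "selective")
  # c: SPM 0.7071 in [0.7, 0.9) -> preferential
  expect_equal(unname(cls["c"]), "preferential")
  expect_error(call_selective(s, p, "nope"), "unknown tissue")
  # output sorted by descending SPM then gene id
  expect_equal(calls$gene_id,
               calls$gene_id[order(-calls$spm, calls$gene_id)])
})

test_that("exact SPM-0.9 boundary is called selective", {
  m <- 100; b <- spm_flat_background(m, 0.9, 22)
  p <- matrix(c(m, rep(b, 21)), nrow = 1,
              dimnames = list("g", sprintf("t%02d", 1:22)))
  s <- compute_spm(p)
  expect_equal(s$spm["g", 1], 0.9, tolerance = 1e-12)
  expect_equal(call_selective(s, p, "t01")$class, "selective")
})

test_that("gene list comparison reports overlaps and fractions", {
  r <- compare_gene_lists(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(r$n_overlap, 2L)
  expect_equal(r$frac_a, 2 / 3)
  expect_equal(r$a_only, "x")
  same <- compare_gene_lists(letters[1:4], letters[1:4])
  expect_equal(same$frac_a, 1)
  expect_equal(same$frac_b, 1)
  expect_equal(compare_gene_lists("a", "b")$n_overlap, 0L)
})
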