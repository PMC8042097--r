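test_that("count filter keeps exactly the genes with >= min_count in >= min_samples", {
  m <- rbind(
    c(5, 5, 5, 0, 0, 0),   # boundary: kept
    c(5, 5, 4, 0, 0, 0),   # one sample short: dropped
    c(4, 4, 4, 4, 4, 4),   # never reaches min_count: dropped
    c(100, 0, 0, 80, 90, 0) # kept
  )
  counts <- make_counts(m, c("Bulk:1", "Bulk:2", "Bulk:3",
                             "CC:1", "CC:2", "CC:3"))
  out <- filter_counts(counts)
  expect_equal(out$gene, c("G01", "G04"))
  expect_equal(filter_counts(out), out)  # idempotent

  zero <- make_counts(matrix(0, 2, 4),
                      c("Bulk:1", "Bulk:2", "CC:1", "CC:2"))
  expect_message(empty <- filter_counts(zero), "no gene")
  expect_equal(nrow(empty), 0)
})

test_that("size factors agree with DESeq2's median-of-ratios estimator", {
  set.seed(10)
  m <- matrix(rnbinom(600, mu = 100, size = 5), nrow = 100)
  m[, 4:6] <- m[, 4:6] * 3L
  counts <- make_counts(m, c(paste0("Bulk:", 1:3), paste0("CC:", 1:3)))
  ours <- estimate_size_factors(counts)$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("size factors fail with guidance when no gene covers all samples", {
  m <- rbind(c(0, 5), c(5, 0))
  counts <- make_counts(m, c("A:1", "B:1"))
  expect_error(estimate_size_factors(counts), "nonzero counts in every sample")
})

test_that("identical groups give zero log2 ratios", {
  set.seed(1)
  block <- matrix(rnbinom(200, mu = 50, size = 10), nrow = 50)
  counts <- make_counts(cbind(block, block),
                        c(paste0("Bulk:", 1:4), paste0("CC:", 1:4)))
  de <- test_differential_expression(counts, "CC", "Bulk")
  expect_true(all(de$log2_ratio == 0))
  expect_true(all(de$p == 1))
})

test_that("genes absent from both groups get NA and leave the BH denominator", {
  m <- rbind(c(10, 12, 9, 11), c(0, 0, 0, 0), c(50, 40, 10, 9))
  counts <- make_counts(m, c("Bulk:1", "Bulk:2", "CC:1", "CC:2"))
  de <- test_differential_expression(counts, "CC", "Bulk")
  expect_true(is.na(de$p[2]))
  expect_equal(de$p_adj[-2], p.adjust(de$p[-2], "BH"))
})

test_that("replicate requirements are enforced", {
  counts <- make_counts(cbind(c(5, 6), c(7, 8), c(9, 10)),
                        c("Bulk:1", "Bulk:2", "CC:1"))
  expect_error(test_differential_expression(counts, "CC", "Bulk"),
               ">= 2 replicates")
})

test_that("selection applies strict thresholds in at least one comparison", {
  mk_de <- function(lfc, padj) {
    structure(
      tibble::tibble(gene = sprintf("G%02d", seq_along(lfc)),
                     base_mean = 100, log2_ratio = lfc,
                     lfc_se = 0.1, stat = 1, p = padj, p_adj = padj),
      class = c("wm_de", "tbl_df", "tbl", "data.frame")
    )
  }
  # 10 clusterable genes plus the two boundary cases
  lfc_cc <- c(rep(c(2, -2), 5), 0.6, 0.58)
  padj_cc <- c(rep(0.01, 10), 0.01, 0.01)
  lfc_st <- c(rep(c(0, 1.5), 5), 0, 0.58)
  padj_st <- c(rep(0.01, 10), 0.9, 0.01)
  out <- select_and_cluster(mk_de(lfc_cc, padj_cc), mk_de(lfc_st, padj_st),
                            k = 2, seed = 1)
  expect_true("G11" %in% out$gene)   # 0.6 > 0.58 with padj 0.01 in CC
  expect_false("G12" %in% out$gene)  # 0.58 is not > 0.58 in either comparison
})

test_that("two separable ratio blobs are reproduced exactly by k = 2", {
  lfc_cc <- c(rep(3, 10), rep(-3, 10))
  lfc_st <- c(rep(0.2, 10), rep(-0.2, 10))
  de_cc <- structure(
    tibble::tibble(gene = sprintf("G%02d", 1:20), base_mean = 10,
                   log2_ratio = lfc_cc, lfc_se = 0.1, stat = 1,
                   p = 0.001, p_adj = 0.001),
    class = c("wm_de", "tbl_df", "tbl", "data.frame"))
  de_st <- structure(
    tibble::tibble(gene = sprintf("G%02d", 1:20), base_mean = 10,
                   log2_ratio = lfc_st, lfc_se = 0.1, stat = 1,
                   p = 0.5, p_adj = 0.9),
    class = c("wm_de", "tbl_df", "tbl", "data.frame"))
  out <- select_and_cluster(de_cc, de_st, k = 2, seed = 3)
  expect_equal(dplyr::n_distinct(out$cluster[1:10]), 1)
  expect_equal(dplyr::n_distinct(out$cluster[11:20]), 1)
  expect_false(out$cluster[1] == out$cluster[11])
  expect_error(select_and_cluster(de_cc, de_st, k = 30, seed = 1),
               "smaller k")
})

test_that("PCA separates planted region profiles and is permutation-equivariant", {
  de <- dplyr::bind_rows(
    tibble::tibble(gene = sprintf("GENE%04d", 1:100), region = "CC", log2fc = 3),
    tibble::tibble(gene = sprintf("GENE%04d", 101:200), region = "ST", log2fc = 3)
  )
  sim <- simulate_region_counts(genes = 1000, n_per_region = 4, de = de,
                                dispersion = 0.02, seed = 9)
  filt <- filter_counts(sim$counts)
  pc <- pca_samples(filt)
  d2 <- as.matrix(dist(as.matrix(pc[, c("PC1", "PC2")])))
  same <- outer(pc$condition, pc$condition, "==")
  sil <- mean(d2[!same]) / mean(d2[same & upper.tri(same)])
  expect_gt(sil, 2)  # regions separate far more than replicates scatter

  perm <- filt[c("gene", rev(setdiff(names(filt), "gene")))]
  pc2 <- pca_samples(perm)
  expect_equal(as.data.frame(pc2[rev(seq_len(nrow(pc2))), ]),
               as.data.frame(pc), ignore_attr = TRUE)
  expect_error(pca_samples(filt[1:2]), "2 samples")
})
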