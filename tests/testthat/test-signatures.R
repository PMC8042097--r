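make_atlas_tbl <- function(m, samples, genes) {
  colnames(m) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

test_that("preprocessing collapses duplicates, filters coverage and centres rows", {
  tbl <- make_atlas_tbl(
    rbind(c(1, 3), c(3, 1), c(5, 5), c(0.1, 0.2)),
    c("A:1", "B:1"),
    c("DUP", "DUP", "CONST", "LOW")
  )
  out <- preprocess_atlas(tbl, low_coverage_min = 1, log2_transform = FALSE)
  # duplicate rows [1,3] and [3,1] average to [2,2], centred to [0,0]
  expect_equal(unlist(out[out$gene == "DUP", -1], use.names = FALSE), c(0, 0))
  # constant rows centre to zero
  expect_equal(unlist(out[out$gene == "CONST", -1], use.names = FALSE), c(0, 0))
  # low-coverage gene dropped
  expect_false("LOW" %in% out$gene)
  # each row's median is 0
  expect_true(all(abs(apply(as.matrix(out[-1]), 1, median)) < 1e-9))
})

test_that("preprocessing is idempotent", {
  atlas <- simulate_atlas(seed = 3)$expression
  once <- preprocess_atlas(atlas)
  twice <- preprocess_atlas(once)
  expect_equal(twice, once)
})

test_that("preprocessing fails clearly when the coverage cutoff removes everything", {
  tbl <- make_atlas_tbl(rbind(c(0.1, 0.1)), c("A:1", "B:1"), "G1")
  expect_error(preprocess_atlas(tbl, low_coverage_min = 10), "10")
})

test_that("CV selection matches hand-computed values and is scale-invariant", {
  tbl <- make_atlas_tbl(
    rbind(c(1, 1, 1), c(1, 3, 2)),
    c("A:1", "B:1", "C:1"),
    c("FLAT", "VAR")
  )
  # row (1,3,2): sd = 1, mean = 2, CV = 0.5
  expect_equal(select_variable_genes(tbl, 0.4), "VAR")
  expect_equal(select_variable_genes(tbl, 0.5), character(0))

  # two conditions, values 1 and 3: CV = sqrt(2)/2 ~ 0.707
  tbl2 <- make_atlas_tbl(rbind(c(1, 3)), c("A:1", "B:1"), "G1")
  expect_equal(select_variable_genes(tbl2, 0.1), "G1")
  expect_equal(select_variable_genes(tbl2, 0.70), "G1")
  expect_equal(select_variable_genes(tbl2, 0.71), character(0))

  scaled <- tbl
  scaled[-1] <- scaled[-1] * 37.5
  expect_equal(select_variable_genes(scaled, 0.4),
               select_variable_genes(tbl, 0.4))
})

test_that("zero-mean genes are excluded from CV selection with a message", {
  tbl <- make_atlas_tbl(rbind(c(0, 0), c(2, 6)), c("A:1", "B:1"),
                        c("ZERO", "OK"))
  expect_message(sel <- select_variable_genes(tbl, 0.1), "zero mean")
  expect_equal(sel, "OK")
})

test_that("noise-free atlas selection recovers exactly the planted markers", {
  nf <- simulate_atlas(n_markers_per_type = 20, n_background_genes = 100,
                       noise_sd = 0, marker_effect = 2, seed = 2)
  markers <- nf$truth$gene[nf$truth$cell_type != "none"]
  sel <- select_variable_genes(nf$expression, 0.3)
  expect_setequal(sel, markers)
})

test_that("block-structured markers yield the planted signatures at k = n_types", {
  nf <- simulate_atlas(n_markers_per_type = 15, n_background_genes = 50,
                       noise_sd = 0, marker_effect = 2, seed = 4)
  centred <- preprocess_atlas(nf$expression)
  markers <- nf$truth$gene[nf$truth$cell_type != "none"]
  sigs <- derive_signatures(centred, markers, k = 3, margin = 0, seed = 0)
  expect_length(sigs, 3)
  for (tt in names(sigs)) {
    planted <- nf$truth$gene[nf$truth$cell_type == tt]
    expect_setequal(sigs[[tt]], planted)
  }
})

test_that("with surplus clusters each signature is a subset of one marker block", {
  sim <- simulate_atlas(seed = 11)  # defaults: 3 types, 50 markers, noise 0.5
  centred <- preprocess_atlas(sim$expression)
  sigs <- derive_signatures(centred, centred$gene, k = 6, margin = 0.5,
                            seed = 0)
  expect_gte(length(sigs), 3)
  recovered <- 0
  for (tt in c("TYPE1", "TYPE2", "TYPE3")) {
    planted <- sim$truth$gene[sim$truth$cell_type == tt]
    inside <- intersect(sigs[[tt]], planted)
    # each signature draws from a single planted block (no cross-type genes)
    cross <- intersect(sigs[[tt]],
                       sim$truth$gene[!sim$truth$cell_type %in% c(tt, "none")])
    expect_length(cross, 0)
    recovered <- recovered + length(inside)
  }
  expect_gte(recovered / 150, 0.95)
})

test_that("signature derivation is deterministic and sample-order invariant", {
  sim <- simulate_atlas(seed = 6)
  centred <- preprocess_atlas(sim$expression)
  genes <- select_variable_genes(sim$expression, 0.3)
  s1 <- derive_signatures(centred, genes, k = 3, seed = 42)
  s2 <- derive_signatures(centred, genes, k = 3, seed = 42)
  expect_identical(s1, s2)

  permuted <- centred[c("gene", rev(setdiff(names(centred), "gene")))]
  s3 <- derive_signatures(permuted, genes, k = 3, seed = 42)
  expect_equal(lapply(unclass(s1)[], sort)[sort(names(s1))],
               lapply(unclass(s3)[], sort)[sort(names(s3))],
               ignore_attr = TRUE)
})

test_that("derivation guards: k too large, empty margin result", {
  sim <- simulate_atlas(n_markers_per_type = 3, n_background_genes = 0,
                        noise_sd = 0, seed = 1)
  centred <- preprocess_atlas(sim$expression)
  expect_error(derive_signatures(centred, centred$gene, k = 100), "exceeds")
  expect_warning(
    empty <- derive_signatures(centred, centred$gene, k = 3, margin = 100),
    "margin"
  )
  expect_length(empty, 0)
})
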