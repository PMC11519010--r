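test_that("cell filter removes by strict inequality and keeps the boundary", {
  tab <- make_cell_table(n_detected = c(499, 500, 501),
                         mito = c(0.10, 0.60, 0.61), n_genes = 600)
  kept <- suppressWarnings(filter_cells(tab))
  expect_equal(rownames(kept$counts), c("c002"))
  ## 499 genes removed even with clean mito; 0.60 mito retained at 500 genes;
  ## 0.61 removed despite enough genes
  tab2 <- make_cell_table(n_detected = c(500, 500), mito = c(0.60, 0.6000001),
                          n_genes = 600)
  kept2 <- suppressWarnings(filter_cells(tab2))
  expect_equal(rownames(kept2$counts), "c001")
})

test_that("constructed 100-cell fixture retains exactly 89 cells", {
  ## 7 cells under the gene threshold, 5 over the mito threshold, 1 overlap
  n_detected <- rep(600, 100)
  n_detected[1:7] <- 499
  mito <- rep(0.1, 100)
  mito[7:11] <- 0.75
  tab <- make_cell_table(n_detected, mito, n_genes = 700)
  expect_warning(kept <- filter_cells(tab), "11 of 100")
  expect_equal(nrow(kept$counts), 89L)
  expect_equal(kept$cell_meta$cell_id,
               tab$cell_meta$cell_id[-(1:11)])
})

test_that("gene filter boundary sits at detection in three cells", {
  counts <- matrix(0, 6, 3, dimnames = list(sprintf("c%d", 1:6),
                                            c("gA", "gB", "gC")))
  counts[1:3, 1] <- 1    # detected in exactly 3 cells -> retained
  counts[1:2, 2] <- 5    # detected in 2 cells -> removed
  counts[1:6, 3] <- 1
  meta <- tibble::tibble(cell_id = rownames(counts), sample_id = "s1",
                         patient_id = "p1", compartment = "E",
                         mito_fraction = 0)
  tab <- cell_table(counts, meta)
  kept <- suppressMessages(filter_genes(tab))
  expect_equal(colnames(kept$counts), c("gA", "gC"))
  expect_equal(kept$cell_meta$n_genes_detected[1], 2L)
})

test_that("gene filter drops a known number from a constructed fixture", {
  set.seed(1)
  counts <- matrix(rpois(30 * 50, 2), 30, 50,
                   dimnames = list(sprintf("c%d", 1:30),
                                   sprintf("g%d", 1:50)))
  counts[3:30, 1:4] <- 0   # 4 genes detected in at most 2 cells
  meta <- tibble::tibble(cell_id = rownames(counts), sample_id = "s1",
                         patient_id = "p1", compartment = "E",
                         mito_fraction = 0)
  kept <- suppressMessages(filter_genes(cell_table(counts, meta)))
  expect_equal(ncol(kept$counts), 46L)
})

test_that("filters are idempotent", {
  a <- tiny_atlas(seed = 17)
  f1 <- suppressWarnings(suppressMessages(
    filter_genes(filter_cells(a$cells, min_genes = 30), min_cells = 3)))
  f2 <- suppressWarnings(suppressMessages(
    filter_genes(filter_cells(f1, min_genes = 30), min_cells = 3)))
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
  expect_identical(f1$cell_meta, f2$cell_meta)
})

test_that("TP10K log-normalisation matches its closed form", {
  counts <- rbind(c(5, 5, 0), c(1, 2, 3))
  dimnames(counts) <- list(c("c1", "c2"), c("g1", "g2", "g3"))
  meta <- tibble::tibble(cell_id = c("c1", "c2"), sample_id = "s1",
                         patient_id = "p1", compartment = "E",
                         mito_fraction = 0)
  norm <- normalize_tp10k_log(cell_table(counts, meta))
  expect_equal(as.numeric(norm[1, ]), c(log(5001), log(5001), 0),
               tolerance = 1e-12)
  ## doubling all counts of a cell leaves its normalised row unchanged
  norm2 <- normalize_tp10k_log(cell_table(counts * 2, meta))
  expect_equal(as.matrix(norm2), as.matrix(norm), tolerance = 1e-12)
})

test_that("normalisation agrees with an independent oracle on random counts", {
  set.seed(23)
  counts <- matrix(rpois(20 * 10, 5), 20, 10,
                   dimnames = list(sprintf("c%d", 1:20),
                                   sprintf("g%d", 1:10)))
  counts[counts == 0] <- 1  # avoid all-zero rows by construction
  meta <- tibble::tibble(cell_id = rownames(counts), sample_id = "s1",
                         patient_id = "p1", compartment = "E",
                         mito_fraction = 0)
  norm <- as.matrix(normalize_tp10k_log(cell_table(counts, meta)))
  oracle <- log1p(sweep(counts, 1, rowSums(counts), "/") * 1e4)
  expect_equal(norm, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all-zero cells are rejected by name", {
  counts <- rbind(c(1, 1), c(0, 0))
  dimnames(counts) <- list(c("good", "empty"), c("g1", "g2"))
  meta <- tibble::tibble(cell_id = c("good", "empty"), sample_id = "s1",
                         patient_id = "p1", compartment = "E",
                         mito_fraction = 0)
  expect_error(normalize_tp10k_log(cell_table(counts, meta)), "empty")
})

test_that("pseudobulk sums exactly and conserves totals", {
  counts <- rbind(c(1, 2, 0), c(0, 1, 4), c(2, 2, 2),
                  c(5, 0, 1), c(1, 1, 1), c(0, 0, 3))
  dimnames(counts) <- list(sprintf("c%d", 1:6), c("g1", "g2", "g3"))
  meta <- tibble::tibble(cell_id = rownames(counts),
                         sample_id = rep(c("s1", "s2"), each = 3),
                         patient_id = "p1", compartment = "E",
                         mito_fraction = 0)
  pb <- pseudobulk(cell_table(counts, meta))
  expect_equal(pb["s1", ], c(g1 = 3, g2 = 5, g3 = 6))
  expect_equal(pb["s2", ], c(g1 = 6, g2 = 1, g3 = 5))
  expect_equal(colSums(pb), colSums(counts))
  ## one cell per sample: pseudobulk equals the counts
  meta1 <- meta |> dplyr::mutate(sample_id = cell_id)
  pb1 <- pseudobulk(cell_table(counts, meta1))
  expect_equal(unname(pb1), unname(counts))
})
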