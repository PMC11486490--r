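test_that("pseudo-bulk sums cell counts exactly and conserves totals", {
  counts <- tibble::tibble(
    feature_id = c("LINE", "SCG1"),
    c1 = c(1L, 5L), c2 = c(2L, 3L), c3 = c(7L, 1L), c4 = c(0L, 4L))
  ann <- tibble::tibble(
    cell_id = c("c1", "c2", "c3", "c4"),
    sample_id = c("s1", "s1", "s1", "s2"),
    cell_type = c("Plasma", "Plasma", "TC", "TC"))
  pb <- pseudo_bulk(counts, ann)
  get <- function(ct, s, f) pb$count[pb$cell_type == ct & pb$sample_id == s &
                                       pb$feature_id == f]
  expect_equal(get("Plasma", "s1", "LINE"), 3)   # 1 + 2
  expect_equal(get("TC", "s1", "LINE"), 7)
  # conservation: sum over cell types equals the sample total per feature
  tot <- dplyr::summarise(dplyr::group_by(pb, feature_id, sample_id),
                          n = sum(count), .groups = "drop")
  expect_equal(tot$n[tot$feature_id == "SCG1" & tot$sample_id == "s1"], 9)
  expect_error(pseudo_bulk(counts, ann[0, ]), "empty")
})

test_that("unannotated cells are dropped with a message and results are
           independent of cell order", {
  cfg <- synthetic_config(seed = 6, sc_n_samples = 4L, sc_cells_per_type = 5L)
  sc <- simulate_single_cell(cfg)
  ann_missing <- sc$annotation[-(1:3), ]
  expect_message(pb <- pseudo_bulk(sc$counts, ann_missing), "3 unannotated")
  expect_equal(attr(pb, "n_dropped_cells"), 3L)
  # permuting cell columns leaves the aggregate unchanged
  perm <- sc$counts[, c(1, 1 + sample.int(ncol(sc$counts) - 1L))]
  pb1 <- pseudo_bulk(sc$counts, sc$annotation)
  pb2 <- pseudo_bulk(perm, sc$annotation)
  expect_equal(as.data.frame(pb1), as.data.frame(pb2))
  # brute-force group-and-sum oracle on the same fixture
  m <- rteage:::as_feature_matrix(sc$counts)
  idx <- match(colnames(m), sc$annotation$cell_id)
  for (row in sample(seq_len(nrow(pb1)), 20)) {
    cells <- sc$annotation$cell_id[
      sc$annotation$cell_type == pb1$cell_type[row] &
        sc$annotation$sample_id == pb1$sample_id[row]]
    expect_equal(pb1$count[row],
                 sum(m[pb1$feature_id[row], colnames(m) %in% cells]))
  }
})

test_that("combined RPM uses the gene + class denominator and sums to 1e6", {
  pb <- tibble::tibble(
    cell_type = "TC", sample_id = "s1",
    feature_id = c("SCG1", "SCG2", "LINE", "L1"),
    count = c(50, 40, 10, 6))
  rpm <- combined_rpm(pb)
  # denominator is 100 (genes 90 + class 10); the family row is excluded
  expect_equal(rpm$rpm[rpm$feature_id == "LINE"], 1e5)
  expect_equal(rpm$rpm[rpm$feature_id == "L1"], 6e4)
  core <- dplyr::filter(rpm, kind != "rte_family")
  expect_equal(sum(core$rpm), 1e6, tolerance = 1e-9)
  # doubling all counts leaves RPM unchanged
  rpm2 <- combined_rpm(dplyr::mutate(pb, count = count * 2))
  expect_equal(rpm2$rpm, rpm$rpm)
  # zero-total combinations are dropped with a warning
  zero <- tibble::tibble(cell_type = "NK", sample_id = "s9",
                         feature_id = "SCG1", count = 0)
  expect_warning(out <- combined_rpm(dplyr::bind_rows(pb, zero)), "NK")
  expect_false(any(out$cell_type == "NK"))
})

test_that("every (cell type, sample) RPM vector sums to one million", {
  cfg <- synthetic_config(seed = 9, sc_n_samples = 6L, sc_cells_per_type = 8L)
  sc <- simulate_single_cell(cfg)
  rpm <- combined_rpm(pseudo_bulk(sc$counts, sc$annotation))
  sums <- rpm |>
    dplyr::filter(kind != "rte_family") |>
    dplyr::group_by(cell_type, sample_id) |>
    dplyr::summarise(s = sum(rpm), .groups = "drop")
  expect_true(all(abs(sums$s - 1e6) / 1e6 < 1e-6))
})

test_that("sample-level signature scoring matches a manual pseudo-bulk run", {
  cfg <- synthetic_config(seed = 10, sc_n_samples = 5L, sc_cells_per_type = 6L)
  sc <- simulate_single_cell(cfg)
  got <- pseudobulk_signature_scores(sc$counts, sc$annotation, sc$signatures)
  expect_equal(dim(rteage:::as_feature_matrix(got)), c(6L, 5L))
  # manual route: sum gene counts per sample, RPM, then score
  m <- rteage:::as_feature_matrix(sc$counts)
  genes <- setdiff(rownames(m), c("LINE", "SINE", "LTR"))
  bysample <- sapply(unique(sc$annotation$sample_id), function(s) {
    cells <- sc$annotation$cell_id[sc$annotation$sample_id == s]
    rowSums(m[genes, colnames(m) %in% cells, drop = FALSE])
  })
  manual <- score_signatures(rpm_normalize(as_mat_tbl(bysample)),
                             sc$signatures)
  expect_equal(rteage:::as_feature_matrix(got)[, colnames(bysample)],
               rteage:::as_feature_matrix(manual)[, colnames(bysample)])
  # rank invariance: doubling a sample's counts leaves its scores unchanged
  doubled <- sc$counts
  s1_cells <- sc$annotation$cell_id[sc$annotation$sample_id ==
                                      sc$annotation$sample_id[1]]
  doubled[, names(doubled) %in% s1_cells] <-
    doubled[, names(doubled) %in% s1_cells] * 2L
  got2 <- pseudobulk_signature_scores(doubled, sc$annotation, sc$signatures)
  expect_equal(rteage:::as_feature_matrix(got2),
               rteage:::as_feature_matrix(got))
})

test_that("cell-type contrasts respect group-size rules and label symmetry", {
  cfg <- synthetic_config(seed = 11, sc_n_samples = 8L, sc_cells_per_type = 6L)
  sc <- simulate_single_cell(cfg)
  rpm <- combined_rpm(pseudo_bulk(sc$counts, sc$annotation))
  sm <- rteage:::as_feature_matrix(
    pseudobulk_signature_scores(sc$counts, sc$annotation, sc$signatures))
  grp <- median_split(tibble::tibble(sample_id = colnames(sm),
                                     score = sm["SASP", ]))
  ct <- celltype_contrast(rpm, grp)
  expect_setequal(unique(ct$rte_id), c("LINE", "SINE", "LTR"))
  expect_equal(nrow(ct), 5L * 3L)
  # swapping the group labels leaves two-sided p unchanged
  swapped <- grp
  swapped$label <- factor(ifelse(grp$label == "high", "low", "high"),
                          levels = c("low", "high"))
  ct2 <- celltype_contrast(rpm, swapped)
  expect_equal(ct2$p, ct$p)
  # a cell type without enough high samples is skipped with a warning
  tiny <- grp
  tiny$label[tiny$label == "high"][-1] <- "low"
  expect_warning(ct3 <- celltype_contrast(rpm, tiny), "skipped")
  expect_equal(nrow(ct3), 0L)
})

test_that("the planted plasma effect is detected against null cell types", {
  res <- sc_recovery_once(1)
  expect_lt(res$planted_p, 0.05)
  expect_true(res$top)
})

test_that("MTX and dense cell-count readers agree", {
  cfg <- synthetic_config(seed = 12, sc_n_samples = 4L, sc_cells_per_type = 3L)
  sc <- simulate_single_cell(cfg)
  m <- rteage:::as_feature_matrix(sc$counts)
  dir <- tempfile(); dir.create(dir)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  back <- read_cell_counts(mtx, file.path(dir, "features.tsv"),
                           file.path(dir, "barcodes.tsv"))
  expect_equal(rteage:::as_feature_matrix(back), m)
})
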