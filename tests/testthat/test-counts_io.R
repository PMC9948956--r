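test_that("Matrix Market round trip preserves the counts exactly", {
  m <- toy_matrix()
  d <- withr::local_tempdir()
  paths <- write_counts(m, d)
  m2 <- read_counts(paths$mtx, paths$features, paths$barcodes)
  expect_identical(as.matrix(m2), as.matrix(m))

  # empty matrix: header only, round trips
  e <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(2, 2),
                            dimnames = list(c("f1", "f2"), c("b1", "b2")))
  pe <- write_counts(as(e, "CsparseMatrix"), file.path(d, "empty"))
  e2 <- read_counts(pe$mtx, pe$features, pe$barcodes)
  expect_identical(as.matrix(e2), as.matrix(e))
})

test_that("reader enforces the count-matrix contract", {
  d <- withr::local_tempdir()
  feats <- file.path(d, "features.tsv"); writeLines(c("f1", "f2"), feats)
  bcs <- file.path(d, "barcodes.tsv"); writeLines(c("b1", "b2"), bcs)

  mk <- function(lines) {
    p <- file.path(d, "m.mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general", lines), p)
    p
  }
  # 2x2 with (1,1)=3, (2,2)=5
  p <- mk(c("2 2 2", "1 1 3", "2 2 5"))
  expect_equal(as.matrix(read_counts(p, feats, bcs)),
               matrix(c(3, 0, 0, 5), 2, dimnames = list(c("f1", "f2"),
                                                        c("b1", "b2"))))
  expect_error(read_counts(mk(c("2 2 1", "1 1 -1")), feats, bcs),
               "negative")
  expect_error(read_counts(mk(c("2 2 1", "1 1 2.5")), feats, bcs),
               "non-integer")
  expect_error(read_counts(mk(c("2 2 2", "1 1 1", "1 1 2")), feats, bcs),
               "duplicate")
  writeLines("f1", feats)
  expect_error(read_counts(mk(c("2 2 1", "1 1 3")), feats, bcs),
               "dimension mismatch")
})

test_that("gzip-compressed sidecars are read transparently", {
  d <- withr::local_tempdir()
  paths <- write_counts(toy_matrix(), d)
  for (p in unlist(paths)) {
    con <- gzfile(paste0(p, ".gz"), "w")
    writeLines(readLines(p), con); close(con)
  }
  m <- read_counts(paste0(paths$mtx, ".gz"), paste0(paths$features, ".gz"),
                   paste0(paths$barcodes, ".gz"))
  expect_identical(as.matrix(m), as.matrix(toy_matrix()))
})

test_that("pseudobulk aggregation matches a per-cell loop oracle", {
  # trivial two-cell case: sums and cell count
  m <- toy_matrix(); ann <- toy_annotations()
  pb <- aggregate_pseudobulk(m, ann, "TARGET")
  a1 <- pb[pb$animal == "A1", ]
  expect_equal(a1$target_umi, 8)        # 3 + 5
  expect_equal(a1$total_umi, 10)        # 3 + 7
  expect_equal(a1$n_cells, 2L)
  # grand totals conserved over the partition
  expect_equal(sum(pb$total_umi), sum(m))
  expect_equal(sum(pb$target_umi), sum(m["TARGET", ]))

  # loop oracle on a seeded synthetic cohort
  co <- generate_cohort(cohort_spec(seed = 7, cells_per_animal = 120))
  pb2 <- aggregate_pseudobulk(co$counts, co$annotations, "TARGET")
  ann2 <- co$annotations
  for (i in sample(nrow(pb2), 5)) {
    bcs <- ann2$barcode[ann2$animal == pb2$animal[i] &
                          ann2$cell_type == pb2$cell_type[i]]
    tgt <- tot <- 0
    for (b in bcs) {
      tgt <- tgt + co$counts["TARGET", b]
      tot <- tot + sum(co$counts[, b])
    }
    expect_equal(pb2$target_umi[i], tgt)
    expect_equal(pb2$total_umi[i], tot)
    expect_equal(pb2$n_cells[i], length(bcs))
  }

  # permutation invariance in cell order
  perm <- sample(ncol(co$counts))
  pb3 <- aggregate_pseudobulk(co$counts[, perm], co$annotations, "TARGET")
  expect_equal(pb2, pb3)
})

test_that("aggregation rejects bad input and drops zero-exposure cells", {
  m <- toy_matrix(); ann <- toy_annotations()
  expect_error(aggregate_pseudobulk(m, ann, "nope"), "target feature")
  expect_error(aggregate_pseudobulk(m, ann[-1, ], "TARGET"), "unannotated")

  m0 <- cbind(m, Matrix::sparseMatrix(i = integer(), j = integer(),
                                      x = numeric(), dims = c(3, 1),
                                      dimnames = list(rownames(m), "bc5")))
  ann0 <- rbind(ann, data.frame(barcode = "bc5", animal = "A2",
                                treatment = "ASO", cell_type = "glia",
                                region = "ctx", weeks_post_dose = 2))
  expect_warning(pb <- aggregate_pseudobulk(m0, ann0, "TARGET"),
                 "zero total UMIs")
  expect_equal(sum(pb$n_cells), 4L)  # bc5 dropped
})

test_that("per-cell extraction is stable and consistent with aggregation", {
  co <- generate_cohort(cohort_spec(seed = 5, cells_per_animal = 80))
  cells <- per_cell_target_counts(co$counts, co$annotations, "TARGET",
                                  "astrocyte")
  expect_equal(cells$barcode, sort(cells$barcode))
  # totals match column sums (loop oracle)
  for (i in sample(nrow(cells), 5))
    expect_equal(cells$total_umi[i],
                 sum(co$counts[, cells$barcode[i]]))
  # sums reproduce the pseudobulk row sums for that type
  pb <- aggregate_pseudobulk(co$counts, co$annotations, "TARGET")
  expect_equal(sum(cells$target_umi),
               sum(pb$target_umi[pb$cell_type == "astrocyte"]))
  expect_error(per_cell_target_counts(co$counts, co$annotations, "TARGET",
                                      "purkinje"), "unknown cell type")
  # treatment filter partitions the type
  a <- per_cell_target_counts(co$counts, co$annotations, "TARGET",
                              "astrocyte", treatment = "control")
  b <- per_cell_target_counts(co$counts, co$annotations, "TARGET",
                              "astrocyte", treatment = "ASO")
  expect_equal(nrow(a) + nrow(b), nrow(cells))
})

test_that("pseudobulk TSV round trips through metadata headers", {
  tab <- equal_offset_table(counts_trt = c(40, 60))
  d <- withr::local_tempdir()
  p <- file.path(d, "pb.tsv")
  write_pseudobulk(tab, p, meta = list(seed = 11, config_hash = "abc"))
  expect_match(readLines(p)[1], "^# seed=11")
  back <- read_pseudobulk(p)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
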