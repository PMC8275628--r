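test_that("ERCC features are recognized and MTX/TSV round trips are exact", {
  endo <- matrix(c(5, 0, 5, 1, 2, 0, 0, 3, 7), 3, 3)
  ercc <- matrix(c(10, 1, 4), 3, 1)
  cm <- make_cm(endo, ercc)
  expect_equal(cm$features$is_ercc, c(FALSE, FALSE, FALSE, TRUE))

  dir <- withr::local_tempdir()
  write_count_matrix(cm, file.path(dir, "mtx"))
  back <- read_count_matrix(file.path(dir, "mtx"))
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts),
               ignore_attr = TRUE)
  expect_equal(back$features, cm$features)
  expect_equal(back$nuclei, cm$nuclei)

  write_count_matrix(cm, file.path(dir, "dense", "counts.tsv"), format = "tsv")
  back2 <- read_count_matrix(file.path(dir, "dense", "counts.tsv"), format = "tsv")
  expect_equal(as.matrix(back2$counts), as.matrix(cm$counts), ignore_attr = TRUE)
})

test_that("invalid counts and mismatched tables are rejected", {
  endo <- matrix(1, 2, 2)
  expect_error(make_cm(endo - 2, matrix(1, 2, 1)), "non-negative")
  expect_error(make_cm(endo + 0.5, matrix(1, 2, 1)), "integral")
  feats <- data.frame(feature_id = c("a", "a"), is_ercc = FALSE, length_kb = 1)
  expect_error(count_matrix(matrix(0, 2, 2), feats,
                            data.frame(nucleus_id = c("n1", "n2"))),
               "duplicate")
  expect_error(count_matrix(matrix(0, 2, 3),
                            data.frame(feature_id = c("a", "b"), length_kb = 1),
                            data.frame(nucleus_id = c("n1", "n2"))),
               "columns")
  # a written file with a negative entry fails on read
  dir <- withr::local_tempdir()
  cm <- make_cm(matrix(1, 2, 2), matrix(1, 2, 1))
  write_count_matrix(cm, file.path(dir, "mtx"))
  mtx <- readLines(file.path(dir, "mtx", "matrix.mtx"))
  mtx[length(mtx)] <- sub("\\d+$", "-3", mtx[length(mtx)])
  writeLines(mtx, file.path(dir, "mtx", "matrix.mtx"))
  expect_error(read_count_matrix(file.path(dir, "mtx")))
})

test_that("per-nucleus QC metrics follow their definitions", {
  endo <- rbind(c(5, 0, 5), c(0, 0, 0), c(0, 0, 0))
  ercc <- matrix(c(10, 0, 8), 3, 1)
  qc <- compute_qc(make_cm(endo, ercc))
  expect_equal(qc$library_size, c(20, 0, 8))
  expect_equal(qc$n_genes_detected, c(2, 0, 0))
  expect_equal(qc$ercc_fraction, c(0.5, 0, 1))
  qc2 <- compute_qc(make_cm(endo, ercc), library_includes_ercc = FALSE)
  expect_equal(qc2$library_size, c(10, 0, 0))
})

test_that("the filter cascade matches a brute-force reading of the rules", {
  for (seed in 1:100) {
    cm <- rand_cm(seed)
    th <- toy_thresholds(seed + 1000)
    got <- apply_qc_filters(cm, th)
    want <- oracle_qc(cm, th)
    expect_equal(got$matrix$nuclei$nucleus_id, want$nuclei)
    expect_equal(sort(got$matrix$features$feature_id), sort(want$features))
    # report counts are monotone non-increasing
    expect_true(all(diff(got$report$steps$n_nuclei) <= 0))
    expect_true(all(diff(got$report$steps$n_features) <= 0))
  }
})

test_that("the filter cascade is idempotent away from threshold boundaries", {
  # Nucleus metrics are measured on the matrix the cascade receives, so a
  # second application sees the post-gene-filter universe; the cascade is a
  # fixed point whenever the gene filter does not push a nucleus metric
  # across a window boundary -- the operating regime of the study windows.
  sim <- simulate_dataset(sim_config(seed = 70, n_hep_2n = 80, n_hep_4n = 80,
                                     n_other = c(endothelial = 40),
                                     n_genes = 800, n_program = 150,
                                     n_housekeeping = 60, n_pericentral = 50,
                                     n_periportal = 50, n_deg = 10,
                                     n_ct_markers = 10))
  th <- sim_qc_thresholds()
  once <- apply_qc_filters(sim$matrix, th)$matrix
  twice <- apply_qc_filters(once, th)$matrix
  expect_equal(as.matrix(twice$counts), as.matrix(once$counts), ignore_attr = TRUE)
  expect_equal(twice$nuclei, once$nuclei)
})

test_that("the 'either' gene-filter reading keeps at least as many genes", {
  cm <- rand_cm(7)
  th <- toy_thresholds(42)
  th_or <- toy_thresholds(42)
  th_or$gene_rule <- "either"
  got <- apply_qc_filters(cm, th_or)
  want <- oracle_qc(cm, th_or)
  expect_equal(sort(got$matrix$features$feature_id), sort(want$features))
  expect_true(ncol(got$matrix$counts) >= ncol(apply_qc_filters(cm, th)$matrix$counts))
})

test_that("an extreme ERCC fraction removes the nucleus at the first step", {
  endo <- rbind(rep(3, 10), rep(3, 10))
  ercc <- cbind(c(400, 5))  # nucleus 1: ercc fraction ~0.93
  cm <- make_cm(endo, ercc)
  th <- qc_thresholds(genes_min = 1, genes_max = 100, gene_min_cells = 0,
                      gene_min_reads = 0, final_genes_max = 100,
                      lib_min = 0, lib_max = 1e6)
  out <- apply_qc_filters(cm, th)
  expect_equal(out$matrix$nuclei$nucleus_id, "N002")
  expect_equal(out$report$steps$n_nuclei[2], 1)
})

test_that("technical replicates are dropped, degenerate cases included", {
  cm <- rand_cm(3, n = 10)
  cm$nuclei$is_technical_replicate[c(2, 5)] <- TRUE
  expect_equal(nrow(drop_technical_replicates(cm)$counts), 8)
  cm$nuclei$is_technical_replicate[] <- FALSE
  expect_equal(drop_technical_replicates(cm)$nuclei, cm$nuclei)
  cm$nuclei$is_technical_replicate[] <- TRUE
  expect_warning(out <- drop_technical_replicates(cm), "all nuclei")
  expect_equal(nrow(out$counts), 0)
})

test_that("filter reports serialize to JSON", {
  out <- apply_qc_filters(rand_cm(11), toy_thresholds(11))
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_report(out$report, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$steps$n_nuclei, out$report$steps$n_nuclei)
})
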