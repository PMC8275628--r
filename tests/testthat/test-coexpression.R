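test_that("binarization thresholds at zero, idempotently, consistent with QC", {
  vals <- rbind(c(0, 2.3, 0.1), c(0, 0, 0), c(1, 0, 5))
  bm <- binarize(make_nm(vals))
  expect_equal(unname(bm$values), rbind(c(0, 1, 1), c(0, 0, 0), c(1, 0, 1)))
  expect_equal(binarize(make_nm(bm$values))$values, bm$values)
  # ones per nucleus equal detected genes on the same gene universe
  cm <- rand_cm(61, n = 20)
  ok <- Matrix::rowSums(ercc_counts(cm)) > 0 & Matrix::rowSums(endo_counts(cm)) > 0
  cm <- cm[ok, ]
  nm <- log_transform(normalize_eq1(cm))
  b <- binarize(nm)
  expect_equal(unname(rowSums(b$values)),
               compute_qc(cm)$n_genes_detected)
})

test_that("marker subsetting drops nuclei expressing no marker", {
  vals <- rbind(c(1, 0, 2), c(0, 0, 0.5), c(0, 0, 0), c(3, 1, 0))
  nm <- make_nm(vals, gene_names = c("Lgr5", "Tert", "Axin2"),
                ploidy = c("2n", "2n", "4n", "4n"))
  bm <- subset_markers_drop_empty(binarize(nm), c("Lgr5", "Tert", "Axin2"))
  expect_equal(nrow(bm$values), 3)  # all-zero nucleus dropped
  expect_equal(colnames(bm$values), c("Lgr5", "Tert", "Axin2"))
  expect_error(subset_markers_drop_empty(binarize(nm), c("Nope")), "none of the markers")
  # all nuclei expressing at least one marker: row identity
  bm2 <- subset_markers_drop_empty(binarize(make_nm(vals[-3, , drop = FALSE],
                                                    gene_names = c("Lgr5", "Tert", "Axin2"))),
                                   c("Lgr5", "Tert", "Axin2"))
  expect_equal(nrow(bm2$values), 3)
})

test_that("Jaccard similarities match explicit set computations", {
  b <- cbind(X = c(1, 1, 0), Y = c(1, 0, 1))
  bm <- list(values = b, features = NULL, nuclei = NULL)
  class(bm) <- "BinaryMatrix"
  jr <- pairwise_jaccard(bm)
  expect_equal(jr$jaccard["X", "Y"], 1 / 3)
  expect_equal(jr$distance["X", "Y"], 2 / 3)
  expect_equal(diag(jr$jaccard), c(X = 1, Y = 1))
  # 100 random binary matrices against the set oracle
  set.seed(62)
  for (i in 1:100) {
    n <- sample(5:25, 1); m <- sample(2:8, 1)
    bb <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.7)), n, m,
                 dimnames = list(NULL, paste0("m", seq_len(m))))
    bmi <- structure(list(values = bb), class = "BinaryMatrix")
    got <- suppressWarnings(pairwise_jaccard(bmi))
    expect_equal(unname(got$jaccard), oracle_jaccard(bb))
    expect_true(isSymmetric(got$jaccard))
    expect_true(all(got$jaccard >= 0 & got$jaccard <= 1))
    # Jaccard distance is a metric: triangle inequality
    D <- got$distance
    for (x in seq_len(m)) for (y in seq_len(m)) for (z in seq_len(m)) {
      expect_lte(D[x, y], D[x, z] + D[z, y] + 1e-12)
    }
  }
})

test_that("planted co-occurrence modules are extracted from the tree", {
  set.seed(63)
  n <- 300
  latent <- rbinom(n, 1, 0.4)
  mod <- sapply(1:6, function(i) rbinom(n, 1, ifelse(latent == 1, 0.9, 0.02)))
  bg <- sapply(1:6, function(i) rbinom(n, 1, 0.1))
  b <- cbind(mod, bg)
  colnames(b) <- c(paste0("mod", 1:6), paste0("bg", 1:6))
  keep <- rowSums(b) > 0
  bm <- structure(list(values = b[keep, ]), class = "BinaryMatrix")
  jr <- pairwise_jaccard(bm)
  mods <- extract_modules(jr, 0.5)
  expect_true(any(vapply(mods, function(m) setequal(m, paste0("mod", 1:6)),
                         logical(1))))
  # module extraction is invariant to marker order
  perm <- sample(ncol(b))
  bmp <- structure(list(values = b[keep, perm]), class = "BinaryMatrix")
  modsp <- extract_modules(pairwise_jaccard(bmp), 0.5)
  expect_true(any(vapply(modsp, function(m) setequal(m, paste0("mod", 1:6)),
                         logical(1))))
})

test_that("module extraction handles degenerate trees", {
  # mutually disjoint markers: no module of size >= 2
  b <- diag(1, 4)
  colnames(b) <- paste0("m", 1:4)
  bm <- structure(list(values = b), class = "BinaryMatrix")
  jr <- pairwise_jaccard(bm)
  expect_length(extract_modules(jr, 0.5), 0)
  # threshold 1.0: everything is one module
  expect_equal(extract_modules(jr, 1.0), list(paste0("m", 1:4)))
})

test_that("co-expression counts match brute-force row sums per ploidy", {
  set.seed(64)
  b <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  b[1, ] <- c(1, 0, 0, 0, 0)  # exactly one marker
  pl <- rep(c("2n", "4n"), 20)
  nuclei <- data.frame(nucleus_id = sprintf("N%02d", 1:40), ploidy = pl)
  bm <- structure(list(values = b, nuclei = nuclei), class = "BinaryMatrix")
  out <- coexpression_counts(bm, min_markers = 2)
  for (grp in c("2n", "4n")) {
    want <- mean(rowSums(b[pl == grp, ]) >= 2)
    expect_equal(out$coexpression$frac_coexpressing[out$coexpression$ploidy == grp],
                 want)
    expect_equal(out$marker_fractions[, grp],
                 colMeans(b[pl == grp, ]), ignore_attr = TRUE)
  }
  # a single-marker nucleus is not counted at min_markers = 2
  expect_false(rowSums(b)[1] >= 2)
  # NA ploidy is ignored
  pl2 <- pl; pl2[3] <- NA
  out2 <- coexpression_counts(bm, ploidy = pl2)
  expect_equal(sum(out2$coexpression$n_nuclei), 39)
})

test_that("the packaged stem panel is the ten-marker list", {
  panel <- stem_marker_panel()
  expect_length(panel, 10)
  expect_true(all(c("Lgr5", "Axin2", "Tert", "Epcam") %in% panel))
})
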