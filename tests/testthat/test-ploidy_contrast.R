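test_that("the detected-gene fold is a ratio of medians of raw detection", {
  # detections 2n {1000, 1200, 1400}, 4n {1500, 1500, 1500} -> 1.25
  g <- 2000
  det <- c(1000, 1200, 1400, 1500, 1500, 1500)
  endo <- t(vapply(det, function(k) c(rep(1L, k), rep(0L, g - k)), integer(g)))
  cm <- make_cm(endo, matrix(5, 6, 1), ploidy = rep(c("2n", "4n"), each = 3))
  expect_equal(detected_genes_fold(cm, ploidy_group(cm, "2n"),
                                   ploidy_group(cm, "4n")), 1.25)
  expect_equal(detected_genes_fold(cm, ploidy_group(cm, "2n"),
                                   ploidy_group(cm, "2n")), 1)
  cm0 <- make_cm(matrix(0L, 2, 4), matrix(5, 2, 1))
  expect_error(detected_genes_fold(cm0, 1, 2), "zero")
  expect_error(detected_genes_fold(cm, ploidy_group(cm, "8n"), 1:2), "non-empty")
})

test_that("Welch statistics match independent computations exactly", {
  a <- c(1.2, 0.8, 3.1, 2.2, 0.1, 1.1)
  b <- c(2.0, 2.4, 1.7, 3.3, 2.8)
  nm <- make_nm(matrix(c(a, b), ncol = 1))
  de <- welch_de(nm, group_a = 1:6, group_b = 7:11)
  expect_equal(de$t_stat, oracle_welch_t(a, b), tolerance = 1e-10)
  ref <- t.test(b, a)
  expect_equal(de$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(de$p, ref$p.value, tolerance = 1e-10)
  expect_equal(de$df, unname(ref$parameter), tolerance = 1e-8)
  # and across 100 random instances
  set.seed(41)
  for (i in 1:100) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    x <- rnorm(na); y <- rnorm(nb, 0.5)
    nm2 <- make_nm(matrix(c(x, y), ncol = 1))
    de2 <- welch_de(nm2, group_a = seq_len(na), group_b = na + seq_len(nb))
    expect_equal(de2$t_stat, oracle_welch_t(x, y), tolerance = 1e-10)
    expect_equal(de2$p, t.test(y, x)$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups yield no calls and zero-variance genes p = 1", {
  set.seed(42)
  vals <- matrix(rlnorm(40 * 50), 40, 50)
  vals[, 50] <- 2  # constant gene
  nm <- make_nm(log1p(vals))
  de <- welch_de(nm, group_a = 1:20, group_b = 1:20)
  expect_equal(sum(de$call != "ns"), 0)
  expect_equal(de$p[50], 1)
  expect_equal(de$t_stat[50], 0)
  # Bonferroni is p * n capped at 1
  de2 <- welch_de(nm, group_a = 1:20, group_b = 21:40)
  expect_equal(de2$p_bonferroni, pmin(1, de2$p * 50))
})

test_that("welch_de is antisymmetric under group exchange", {
  set.seed(43)
  vals <- log1p(matrix(rlnorm(60 * 80, 1, 1), 60, 80))
  vals[31:60, 1:5] <- vals[31:60, 1:5] + 2
  nm <- make_nm(vals)
  ab <- welch_de(nm, 1:30, 31:60)
  ba <- welch_de(nm, 31:60, 1:30)
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-9)
  expect_equal(ab$t_stat, -ba$t_stat, tolerance = 1e-9)
  expect_equal(ab$call == "up", ba$call == "down")
})

test_that("planted mean shifts are recovered with high precision and recall", {
  set.seed(44)
  g <- 2000; n <- 150
  mu <- rlnorm(g, log(5), 1)
  counts_a <- matrix(rnbinom(n * g, size = 1, mu = rep(mu, each = n)), n, g)
  mu_b <- mu
  mu_b[1:20] <- mu_b[1:20] * 4  # planted 4-fold shift
  counts_b <- matrix(rnbinom(n * g, size = 1, mu = rep(mu_b, each = n)), n, g)
  nm <- make_nm(log1p(rbind(counts_a, counts_b)))
  de <- welch_de(nm, seq_len(n), n + seq_len(n))
  called <- which(de$call != "ns")
  expect_gte(mean(called %in% 1:20), 0.9)      # precision
  expect_gte(mean(1:20 %in% called), 0.9)      # recall
})

test_that("the KS statistic equals the sup-distance of the empirical CDFs", {
  a <- c(0.0, 0.2, 0.4, 0.6)
  b <- c(0.5, 0.7, 0.9, 1.1)
  nm <- make_nm(matrix(c(a, b), ncol = 1))
  ks <- ks_shift(nm, 1:4, 5:8)
  expect_equal(ks$D, 0.75)
  expect_equal(ks$D, oracle_ks_D(a, b))
  # identical samples: D = 0, not shifted; disjoint supports: D = 1
  nm2 <- make_nm(matrix(rep(c(1, 2, 3, 4), 2), ncol = 1))
  ks2 <- ks_shift(nm2, 1:4, 5:8)
  expect_equal(ks2$D, 0)
  expect_false(ks2$shifted)
  nm3 <- make_nm(matrix(c(1, 2, 3, 4, 11, 12, 13, 14), ncol = 1))
  expect_equal(ks_shift(nm3, 1:4, 5:8)$D, 1)
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(45)
  for (i in 1:20) {
    na <- sample(5:15, 1); nb <- sample(5:15, 1)  # exact regime
    x <- round(rnorm(na), 1); y <- round(rnorm(nb, 0.4), 1)  # with ties
    nm <- make_nm(matrix(c(x, y), ncol = 1))
    ks <- ks_shift(nm, seq_len(na), na + seq_len(nb))
    ref <- suppressWarnings(ks.test(x, y, exact = TRUE))
    expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ks$p, ref$p.value, tolerance = 1e-8)
  }
  # asymptotic regime against the reference asymptotic p
  x <- rnorm(60); y <- rnorm(70, 0.3)
  nm <- make_nm(matrix(c(x, y), ncol = 1))
  ks <- ks_shift(nm, 1:60, 61:130)
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ks$p, ref$p.value, tolerance = 0.02)
})

test_that("the KS statistic is invariant under strictly monotone transforms", {
  set.seed(46)
  x <- rlnorm(25); y <- rlnorm(30, 0.5)
  d0 <- ks_shift(make_nm(matrix(c(x, y), ncol = 1)), 1:25, 26:55)$D
  for (f in list(function(v) v^3, function(v) log1p(v), function(v) 5 * v + 2)) {
    d1 <- ks_shift(make_nm(matrix(f(c(x, y)), ncol = 1)), 1:25, 26:55)$D
    expect_equal(d1, d0)
  }
})

test_that("the MA table applies the mean-expression window", {
  set.seed(47)
  vals <- log1p(matrix(rlnorm(40 * 60, 0, 2), 40, 60))
  nm <- make_nm(vals)
  de <- welch_de(nm, 1:20, 21:40)
  tab <- ma_table(de, mean_range = c(0.1, 100))
  expect_equal(nrow(tab), sum(de$base_mean >= 0.1 & de$base_mean <= 100))
  expect_true(all(tab$base_mean >= 0.1 & tab$base_mean <= 100))
  # explicit boundary behavior
  de_fake <- de
  de_fake$base_mean[1] <- 0.05
  de_fake$base_mean[2] <- 50
  tab2 <- ma_table(de_fake)
  expect_false(de_fake$feature_id[1] %in% tab2$feature_id)
  expect_true(de_fake$feature_id[2] %in% tab2$feature_id)
})
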