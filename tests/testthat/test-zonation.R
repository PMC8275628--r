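test_that("zonation clustering recovers lobule structure deterministically", {
  skip_if_not_installed("mclust")
  lob <- small_lobule(71)
  panel <- lob$truth$panels$zonation
  zc <- cluster_zonation_markers(lob$nm, panel, n_clusters = 3, seed = 7)
  expect_equal(length(unique(zc)), 3)
  terciles <- cut(lob$z, c(0, 1 / 3, 2 / 3, 1), include.lowest = TRUE)
  expect_gt(ari(zc, terciles), 0.7)
  zc2 <- cluster_zonation_markers(lob$nm, panel, n_clusters = 3, seed = 7)
  expect_identical(zc, zc2)
  # constant marker expression: single cluster with a warning
  flat <- make_nm(matrix(1, 30, 10),
                  gene_names = c(panel$pericentral[1:5], panel$periportal[1:5]))
  expect_warning(zc3 <- cluster_zonation_markers(flat, panel, seed = 1),
                 "constant")
  expect_equal(unique(zc3), 1L)
})

test_that("clusters are annotated CV/PV by their marker scores", {
  lob <- small_lobule(72)
  panel <- lob$truth$panels$zonation
  # two clusters from the latent halves themselves: annotation >= 90% accurate
  zc <- cluster_zonation_markers(lob$nm, panel, n_clusters = 2, seed = 7)
  za <- annotate_cv_pv(zc, lob$nm, panel)
  truth_zone <- ifelse(lob$z < 0.5, "CV", "PV")
  expect_gte(mean(za$zone == truth_zone), 0.9)
  # swapping the panel lists swaps every label
  swapped <- list(pericentral = panel$periportal, periportal = panel$pericentral)
  za2 <- annotate_cv_pv(zc, lob$nm, swapped)
  expect_true(all(za2$zone != za$zone))
})

test_that("a dominant pericentral signature labels the cluster CV", {
  set.seed(73)
  vals <- matrix(rlnorm(60 * 8, 1, 0.1), 60, 8)
  vals[1:30, 1:4] <- vals[1:30, 1:4] * 5  # pericentral genes up in cluster 1
  vals[31:60, 5:8] <- vals[31:60, 5:8] * 5
  nm <- make_nm(log1p(vals), gene_names = c(paste0("cv", 1:4), paste0("pv", 1:4)))
  panel <- list(pericentral = paste0("cv", 1:4), periportal = paste0("pv", 1:4))
  za <- annotate_cv_pv(rep(1:2, each = 30), nm, panel)
  expect_equal(unique(za$zone[1:30]), "CV")
  expect_equal(unique(za$zone[31:60]), "PV")
})

test_that("diffusion pseudotime recovers a noiseless 1-D gradient exactly", {
  n <- 60
  z <- seq(0, 1, length.out = n)
  vals <- cbind(3 - 2.5 * z, 0.5 + 2.5 * z)  # one falling, one rising marker
  nm <- make_nm(vals, gene_names = c("cv1", "pv1"))
  panel <- list(pericentral = "cv1", periportal = "pv1")
  dpt <- diffusion_pseudospace(nm, panel, k_neighbors = 10)
  expect_equal(order(dpt), order(z))
  expect_equal(dpt[1], 0)
  # reversing the root reverses the orientation
  dpt_rev <- diffusion_pseudospace(nm, panel, k_neighbors = 10,
                                   root = "periportal")
  expect_lt(cor(dpt, dpt_rev), -0.99)
})

test_that("pseudospace tracks the latent lobule coordinate in simulations", {
  lob <- small_lobule(74, n2 = 280, n4 = 320)  # ~600 hepatocytes
  dpt <- diffusion_pseudospace(lob$nm, lob$truth$panels$zonation)
  expect_gte(abs(cor(dpt, lob$z, method = "spearman")), 0.8)
  # invariance (up to orientation) to uniform scaling of the marker matrix
  nm2 <- lob$nm
  nm2$values <- nm2$values * 2
  dpt2 <- diffusion_pseudospace(nm2, lob$truth$panels$zonation)
  expect_gt(abs(cor(dpt, dpt2, method = "spearman")), 0.95)
})

test_that("a disconnected neighbor graph is reported", {
  vals <- rbind(matrix(0, 15, 2), matrix(100, 15, 2)) +
    matrix(runif(60, 0, 0.01), 30, 2)
  nm <- make_nm(vals, gene_names = c("cv1", "pv1"))
  panel <- list(pericentral = "cv1", periportal = "pv1")
  expect_error(diffusion_pseudospace(nm, panel, k_neighbors = 5),
               "disconnected")
})

test_that("ploidy enrichment follows its definition", {
  za <- data.frame(nucleus_id = sprintf("N%03d", 1:200),
                   zone_cluster = 1L,
                   zone = c(rep("CV", 65), rep("PV", 35),
                            rep("CV", 50), rep("PV", 50)))
  ploidy <- rep(c("4n", "2n"), each = 100)
  expect_equal(ploidy_enrichment(za, ploidy), 1.3)
  # zone independent of ploidy: enrichment 1
  za2 <- za
  za2$zone <- rep(c("CV", "PV"), 100)
  expect_equal(ploidy_enrichment(za2, ploidy), 1)
  # alternative definition: 4n CV fraction over the overall CV fraction
  expect_equal(ploidy_enrichment(za, ploidy, method = "vs_overall"),
               0.65 / 0.575)
  expect_error(ploidy_enrichment(za, rep("8n", 200)), "empty ploidy")
})

test_that("binned profiles average expression within pseudospace deciles", {
  set.seed(75)
  n <- 200
  dpt <- runif(n)
  vals <- cbind(exp(-2 * dpt) * 10, rep(3, n)) +
    matrix(abs(rnorm(2 * n, 0, 0.05)), n, 2)
  nm <- make_nm(vals, gene_names = c("cv1", "flat"))
  out <- bin_profiles(dpt, nm, c("cv1", "flat"), n_bins = 10)
  expect_equal(out$bin, oracle_bins(dpt, 10))
  # constant gene: flat profile
  expect_lt(diff(range(out$profile["flat", ])), 0.1)
  # strong pericentral gene: non-increasing along CV -> PV in >= 8/10 seeds
  mono <- 0L
  for (s in 1:10) {
    set.seed(800 + s)
    d <- runif(500)
    counts <- rnbinom(500, size = 8, mu = 80 * exp(-3 * d))
    nm_s <- make_nm(cbind(log1p(counts)), gene_names = "cv1")
    prof <- bin_profiles(d, nm_s, "cv1", n_bins = 10)$profile[1, ]
    if (all(diff(prof[!is.na(prof)]) <= 0.05)) mono <- mono + 1L
  }
  expect_gte(mono, 8)
})

test_that("zonation x ploidy intersections recover planted counts", {
  # ploidy placed independently of the zone (enrichment 1) so the planted
  # zonation-DE structure is the only zone-linked signal
  cfg <- sim_config(seed = 76, n_hep_2n = 350, n_hep_4n = 400,
                    n_other = c(hepatobiliary = 20, endothelial = 20),
                    n_genes = 1500, n_program = 300, n_housekeeping = 100,
                    n_ct_markers = 10, n_deg = 20,
                    n_pericentral = 40, n_periportal = 40,
                    n_zon_ploidy_only = 10, slope_range = c(2, 3),
                    zon_only_slope = 3, enrichment_4n_cv = 1)
  sim <- simulate_dataset(cfg)
  hep_ids <- sim$truth$nuclei$nucleus_id[sim$truth$nuclei$cell_type == "hepatocyte"]
  nm <- log_transform(normalize_eq1(sim$matrix[hep_ids, ]))
  z <- sim$truth$nuclei$z[match(nm$nuclei$nucleus_id, sim$truth$nuclei$nucleus_id)]
  za <- data.frame(nucleus_id = nm$nuclei$nucleus_id, zone_cluster = 1L,
                   zone = ifelse(z < 0.5, "CV", "PV"))
  zsum <- zonation_de_by_ploidy(nm, za)
  # planted: 30 shared pericentral + 10 pericentral only in 4n
  expect_lte(abs(zsum$cv_up_total - 40), 2)
  expect_lte(abs(zsum$cv_up_only_4n - 10), 2)
  expect_lte(abs(zsum$pv_up_total - 40), 2)
  expect_lte(abs(zsum$pv_up_only_2n - 10), 2)
  # counts are invariant to nucleus order
  perm <- sample(nrow(nm$values))
  zsum2 <- zonation_de_by_ploidy(nm[perm, ], za[perm, ])
  expect_equal(zsum2$cv_up_total, zsum$cv_up_total)
  expect_equal(zsum2$cv_up_only_4n, zsum$cv_up_only_4n)
  # a stratum below the minimum size is skipped with a warning
  tiny <- nm[c(1:15, 400:414), ]
  za_tiny <- za[match(tiny$nuclei$nucleus_id, za$nucleus_id), ]
  expect_warning(zonation_de_by_ploidy(tiny, za_tiny, min_group = 30),
                 "skipped")
})
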