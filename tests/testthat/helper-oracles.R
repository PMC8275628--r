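# Fixture builders and independent brute-force oracles used across the suite.

# --- fixture builders -------------------------------------------------------

# CountMatrix from an endogenous block and an ERCC block
make_cm <- function(endo, ercc, ploidy = NULL, dilution = NULL,
                    lengths = NULL, plate = NULL, tech = NULL) {
  n <- nrow(endo)
  g <- ncol(endo)
  e <- ncol(ercc)
  features <- data.frame(
    feature_id = c(sprintf("G%03d", seq_len(g)), sprintf("ERCC-%05d", seq_len(e))),
    gene_name = c(sprintf("g%03d", seq_len(g)), sprintf("ERCC-%05d", seq_len(e))),
    is_ercc = c(rep(FALSE, g), rep(TRUE, e)),
    length_kb = c(if (is.null(lengths)) rep(1, g) else lengths, rep(NA, e)))
  nuclei <- data.frame(
    nucleus_id = sprintf("N%03d", seq_len(n)),
    ploidy = if (is.null(ploidy)) rep("2n", n) else ploidy,
    plate_id = if (is.null(plate)) rep("P1", n) else plate,
    animal_id = "M1",
    dilution_group = if (is.null(dilution)) rep("d1", n) else dilution,
    is_technical_replicate = if (is.null(tech)) rep(FALSE, n) else tech)
  count_matrix(cbind(endo, ercc), features, nuclei)
}

# NormalizedMatrix straight from a values matrix (unit size factors)
make_nm <- function(values, is_log = TRUE, ploidy = NULL, plate = NULL,
                    gene_names = NULL) {
  n <- nrow(values)
  g <- ncol(values)
  features <- data.frame(
    feature_id = sprintf("G%03d", seq_len(g)),
    gene_name = if (is.null(gene_names)) sprintf("g%03d", seq_len(g)) else gene_names,
    is_ercc = FALSE, length_kb = 1)
  nuclei <- data.frame(
    nucleus_id = sprintf("N%04d", seq_len(n)),
    ploidy = if (is.null(ploidy)) rep("2n", n) else ploidy,
    plate_id = if (is.null(plate)) rep("P1", n) else plate,
    animal_id = "M1", dilution_group = "d1", is_technical_replicate = FALSE)
  sf <- data.frame(nucleus_id = nuclei$nucleus_id, sf = 1, dilution_group = "d1")
  normalized_matrix(values, features, nuclei, sf, is_log = is_log)
}

# random toy CountMatrix with wide QC spread
rand_cm <- function(seed, n = 50, g = 30, e = 4) {
  set.seed(seed)
  lib_scale <- exp(stats::runif(n, log(0.2), log(6)))
  endo <- matrix(stats::rpois(n * g, outer(lib_scale, stats::runif(g, 0.1, 8))), n, g)
  ercc <- matrix(stats::rpois(n * e, outer(lib_scale * stats::runif(n, 0.1, 3),
                                           stats::runif(e, 0.5, 6))), n, e)
  make_cm(endo, ercc)
}

toy_thresholds <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qc_thresholds(ercc_frac_min = stats::runif(1, 0.02, 0.15),
                ercc_frac_max = stats::runif(1, 0.5, 0.95),
                genes_min = sample(3:8, 1), genes_max = sample(20:29, 1),
                gene_min_cells = sample(2:6, 1), gene_min_reads = sample(3:12, 1),
                final_genes_max = sample(18:28, 1),
                lib_min = sample(10:40, 1), lib_max = sample(150:600, 1))
}

# small hepatocyte-rich simulation for zonation-level tests
small_lobule <- function(seed, n2 = 250, n4 = 300) {
  cfg <- sim_config(seed = seed, n_hep_2n = n2, n_hep_4n = n4,
                    n_other = c(hepatobiliary = 20, endothelial = 20),
                    n_genes = 1200, n_program = 250, n_housekeeping = 100,
                    n_pericentral = 80, n_periportal = 80, n_deg = 20,
                    n_ct_markers = 10)
  sim <- simulate_dataset(cfg)
  hep_ids <- sim$truth$nuclei$nucleus_id[sim$truth$nuclei$cell_type == "hepatocyte"]
  cm <- sim$matrix[hep_ids, ]
  nm <- log_transform(normalize_eq1(cm))
  z <- sim$truth$nuclei$z[match(nm$nuclei$nucleus_id, sim$truth$nuclei$nucleus_id)]
  list(nm = nm, cm = cm, z = z, truth = sim$truth, cfg = cfg)
}

# --- independent oracles ----------------------------------------------------

# QC cascade re-evaluated straight from the textual rules
oracle_qc <- function(cm, th) {
  endo <- as.matrix(cm$counts[, !cm$features$is_ercc, drop = FALSE])
  ercc <- as.matrix(cm$counts[, cm$features$is_ercc, drop = FALSE])
  total <- rowSums(endo) + rowSums(ercc)
  frac <- ifelse(total > 0, rowSums(ercc) / total, 0)
  ngenes <- rowSums(endo > 0)
  lib <- if (th$library_includes_ercc) total else rowSums(endo)
  nuc <- cm$nuclei$nucleus_id
  keep <- frac > th$ercc_frac_min & frac < th$ercc_frac_max
  keep <- keep & (ngenes > th$genes_min & ngenes < th$genes_max)
  endo_k <- endo[keep, , drop = FALSE]
  gkeep <- logical(ncol(endo_k))
  for (j in seq_len(ncol(endo_k))) {
    cells <- sum(endo_k[, j] > 0)
    reads <- sum(endo_k[, j])
    gkeep[j] <- if (th$gene_rule == "both") {
      cells >= th$gene_min_cells && reads >= th$gene_min_reads
    } else {
      cells >= th$gene_min_cells || reads >= th$gene_min_reads
    }
  }
  keep2 <- keep & ngenes < th$final_genes_max & lib >= th$lib_min & lib <= th$lib_max
  list(nuclei = nuc[keep2],
       features = c(cm$features$feature_id[!cm$features$is_ercc][gkeep],
                    cm$features$feature_id[cm$features$is_ercc]))
}

# Jaccard similarity from explicit index sets
oracle_jaccard <- function(b) {
  m <- ncol(b)
  J <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      X <- which(b[, i] == 1)
      Y <- which(b[, j] == 1)
      u <- length(union(X, Y))
      J[i, j] <- if (u == 0) 0 else length(intersect(X, Y)) / u
    }
  }
  diag(J) <- 1
  J
}

# two-sample KS statistic: sup over pooled unique breakpoints
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Welch t from the textbook formula (b relative to a)
oracle_welch_t <- function(a, b) {
  (mean(b) - mean(a)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# exact two-sided Mann-Whitney p by enumeration of all assignments (no ties)
oracle_mw_p <- function(x, y) {
  n <- length(x)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + length(y), n)
  all_r <- rank(c(x, y))
  dist <- apply(combos, 2, function(ii) sum(all_r[ii]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(dist <= u_obs), mean(dist >= u_obs)))
}

# decile/bin assignment by direct interval search
oracle_bins <- function(dpt, n_bins) {
  vapply(dpt, function(v) {
    if (v >= 1) return(n_bins)
    for (b in seq_len(n_bins)) {
      if (v >= (b - 1) / n_bins && v < b / n_bins) return(b)
    }
    stop("unreachable")
  }, integer(1))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
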