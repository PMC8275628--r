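# Pipeline orchestration: a validated configuration object and a stage
# runner that chains the analysis in study order (simulate/load -> QC ->
# normalize -> cluster/annotate -> ploidy contrasts -> variability ->
# co-expression -> zonation), writing TSV/JSON artifacts and a run manifest.

#' Pipeline configuration
#'
#' Central configuration for [run_pipeline()]. Thresholds default to the
#' study values where the study states them; every stochastic stage takes
#' its seed from `seed`. Either `input` (a directory readable by
#' [read_count_matrix()]) or `simulate = TRUE` must be chosen.
#'
#' @param seed integer seed used for every stochastic step.
#' @param input optional path to an MTX directory with a count matrix.
#' @param simulate simulate input data with [simulate_dataset()] instead of
#'   reading it (default `TRUE` when `input` is `NULL`).
#' @param sim a [sim_config()] (defaults to `sim_config(seed)`).
#' @param qc a [qc_thresholds()] object; defaults to [sim_qc_thresholds()]
#'   when simulating and to the study thresholds otherwise.
#' @param scale_constant normalization scale constant (study value 10000).
#' @param max_norm_total post-normalization cap (study value 50000).
#' @param batch_correct apply plate-covariate batch correction (default
#'   `FALSE`; the simulation plants no plate effects).
#' @param n_pcs,k_neighbors,resolution clustering parameters.
#' @param lfc_threshold,alpha DE call rules (study values 0.5 / 0.05).
#' @param ks_d_threshold KS call rule (study value 0.15).
#' @param coexpr_distance_threshold Jaccard tree cut (default 0.5).
#' @param n_bins pseudospace bins (study value 10).
#' @param zone_clusters zonation cluster count (study value 3).
#' @param celltype_panel,zonation_panel,stem_markers panels; `NULL` means the
#'   simulation's own panels (when simulating) or the packaged panels.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, input = NULL, simulate = is.null(input),
                            sim = NULL, qc = NULL,
                            scale_constant = 10000, max_norm_total = 50000,
                            batch_correct = FALSE,
                            n_pcs = 50, k_neighbors = 15, resolution = 1,
                            lfc_threshold = 0.5, alpha = 0.05,
                            ks_d_threshold = 0.15,
                            coexpr_distance_threshold = 0.5,
                            n_bins = 10, zone_clusters = 3,
                            celltype_panel = NULL, zonation_panel = NULL,
                            stem_markers = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  if (!simulate && is.null(input)) stop("either simulate or provide an input path")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(qc)) qc <- if (simulate) sim_qc_thresholds() else qc_thresholds()
  cfg <- list(seed = as.integer(seed), input = input, simulate = simulate,
              sim = sim, qc = qc, scale_constant = scale_constant,
              max_norm_total = max_norm_total, batch_correct = batch_correct,
              n_pcs = n_pcs, k_neighbors = k_neighbors, resolution = resolution,
              lfc_threshold = lfc_threshold, alpha = alpha,
              ks_d_threshold = ks_d_threshold,
              coexpr_distance_threshold = coexpr_distance_threshold,
              n_bins = n_bins, zone_clusters = zone_clusters,
              celltype_panel = celltype_panel,
              zonation_panel = zonation_panel, stem_markers = stem_markers)
  for (p in c("scale_constant", "max_norm_total", "n_pcs", "k_neighbors",
              "resolution", "lfc_threshold", "alpha", "ks_d_threshold",
              "coexpr_distance_threshold", "n_bins", "zone_clusters")) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0) {
      stop("invalid pipeline parameter '", p, "': must be a positive number")
    }
  }
  if (alpha >= 1) stop("alpha must be below 1")
  structure(cfg, class = "pipeline_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in study order and writes each stage's
#' artifacts under `outdir`, plus a machine-readable `manifest.json`
#' (package version, seed, thresholds, stages run). Stages:
#' `simulate` (or load), `qc`, `normalize`, `cluster`, `ploidy`,
#' `variability`, `coexpr`, `zonation`; `"all"` chains everything. Outputs
#' are byte-identical across reruns with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages character vector of stage names or `"all"`.
#' @return (invisibly) a list with the in-memory results of every stage run.
#' @export
run_pipeline <- function(config, outdir, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "qc", "normalize", "cluster", "ploidy",
                  "variability", "coexpr", "zonation")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # stages run in order; a later stage recomputes everything it depends on
  stages <- all_stages[seq_len(max(match(stages, all_stages)))]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  ## input
  if (config$simulate) {
    sim <- simulate_dataset(config$sim)
    res$truth <- sim$truth
    res$raw <- sim$matrix
    if ("simulate" %in% stages) {
      write_count_matrix(sim$matrix, file.path(outdir, "counts"))
      .write_tsv(sim$truth$nuclei, file.path(outdir, "ground_truth_nuclei.tsv"))
      .write_tsv(sim$truth$genes, file.path(outdir, "ground_truth_genes.tsv"))
    }
    panels <- sim$truth$panels
  } else {
    res$raw <- read_count_matrix(config$input)
    panels <- list(celltype = read_marker_panel(),
                   zonation = zonation_panel(),
                   stem_markers = stem_marker_panel())
  }
  # explicit panels in the config (panel objects, not paths) win
  if (!is.null(config$celltype_panel)) panels$celltype <- config$celltype_panel
  if (!is.null(config$zonation_panel)) panels$zonation <- config$zonation_panel
  if (!is.null(config$stem_markers)) panels$stem_markers <- config$stem_markers

  ## qc
  cm <- drop_technical_replicates(res$raw)
  qcres <- apply_qc_filters(cm, config$qc)
  res$qc <- qcres
  if ("qc" %in% stages) {
    write_filter_report(qcres$report, file.path(outdir, "filter_report.json"))
  }
  cm <- qcres$matrix
  if (nrow(cm$counts) == 0L) stop("no nuclei survive QC; nothing to analyze")

  ## normalize
  sf <- ercc_size_factors(cm)
  nm <- normalize_eq1(cm, sf, scale_constant = config$scale_constant)
  nm <- post_normalization_filter(nm, config$max_norm_total)
  cm <- cm[nm$nuclei$nucleus_id, ]
  nm <- log_transform(nm)
  if (config$batch_correct) nm <- batch_correct(nm)
  res$normalized <- nm
  res$counts_filtered <- cm
  if ("normalize" %in% stages) {
    .write_tsv(nm$size_factors, file.path(outdir, "size_factors.tsv"))
    write_normalized_matrix(nm, file.path(outdir, "normalized"))
  }
  if (!any(stages %in% all_stages[-(1:3)])) {
    .write_manifest(config, outdir, stages)
    return(invisible(res))
  }

  ## cluster + annotate
  ca <- embed_and_cluster(nm, n_pcs = config$n_pcs,
                          k_neighbors = config$k_neighbors,
                          resolution = config$resolution, seed = config$seed)
  ca <- annotate_clusters(ca, nm, panels$celltype)
  res$clusters <- ca
  if ("cluster" %in% stages) .write_tsv(ca, file.path(outdir, "clusters.tsv"))
  hep <- subset_hepatocytes(nm, ca)
  hep_cm <- cm[hep$nuclei$nucleus_id, ]
  res$hepatocytes <- hep

  ## ploidy contrasts (2n vs 4n hepatocytes)
  if ("ploidy" %in% stages) {
    g2 <- ploidy_group(hep, "2n"); g4 <- ploidy_group(hep, "4n")
    res$detected_fold <- detected_genes_fold(hep_cm, ploidy_group(hep_cm, "2n"),
                                             ploidy_group(hep_cm, "4n"))
    de <- welch_de(hep, g2, g4, lfc_threshold = config$lfc_threshold,
                   alpha = config$alpha)
    shift <- ks_shift(hep, g2, g4, d_threshold = config$ks_d_threshold,
                      alpha = config$alpha)
    res$de <- de
    res$ks <- shift
    .write_tsv(de, file.path(outdir, "de_2n_vs_4n.tsv"))
    .write_tsv(shift, file.path(outdir, "ks_2n_vs_4n.tsv"))
    jsonlite::write_json(c(de_summary(de, shift),
                           detected_genes_fold = res$detected_fold),
                         file.path(outdir, "ploidy_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## variability
  if ("variability" %in% stages) {
    vr <- cv_compare(hep, ploidy_group(hep, "2n"), ploidy_group(hep, "4n"))
    res$variability <- vr
    hv2 <- hvg_nonde_count(hep, ploidy_group(hep, "2n"), res$de)
    hv4 <- hvg_nonde_count(hep, ploidy_group(hep, "4n"), res$de)
    res$hvg <- list(`2n` = hv2, `4n` = hv4)
    .write_tsv(vr$cv_table, file.path(outdir, "cv_per_gene.tsv"))
    jsonlite::write_json(list(ratio_of_medians = vr$ratio_of_medians,
                              mw_p = vr$mw_p,
                              n_hvg_non_de_2n = hv2$n_hvg_non_de,
                              n_hvg_non_de_4n = hv4$n_hvg_non_de),
                         file.path(outdir, "variability_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## stem-marker co-expression
  if ("coexpr" %in% stages) {
    bm <- subset_markers_drop_empty(binarize(hep), panels$stem_markers)
    jr <- pairwise_jaccard(bm)
    mods <- extract_modules(jr, config$coexpr_distance_threshold)
    cc <- coexpression_counts(bm)
    res$coexpr <- list(binary = bm, jaccard = jr, modules = mods, counts = cc)
    .write_tsv(data.frame(marker = rownames(jr$jaccard), jr$jaccard,
                          check.names = FALSE),
               file.path(outdir, "jaccard.tsv"))
    jsonlite::write_json(list(n_nuclei = nrow(bm$values),
                              n_markers = ncol(bm$values),
                              modules = mods,
                              coexpression = cc$coexpression),
                         file.path(outdir, "coexpression.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  ## zonation
  if ("zonation" %in% stages) {
    zc <- cluster_zonation_markers(hep, panels$zonation,
                                   n_clusters = config$zone_clusters,
                                   k_neighbors = config$k_neighbors,
                                   seed = config$seed)
    za <- annotate_cv_pv(zc, hep, panels$zonation)
    dpt <- diffusion_pseudospace(hep, panels$zonation,
                                 k_neighbors = config$k_neighbors)
    za$dpt <- dpt
    enr <- ploidy_enrichment(za, hep$nuclei$ploidy)
    prof_genes <- c(panels$zonation$pericentral[seq_len(min(4, length(panels$zonation$pericentral)))],
                    panels$zonation$periportal[seq_len(min(4, length(panels$zonation$periportal)))])
    prof <- bin_profiles(dpt, hep, prof_genes, n_bins = config$n_bins)
    za$bin <- prof$bin
    zsum <- zonation_de_by_ploidy(hep, za, lfc_threshold = config$lfc_threshold,
                                  alpha = config$alpha)
    res$zonation <- list(assignment = za, enrichment = enr,
                         profiles = prof$profile, summary = zsum)
    .write_tsv(za, file.path(outdir, "zonation_assignment.tsv"))
    .write_tsv(data.frame(gene = rownames(prof$profile), prof$profile,
                          check.names = FALSE),
               file.path(outdir, "zonation_profiles.tsv"))
    jsonlite::write_json(list(pericentral_enrichment_4n = enr,
                              cv_up_total = zsum$cv_up_total,
                              cv_up_only_4n = zsum$cv_up_only_4n,
                              pv_up_total = zsum$pv_up_total,
                              pv_up_only_2n = zsum$pv_up_only_2n),
                         file.path(outdir, "zonation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  .write_manifest(config, outdir, stages)
  invisible(res)
}

.write_manifest <- function(config, outdir, stages) {
  manifest <- list(
    package = "hepnuc",
    version = as.character(utils::packageVersion("hepnuc")),
    seed = config$seed,
    stages = stages,
    simulate = config$simulate,
    thresholds = list(qc = unclass(config$qc),
                      scale_constant = config$scale_constant,
                      max_norm_total = config$max_norm_total,
                      lfc_threshold = config$lfc_threshold,
                      alpha = config$alpha,
                      ks_d_threshold = config$ks_d_threshold,
                      coexpr_distance_threshold = config$coexpr_distance_threshold,
                      n_bins = config$n_bins,
                      zone_clusters = config$zone_clusters))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}
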