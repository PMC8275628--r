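#' Per-nucleus quality-control metrics
#'
#' Computes, for every nucleus, the library size (sum of all feature counts,
#' spike-ins included by default), the number of endogenous genes detected
#' (count > 0) and the fraction of counts that map to ERCC spike-in species.
#'
#' @param cm a `CountMatrix`.
#' @param library_includes_ercc if `FALSE`, library size is computed over
#'   endogenous genes only. The default mirrors "mapped reads", which include
#'   the spike-ins.
#' @return data.frame with columns `nucleus_id`, `library_size`,
#'   `n_genes_detected`, `ercc_fraction` (0 for empty nuclei).
#' @export
compute_qc <- function(cm, library_includes_ercc = TRUE) {
  total <- as.numeric(Matrix::rowSums(cm$counts))
  ercc <- as.numeric(Matrix::rowSums(ercc_counts(cm)))
  lib <- if (library_includes_ercc) total else total - ercc
  ngene <- as.numeric(Matrix::rowSums(endo_counts(cm) > 0))
  frac <- ifelse(total > 0, ercc / total, 0)
  data.frame(nucleus_id = cm$nuclei$nucleus_id, library_size = lib,
             n_genes_detected = ngene, ercc_fraction = frac,
             stringsAsFactors = FALSE)
}

#' QC filter thresholds
#'
#' Defaults are the study values for a ~54k-gene, ~200k-read matrix: nuclei
#' kept if the ERCC fraction is strictly between 5% and 90% and the number of
#' detected genes strictly between 1000 and 7000; genes kept if detected in at
#' least 25 nuclei and carrying at least 250 total reads; finally nuclei kept
#' if they have fewer than 7000 detected genes and a library size between
#' 10000 and 300000 reads (inclusive). Every threshold is configurable; use
#' scaled values for matrices of different depth/size.
#'
#' @param ercc_frac_min,ercc_frac_max strict ERCC-fraction window.
#' @param genes_min,genes_max strict detected-genes window.
#' @param gene_min_cells,gene_min_reads gene-level filter thresholds.
#' @param gene_rule `"both"` keeps genes meeting *both* gene-level criteria
#'   (the stricter reading of removing genes sequenced in few cells and with
#'   low read count); `"either"` keeps genes meeting at least one.
#' @param final_genes_max strict upper bound on detected genes in the final
#'   nucleus filter.
#' @param lib_min,lib_max inclusive library-size window.
#' @param library_includes_ercc whether library size counts spike-in reads.
#' @return a named list of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(ercc_frac_min = 0.05, ercc_frac_max = 0.90,
                          genes_min = 1000, genes_max = 7000,
                          gene_min_cells = 25, gene_min_reads = 250,
                          gene_rule = c("both", "either"),
                          final_genes_max = 7000,
                          lib_min = 10000, lib_max = 300000,
                          library_includes_ercc = TRUE) {
  gene_rule <- match.arg(gene_rule)
  th <- list(ercc_frac_min = ercc_frac_min, ercc_frac_max = ercc_frac_max,
             genes_min = genes_min, genes_max = genes_max,
             gene_min_cells = gene_min_cells, gene_min_reads = gene_min_reads,
             gene_rule = gene_rule, final_genes_max = final_genes_max,
             lib_min = lib_min, lib_max = lib_max,
             library_includes_ercc = library_includes_ercc)
  num <- vapply(th[setdiff(names(th), c("gene_rule", "library_includes_ercc"))],
                is.numeric, logical(1))
  if (!all(num)) stop("thresholds must be numeric")
  if (any(unlist(th[names(num)]) < 0)) stop("thresholds must be non-negative")
  if (ercc_frac_min >= ercc_frac_max || genes_min >= genes_max ||
      lib_min > lib_max) {
    stop("threshold windows must be non-empty")
  }
  structure(th, class = "qc_thresholds")
}

#' Apply the ordered QC filter cascade
#'
#' Filters are applied in the order of the study's processing: (1) nuclei by
#' ERCC-fraction window, (2) nuclei by detected-genes window, (3) endogenous
#' genes by detection breadth and total read count, (4) nuclei by a final
#' detected-genes cap and library-size window. Nucleus-level metrics
#' (detected genes, library size, ERCC fraction) are computed once on the full
#' feature universe and reused in every nucleus step, matching the stated
#' step order; ERCC features are never removed by the gene filter (they are
#' needed later for size factors).
#'
#' @param cm a `CountMatrix`.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `matrix` (the filtered `CountMatrix`) and `report` (a
#'   `FilterReport`: ordered per-step nucleus/feature counts plus the
#'   thresholds used).
#' @export
apply_qc_filters <- function(cm, thresholds = qc_thresholds()) {
  th <- thresholds
  qc <- compute_qc(cm, library_includes_ercc = th$library_includes_ercc)
  steps <- list(list(step = "input", n_nuclei = nrow(cm$counts),
                     n_features = ncol(cm$counts)))

  keep_n <- qc$ercc_fraction > th$ercc_frac_min & qc$ercc_fraction < th$ercc_frac_max
  cm <- cm[keep_n, ]
  qc <- qc[keep_n, , drop = FALSE]
  steps <- c(steps, list(list(step = "ercc_fraction_window",
                              n_nuclei = nrow(cm$counts), n_features = ncol(cm$counts))))

  keep_n <- qc$n_genes_detected > th$genes_min & qc$n_genes_detected < th$genes_max
  cm <- cm[keep_n, ]
  qc <- qc[keep_n, , drop = FALSE]
  steps <- c(steps, list(list(step = "genes_detected_window",
                              n_nuclei = nrow(cm$counts), n_features = ncol(cm$counts))))

  endo <- endo_counts(cm)
  n_cells <- as.numeric(Matrix::colSums(endo > 0))
  n_reads <- as.numeric(Matrix::colSums(endo))
  ok <- if (th$gene_rule == "both") {
    n_cells >= th$gene_min_cells & n_reads >= th$gene_min_reads
  } else {
    n_cells >= th$gene_min_cells | n_reads >= th$gene_min_reads
  }
  keep_f <- cm$features$is_ercc
  keep_f[!cm$features$is_ercc] <- ok
  cm <- cm[, keep_f]
  steps <- c(steps, list(list(step = "gene_filter",
                              n_nuclei = nrow(cm$counts), n_features = ncol(cm$counts))))

  keep_n <- qc$n_genes_detected < th$final_genes_max &
    qc$library_size >= th$lib_min & qc$library_size <= th$lib_max
  cm <- cm[keep_n, ]
  steps <- c(steps, list(list(step = "final_genes_and_library",
                              n_nuclei = nrow(cm$counts), n_features = ncol(cm$counts))))

  report <- structure(
    list(steps = do.call(rbind, lapply(steps, as.data.frame)),
         thresholds = unclass(th)),
    class = "FilterReport")
  if (nrow(cm$counts) == 0L) warning("no nuclei left after QC filtering")
  list(matrix = cm, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("QC filter cascade:\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Serialize a FilterReport to JSON
#' @param report a `FilterReport`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(list(steps = report$steps, thresholds = report$thresholds),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Remove flagged technical replicates
#'
#' Nuclei flagged as technical replicates (re-sequenced wells containing the
#' same material as another library) are dropped before normalization.
#'
#' @param cm a `CountMatrix`.
#' @return the `CountMatrix` without flagged nuclei.
#' @export
drop_technical_replicates <- function(cm) {
  flag <- cm$nuclei$is_technical_replicate
  flag[is.na(flag)] <- FALSE
  if (all(flag)) warning("all nuclei are flagged as technical replicates")
  cm[!flag, ]
}
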