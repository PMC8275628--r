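#' ERCC spike-in size factors
#'
#' The size factor of a nucleus is its total ERCC count divided by the mean
#' ERCC total across all nuclei that received the same spike-in dilution, so
#' size factors average to exactly 1 within each dilution group. Because the
#' spike-in input is constant within a dilution, the size factor measures the
#' per-nucleus technical capture/sequencing efficiency.
#'
#' @param cm a `CountMatrix` (after QC; every nucleus must have ERCC counts).
#' @return data.frame with `nucleus_id`, `sf`, `dilution_group`.
#' @export
ercc_size_factors <- function(cm) {
  ercc_sum <- as.numeric(Matrix::rowSums(ercc_counts(cm)))
  if (any(ercc_sum <= 0)) {
    stop("nuclei with zero ERCC counts (should have been removed by QC): ",
         paste(utils::head(cm$nuclei$nucleus_id[ercc_sum <= 0], 5), collapse = ", "))
  }
  group <- cm$nuclei$dilution_group
  grp_mean <- tapply(ercc_sum, group, mean)
  sf <- ercc_sum / as.numeric(grp_mean[group])
  data.frame(nucleus_id = cm$nuclei$nucleus_id, sf = sf,
             dilution_group = group, stringsAsFactors = FALSE)
}

#' Gene-length and ERCC-coverage normalization
#'
#' Endogenous counts are divided by gene length in kilobases, then each
#' nucleus is rescaled so that its length-normalized total equals
#' `scale_constant` times its ERCC size factor:
#' \deqn{x'_{ij} = \frac{x_{ij}/L_j}{\sum_j (x_{ij}/L_j) \,/\, (c \cdot sf_i)}}
#' Nuclei with few endogenous reads relative to their spike-ins are thereby
#' divided by a smaller factor than nuclei with proportionally many endogenous
#' reads, so absolute differences in transcriptome size that the spike-ins
#' reveal are retained rather than flattened. ERCC features are excluded from
#' the output.
#'
#' @param cm a `CountMatrix`.
#' @param sf size factor table from [ercc_size_factors()] (computed if `NULL`).
#' @param scale_constant the constant `c` above; the study value is 10000.
#' @return a `NormalizedMatrix` whose per-nucleus totals equal
#'   `scale_constant * sf`.
#' @export
normalize_eq1 <- function(cm, sf = NULL, scale_constant = 10000) {
  if (is.null(sf)) sf <- ercc_size_factors(cm)
  stopifnot(identical(sf$nucleus_id, cm$nuclei$nucleus_id))
  endo_feat <- cm$features[!cm$features$is_ercc, , drop = FALSE]
  if (anyNA(endo_feat$length_kb)) {
    stop("missing gene lengths for: ",
         paste(utils::head(endo_feat$feature_id[is.na(endo_feat$length_kb)], 5),
               collapse = ", "))
  }
  x <- as.matrix(endo_counts(cm))
  per_kb <- sweep(x, 2L, endo_feat$length_kb, "/")
  totals <- rowSums(per_kb)
  if (any(totals <= 0)) {
    stop("nuclei with zero endogenous counts: ",
         paste(utils::head(cm$nuclei$nucleus_id[totals <= 0], 5), collapse = ", "))
  }
  factor_i <- totals / (scale_constant * sf$sf)
  values <- per_kb / factor_i
  normalized_matrix(values, endo_feat, cm$nuclei, sf,
                    scale_constant = scale_constant)
}

#' Remove nuclei with excessive normalized totals
#'
#' After normalization, a nucleus's total equals `scale_constant * sf`, so
#' this removes nuclei whose spike-in-implied coverage is extreme (the study
#' cap is 50000 length-normalized total counts, i.e. a size factor above 5 at
#' the default scale constant).
#'
#' @param nm a `NormalizedMatrix`, not yet log-transformed.
#' @param max_total inclusive cap on the per-nucleus normalized total.
#' @return the filtered `NormalizedMatrix`.
#' @export
post_normalization_filter <- function(nm, max_total = 50000) {
  if (nm$is_log) stop("apply the post-normalization filter before log transform")
  keep <- rowSums(nm$values) <= max_total
  nm[keep, ]
}

#' Natural-log transform
#'
#' Replaces values by `log(1 + x)`. Refuses to run twice.
#'
#' @param nm a `NormalizedMatrix`.
#' @return the log-transformed `NormalizedMatrix` (`is_log = TRUE`).
#' @export
log_transform <- function(nm) {
  if (nm$is_log) stop("matrix is already log-transformed")
  nm$values <- log1p(nm$values)
  nm$is_log <- TRUE
  nm
}

#' Empirical-Bayes batch correction across plates
#'
#' Location/scale batch adjustment (the ComBat algorithm, delegated to
#' \pkg{sva}) of the log-transformed matrix with the plate as the batch
#' covariate. Genes with zero variance across nuclei are passed through
#' unchanged. Optional: single-plate data needs no correction.
#'
#' @param nm a log-transformed `NormalizedMatrix`.
#' @param covariate name of the nucleus metadata column holding the batch
#'   (default `"plate_id"`).
#' @param mean_only if `TRUE`, adjust batch locations only (the fallback for
#'   very small batches).
#' @return the corrected `NormalizedMatrix` (`is_batch_corrected = TRUE`);
#'   dimensions and nucleus order are unchanged.
#' @export
batch_correct <- function(nm, covariate = "plate_id", mean_only = FALSE) {
  if (!nm$is_log) stop("batch correction expects log-transformed values")
  if (!requireNamespace("sva", quietly = TRUE)) {
    stop("batch_correct requires the 'sva' package")
  }
  batch <- nm$nuclei[[covariate]]
  if (is.null(batch)) stop("no such nucleus metadata column: ", covariate)
  sizes <- table(batch)
  if (length(sizes) < 2L) return(nm)  # nothing to correct
  if (any(sizes < 2L)) {
    stop("batches with a single nucleus: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  dat <- t(nm$values)  # genes x nuclei
  keep <- apply(dat, 1L, stats::var) > 0
  corrected <- dat
  if (any(keep)) {
    corrected[keep, ] <- suppressMessages(
      sva::ComBat(dat[keep, , drop = FALSE], batch = batch,
                  mean.only = mean_only))
  }
  nm$values <- t(corrected)
  nm$is_batch_corrected <- TRUE
  nm
}
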