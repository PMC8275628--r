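#' Construct a validated nuclei x features count matrix
#'
#' The central data container of the package: raw, non-negative integer counts
#' for single nuclei over a feature set that mixes endogenous genes and ERCC
#' spike-in species, together with a feature table and a nucleus metadata
#' table. All downstream steps (QC, size factors, normalization) start here.
#'
#' @param counts numeric matrix or [Matrix::sparseMatrix()], nuclei in rows and
#'   features in columns; entries must be non-negative integers.
#' @param features data.frame with columns `feature_id`, `gene_name`,
#'   `is_ercc` (logical) and `length_kb` (gene length in kilobases, positive
#'   for endogenous genes). If `is_ercc` is missing it is derived from the
#'   `"ERCC-"` prefix of `feature_id`.
#' @param nuclei data.frame with columns `nucleus_id`, `ploidy` (one of
#'   `"2n"`, `"4n"`, `"8n"`, `"16n"`), `plate_id`, `animal_id`,
#'   `dilution_group` and `is_technical_replicate` (logical). Missing optional
#'   columns are filled with placeholders.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, features, nuclei) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(length(dim(counts)) == 2L)
  features <- .complete_feature_table(features)
  nuclei <- .complete_nucleus_table(nuclei)
  if (nrow(counts) != nrow(nuclei)) {
    stop("count matrix has ", nrow(counts), " rows but nucleus table has ",
         nrow(nuclei), " entries")
  }
  if (ncol(counts) != nrow(features)) {
    stop("count matrix has ", ncol(counts), " columns but feature table has ",
         nrow(features), " entries")
  }
  .check_count_values(counts)
  rownames(counts) <- nuclei$nucleus_id
  colnames(counts) <- features$feature_id
  structure(list(counts = counts, features = features, nuclei = nuclei),
            class = "CountMatrix")
}

.complete_feature_table <- function(features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(features)) stop("feature table needs a 'feature_id' column")
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) stop("duplicate feature_id values")
  if (!"gene_name" %in% names(features)) features$gene_name <- features$feature_id
  if (!"is_ercc" %in% names(features)) {
    features$is_ercc <- startsWith(features$feature_id, "ERCC-")
  }
  features$is_ercc <- as.logical(features$is_ercc)
  if (anyNA(features$is_ercc)) stop("is_ercc flags must be TRUE/FALSE")
  if (!"length_kb" %in% names(features)) features$length_kb <- NA_real_
  endo_len <- features$length_kb[!features$is_ercc]
  if (any(!is.na(endo_len) & endo_len <= 0)) {
    stop("length_kb must be positive for endogenous genes")
  }
  rownames(features) <- NULL
  features
}

.complete_nucleus_table <- function(nuclei) {
  nuclei <- as.data.frame(nuclei, stringsAsFactors = FALSE)
  if (!"nucleus_id" %in% names(nuclei)) stop("nucleus table needs a 'nucleus_id' column")
  nuclei$nucleus_id <- as.character(nuclei$nucleus_id)
  if (anyDuplicated(nuclei$nucleus_id)) stop("duplicate nucleus_id values")
  if (!"ploidy" %in% names(nuclei)) nuclei$ploidy <- NA_character_
  known <- c("2n", "4n", "8n", "16n")
  bad <- !is.na(nuclei$ploidy) & !nuclei$ploidy %in% known
  if (any(bad)) stop("unknown ploidy values: ", paste(unique(nuclei$ploidy[bad]), collapse = ", "))
  for (col in c("plate_id", "animal_id", "dilution_group")) {
    if (!col %in% names(nuclei)) nuclei[[col]] <- "unknown"
    nuclei[[col]] <- as.character(nuclei[[col]])
  }
  if (!"is_technical_replicate" %in% names(nuclei)) nuclei$is_technical_replicate <- FALSE
  nuclei$is_technical_replicate <- as.logical(nuclei$is_technical_replicate)
  rownames(nuclei) <- NULL
  nuclei
}

.check_count_values <- function(counts) {
  x <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(x)) {
    if (anyNA(x)) stop("counts contain missing values")
    if (any(x < 0)) stop("counts must be non-negative")
    if (any(x != round(x))) stop("counts must be integral")
  }
  invisible(TRUE)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "nuclei x", ncol(x$counts), "features (",
      sum(x$features$is_ercc), "ERCC )\n")
  tab <- table(x$nuclei$ploidy, useNA = "ifany")
  cat("  ploidy:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a CountMatrix by nuclei and/or features
#'
#' @param x a `CountMatrix`.
#' @param i nucleus index (integer, logical, or nucleus_id character vector).
#' @param j feature index (integer, logical, or feature_id character vector).
#' @param ... ignored.
#' @return the subsetted `CountMatrix`.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$nuclei$nucleus_id)
  if (is.character(j)) j <- match(j, x$features$feature_id)
  if (anyNA(i) || anyNA(j)) stop("unknown nucleus or feature ids in subset")
  count_matrix(x$counts[i, j, drop = FALSE],
               x$features[j, , drop = FALSE],
               x$nuclei[i, , drop = FALSE])
}

#' Endogenous (non-spike-in) part of a count matrix
#' @param cm a `CountMatrix`.
#' @return matrix of counts over endogenous genes only.
#' @export
endo_counts <- function(cm) cm$counts[, !cm$features$is_ercc, drop = FALSE]

#' ERCC spike-in part of a count matrix
#' @param cm a `CountMatrix`.
#' @return matrix of counts over ERCC features only.
#' @export
ercc_counts <- function(cm) cm$counts[, cm$features$is_ercc, drop = FALSE]

#' Construct a normalized expression matrix
#'
#' Holds length- and coverage-normalized expression over endogenous genes,
#' together with the size factors that produced it and transform flags.
#' Produced by [normalize_eq1()]; not usually called directly.
#'
#' @param values dense numeric matrix, nuclei x endogenous genes.
#' @param features feature table restricted to endogenous genes.
#' @param nuclei nucleus metadata table.
#' @param size_factors data.frame with `nucleus_id`, `sf`, `dilution_group`.
#' @param scale_constant the scale constant of the normalization (default 10000).
#' @param is_log whether values are natural-log(1 + x) transformed.
#' @param is_batch_corrected whether batch correction has been applied.
#' @return an object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, features, nuclei, size_factors,
                              scale_constant = 10000, is_log = FALSE,
                              is_batch_corrected = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(nuclei), ncol(values) == nrow(features))
  if (any(!is.finite(values))) stop("normalized values must be finite")
  if (any(features$is_ercc)) stop("NormalizedMatrix holds endogenous genes only")
  stopifnot(identical(size_factors$nucleus_id, nuclei$nucleus_id))
  if (any(size_factors$sf <= 0)) stop("size factors must be positive")
  rownames(values) <- nuclei$nucleus_id
  colnames(values) <- features$feature_id
  structure(list(values = values, features = features, nuclei = nuclei,
                 size_factors = size_factors, scale_constant = scale_constant,
                 is_log = is_log, is_batch_corrected = is_batch_corrected),
            class = "NormalizedMatrix")
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", nrow(x$values), "nuclei x", ncol(x$values), "genes;",
      "log =", x$is_log, "; batch-corrected =", x$is_batch_corrected, "\n")
  invisible(x)
}

#' Subset a NormalizedMatrix by nuclei and/or genes
#' @inheritParams [.CountMatrix
#' @return the subsetted `NormalizedMatrix`.
#' @export
`[.NormalizedMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$nuclei$nucleus_id)
  if (is.character(j)) j <- match(j, x$features$feature_id)
  if (anyNA(i) || anyNA(j)) stop("unknown nucleus or gene ids in subset")
  normalized_matrix(x$values[i, j, drop = FALSE],
                    x$features[j, , drop = FALSE],
                    x$nuclei[i, , drop = FALSE],
                    x$size_factors[i, , drop = FALSE],
                    scale_constant = x$scale_constant, is_log = x$is_log,
                    is_batch_corrected = x$is_batch_corrected)
}

# resolve gene names or feature ids against a feature table; warn about misses
.resolve_genes <- function(features, genes, what = "gene") {
  idx <- match(genes, features$gene_name)
  miss <- is.na(idx)
  idx[miss] <- match(genes[miss], features$feature_id)
  if (anyNA(idx)) {
    warning("dropping ", sum(is.na(idx)), " ", what, "(s) not in the matrix: ",
            paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  }
  idx[!is.na(idx)]
}
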