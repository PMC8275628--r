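#' Read a count matrix from disk
#'
#' Two on-disk layouts are supported. `"mtx_dir"` is a directory holding
#' `matrix.mtx` (Matrix Market coordinate format, features x nuclei, the usual
#' genomics convention), `features.tsv` and `nuclei.tsv`. `"tsv"` is a single
#' dense tab-separated table (features in rows, nuclei in columns, first
#' column = feature_id) with the same two sidecar tables next to it.
#' ERCC spike-ins are recognized by an explicit `is_ercc` column in
#' `features.tsv`, or failing that by the `"ERCC-"` feature-id prefix.
#'
#' @param path directory (for `mtx_dir`) or counts file (for `tsv`).
#' @param format `"mtx_dir"` or `"tsv"`.
#' @return a [count_matrix()] object.
#' @export
read_count_matrix <- function(path, format = c("mtx_dir", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("no such directory: ", path)
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    features <- utils::read.delim(file.path(path, "features.tsv"),
                                  stringsAsFactors = FALSE)
    nuclei <- utils::read.delim(file.path(path, "nuclei.tsv"),
                                stringsAsFactors = FALSE)
    counts <- Matrix::t(m)  # stored features x nuclei
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- tab[[1]]
    counts <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(counts) <- ids
    side <- dirname(path)
    features <- utils::read.delim(file.path(side, "features.tsv"),
                                  stringsAsFactors = FALSE)
    nuclei <- utils::read.delim(file.path(side, "nuclei.tsv"),
                                stringsAsFactors = FALSE)
    counts <- counts[match(nuclei$nucleus_id, rownames(counts)),
                     match(features$feature_id, colnames(counts)), drop = FALSE]
  }
  count_matrix(counts, features, nuclei)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]; `read_count_matrix(write_count_matrix(cm))`
#' round-trips counts and metadata exactly.
#'
#' @param cm a `CountMatrix`.
#' @param path output directory (`mtx_dir`) or counts file path (`tsv`).
#' @param format `"mtx_dir"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, format = c("mtx_dir", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::t(methods::as(methods::as(Matrix::Matrix(cm$counts, sparse = TRUE),
                                           "generalMatrix"), "CsparseMatrix"))
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    utils::write.table(cm$features, file.path(path, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cm$nuclei, file.path(path, "nuclei.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    dense <- t(as.matrix(cm$counts))
    tab <- data.frame(feature_id = rownames(dense), dense, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cm$features, file.path(dirname(path), "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cm$nuclei, file.path(dirname(path), "nuclei.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a normalized matrix with a provenance sidecar
#'
#' Emits `normalized.tsv` (genes x nuclei, dense) plus `normalized.json`
#' recording size factors, the scale constant and transform flags, so a
#' normalized matrix can be reloaded with full provenance.
#'
#' @param nm a `NormalizedMatrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_normalized_matrix <- function(nm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dense <- t(nm$values)
  tab <- data.frame(feature_id = rownames(dense), dense, check.names = FALSE)
  utils::write.table(tab, file.path(dir, "normalized.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scale_constant = nm$scale_constant, is_log = nm$is_log,
               is_batch_corrected = nm$is_batch_corrected,
               size_factors = nm$size_factors, nuclei = nm$nuclei,
               features = nm$features)
  jsonlite::write_json(meta, file.path(dir, "normalized.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a normalized matrix written by [write_normalized_matrix()]
#' @param dir directory holding `normalized.tsv` and `normalized.json`.
#' @return a `NormalizedMatrix`.
#' @export
read_normalized_matrix <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "normalized.tsv"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "normalized.json"),
                              simplifyVector = TRUE)
  values <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(values) <- tab[[1]]
  normalized_matrix(values, as.data.frame(meta$features),
                    as.data.frame(meta$nuclei),
                    as.data.frame(meta$size_factors),
                    scale_constant = meta$scale_constant, is_log = meta$is_log,
                    is_batch_corrected = meta$is_batch_corrected)
}
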