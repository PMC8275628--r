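# Binary co-expression analysis of stem/progenitor markers: binarization of
# the log-normalized matrix, pairwise Jaccard similarity between marker
# detection patterns, hierarchical module extraction, and per-nucleus
# co-expression counts.

#' Binarize a log-normalized matrix
#'
#' Entry 1 where the log-normalized value is strictly positive (the gene is
#' detected in the nucleus), 0 otherwise. Idempotent.
#'
#' @param nm a log-transformed `NormalizedMatrix`.
#' @return list of class `BinaryMatrix`: `values` (0/1 matrix), `features`,
#'   `nuclei`.
#' @export
binarize <- function(nm) {
  if (!nm$is_log) stop("binarize expects log-transformed values")
  b <- (nm$values > 0) * 1L
  structure(list(values = b, features = nm$features, nuclei = nm$nuclei),
            class = "BinaryMatrix")
}

#' Restrict a binary matrix to markers and drop empty nuclei
#'
#' Keeps only the requested marker genes and removes nuclei in which none of
#' them is detected (in the study this leaves 364 hepatocyte nuclei by 11
#' stem-cell markers).
#'
#' @param bm a `BinaryMatrix`.
#' @param markers character vector of marker gene names (resolved against
#'   gene names, then feature ids; missing markers are dropped with warning).
#' @return the restricted `BinaryMatrix` with no all-zero nucleus rows.
#' @export
subset_markers_drop_empty <- function(bm, markers) {
  idx <- .resolve_genes(bm$features, markers, "marker")
  if (length(idx) == 0L) stop("none of the markers is present in the matrix")
  vals <- bm$values[, idx, drop = FALSE]
  colnames(vals) <- bm$features$gene_name[idx]
  keep <- rowSums(vals) > 0
  structure(list(values = vals[keep, , drop = FALSE],
                 features = bm$features[idx, , drop = FALSE],
                 nuclei = bm$nuclei[keep, , drop = FALSE]),
            class = "BinaryMatrix")
}

#' Pairwise Jaccard similarity between markers
#'
#' For two markers with nucleus detection sets X and Y, the Jaccard index is
#' `J = |X n Y| / |X u Y|`; expression level is ignored, only presence
#' counts. The distance `1 - J` feeds average-linkage hierarchical
#' clustering, whose tree is used for module extraction. A marker detected in
#' no retained nucleus gets similarity 0 against every other marker (with a
#' warning); diagonal entries are 1.
#'
#' @param bm a `BinaryMatrix` (typically from [subset_markers_drop_empty()]).
#' @param linkage hierarchical linkage: `"average"` (default), `"single"` or
#'   `"complete"`.
#' @return list of class `JaccardResult`: `jaccard` (similarity matrix),
#'   `distance` (`1 - jaccard`), `tree` (an [stats::hclust()] object),
#'   `linkage`.
#' @export
pairwise_jaccard <- function(bm, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  b <- bm$values
  if (ncol(b) < 2L) stop("need at least 2 markers")
  inter <- crossprod(b)
  sizes <- diag(inter)
  union <- outer(sizes, sizes, "+") - inter
  J <- ifelse(union > 0, inter / union, 0)
  if (any(sizes == 0)) {
    warning("markers with no positive nucleus: ",
            paste(colnames(b)[sizes == 0], collapse = ", "))
  }
  diag(J) <- 1
  dimnames(J) <- list(colnames(b), colnames(b))
  D <- 1 - J
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  structure(list(jaccard = J, distance = D, tree = tree, linkage = linkage),
            class = "JaccardResult")
}

#' Extract co-expression modules from the Jaccard tree
#'
#' Cuts the hierarchical tree at a Jaccard-distance threshold and reports the
#' resulting flat clusters of size >= 2 as modules, largest first.
#'
#' @param jr a `JaccardResult`.
#' @param distance_threshold tree cut height (default 0.5).
#' @return list of character vectors (marker names per module); empty list if
#'   no module of size >= 2 exists.
#' @export
extract_modules <- function(jr, distance_threshold = 0.5) {
  cl <- stats::cutree(jr$tree, h = distance_threshold)
  groups <- split(names(cl), cl)
  groups <- Filter(function(g) length(g) >= 2L, groups)
  groups <- lapply(groups, function(g) sort(g))
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  unname(groups)
}

#' Per-ploidy marker co-expression counts
#'
#' For each ploidy class: the fraction of nuclei in which at least
#' `min_markers` of the markers are detected simultaneously, and each
#' marker's positive fraction. Empty ploidy groups report `NA`.
#'
#' @param bm a marker-restricted `BinaryMatrix`.
#' @param min_markers co-expression threshold (default 2; the study reports
#'   that more than two stem/progenitor markers are co-expressed in both 2n
#'   and 4n hepatocytes).
#' @param ploidy optional vector of ploidy labels per nucleus (defaults to
#'   the matrix's metadata).
#' @return list with `coexpression` (data.frame: ploidy, n_nuclei,
#'   frac_coexpressing) and `marker_fractions` (markers x ploidy matrix).
#' @export
coexpression_counts <- function(bm, min_markers = 2, ploidy = NULL) {
  if (is.null(ploidy)) ploidy <- bm$nuclei$ploidy
  stopifnot(length(ploidy) == nrow(bm$values))
  levels <- unique(ploidy[!is.na(ploidy)])
  rows <- lapply(levels, function(pl) {
    in_pl <- !is.na(ploidy) & ploidy == pl
    n <- sum(in_pl)
    frac <- if (n > 0) mean(rowSums(bm$values[in_pl, , drop = FALSE]) >= min_markers) else NA_real_
    data.frame(ploidy = pl, n_nuclei = n, frac_coexpressing = frac,
               stringsAsFactors = FALSE)
  })
  marker_frac <- vapply(levels, function(pl) {
    in_pl <- !is.na(ploidy) & ploidy == pl
    if (!any(in_pl)) return(rep(NA_real_, ncol(bm$values)))
    colMeans(bm$values[in_pl, , drop = FALSE])
  }, numeric(ncol(bm$values)))
  if (is.null(dim(marker_frac))) {
    marker_frac <- matrix(marker_frac, ncol = length(levels),
                          dimnames = list(colnames(bm$values), levels))
  } else {
    dimnames(marker_frac) <- list(colnames(bm$values), levels)
  }
  list(coexpression = do.call(rbind, rows), marker_fractions = marker_frac)
}

#' The packaged stem/progenitor marker panel
#'
#' The ten stem/progenitor cell-like markers analyzed in hepatocytes:
#' Icam1, Afp, Sox9, Epcam, Axin2, Tbx3, Itga6, Tert, Lgr5, Notch2. The panel
#' file is user-editable; pass your own vector to the co-expression functions
#' to change it.
#'
#' @param path optional YAML file with a `stem_markers` list.
#' @return character vector of marker gene names.
#' @export
stem_marker_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stem_panel.yaml", package = "hepnuc")
  }
  as.character(yaml::read_yaml(path)$stem_markers)
}
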