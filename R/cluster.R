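#' Cell-type marker panels
#'
#' Reads a YAML/JSON mapping of cell-type label to marker gene lists. The
#' packaged default panel covers the major liver cell types (hepatocytes,
#' hepatobiliary cells, endothelial cells, Kupffer/antigen-presenting cells,
#' lymphocytes, stellate cells), three illustrative markers each.
#'
#' @param path optional path to a YAML or JSON panel file; the packaged panel
#'   is used when `NULL`.
#' @return named list of character vectors (label -> gene names).
#' @export
read_marker_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "celltype_panels.yaml", package = "hepnuc")
  }
  panel <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  panel <- lapply(panel, as.character)
  if (is.null(names(panel)) || anyDuplicated(names(panel))) {
    stop("marker panel labels must be unique and named")
  }
  panel
}

# internal: truncated PCA scores (irlba for big matrices, base svd otherwise)
.pca_scores <- function(x, n_pcs) {
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  xc <- sweep(x, 2L, colMeans(x))
  if (min(dim(x)) > 120 && n_pcs < min(dim(x)) / 3) {
    fit <- irlba::irlba(xc, nv = n_pcs)
    scores <- fit$u %*% diag(fit$d, n_pcs, n_pcs)
  } else {
    sv <- svd(xc, nu = n_pcs, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  }
  rownames(scores) <- rownames(x)
  scores
}

# internal: symmetric unweighted kNN graph (Euclidean), as an igraph object
.knn_graph <- function(scores, k) {
  n <- nrow(scores)
  if (n <= k) stop("need more nuclei (", n, ") than neighbors k = ", k)
  d <- as.matrix(stats::dist(scores))
  idx <- apply(d, 1L, function(row) order(row)[2:(k + 1L)])
  edges <- cbind(rep(seq_len(n), each = k), as.integer(idx))
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  g
}

#' Embed and cluster nuclei
#'
#' PCA on the log-normalized matrix, a k-nearest-neighbor graph in PC space,
#' and modularity-based Louvain community detection. Deterministic for a fixed
#' seed. Low resolution (~0.1) reproduces the coarse hepatocyte/non-hepatocyte
#' split; resolution ~1 separates the individual cell types.
#'
#' @param nm a log-transformed `NormalizedMatrix`.
#' @param n_pcs number of principal components (default 50).
#' @param k_neighbors neighbors for the kNN graph (default 15).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed random seed (mandatory; community detection is stochastic).
#' @return data.frame of class `ClusterAssignment` with `nucleus_id`,
#'   `cluster_id` (integers starting at 1), `cell_type` (NA until
#'   [annotate_clusters()] is run) and the `resolution` used.
#' @export
embed_and_cluster <- function(nm, n_pcs = 50, k_neighbors = 15,
                              resolution = 1, seed) {
  if (!nm$is_log) stop("clustering expects log-transformed values")
  if (missing(seed)) stop("a seed is required")
  if (stats::sd(nm$values) == 0) {
    # no structure at all: a single cluster
    out <- data.frame(nucleus_id = nm$nuclei$nucleus_id, cluster_id = 1L,
                      cell_type = NA_character_, resolution = resolution,
                      stringsAsFactors = FALSE)
    class(out) <- c("ClusterAssignment", "data.frame")
    return(out)
  }
  scores <- .pca_scores(nm$values, n_pcs)
  if (max(abs(sweep(scores, 2L, scores[1L, ]))) < 1e-10) {
    # identical nuclei: no structure, one cluster
    out <- data.frame(nucleus_id = nm$nuclei$nucleus_id, cluster_id = 1L,
                      cell_type = NA_character_, resolution = resolution,
                      stringsAsFactors = FALSE)
    class(out) <- c("ClusterAssignment", "data.frame")
    return(out)
  }
  g <- .knn_graph(scores, k_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cl <- as.integer(igraph::membership(comm))
  out <- data.frame(nucleus_id = nm$nuclei$nucleus_id, cluster_id = cl,
                    cell_type = NA_character_, resolution = resolution,
                    stringsAsFactors = FALSE)
  class(out) <- c("ClusterAssignment", "data.frame")
  out
}

#' Label clusters from marker panels
#'
#' Each marker gene is z-scored across all nuclei; each cluster is labeled
#' with the cell type whose mean marker z-score in that cluster is maximal.
#' Panel genes absent from the matrix are dropped with a warning; exact score
#' ties leave the cluster `"unassigned"` with a warning.
#'
#' @param ca a `ClusterAssignment` from [embed_and_cluster()].
#' @param nm the log-transformed `NormalizedMatrix` the clustering was run on.
#' @param panel named list of marker gene vectors (see [read_marker_panel()]).
#' @return the `ClusterAssignment` with `cell_type` filled in.
#' @export
annotate_clusters <- function(ca, nm, panel) {
  if (length(panel) == 0L) stop("empty marker panel")
  stopifnot(identical(ca$nucleus_id, nm$nuclei$nucleus_id))
  scores <- vapply(panel, function(genes) {
    idx <- .resolve_genes(nm$features, genes, "marker gene")
    if (length(idx) == 0L) return(rep(NA_real_, nrow(nm$values)))
    sub <- nm$values[, idx, drop = FALSE]
    z <- scale(sub)
    z[, attr(z, "scaled:scale") == 0] <- 0
    rowMeans(z)
  }, numeric(nrow(nm$values)))
  if (all(is.na(scores))) stop("no panel gene found in the matrix")
  for (cl in unique(ca$cluster_id)) {
    in_cl <- ca$cluster_id == cl
    mean_scores <- colMeans(scores[in_cl, , drop = FALSE])
    best <- which(mean_scores == max(mean_scores, na.rm = TRUE))
    if (length(best) != 1L) {
      warning("tied marker scores in cluster ", cl, "; leaving unassigned")
      ca$cell_type[in_cl] <- "unassigned"
    } else {
      ca$cell_type[in_cl] <- names(panel)[best]
    }
  }
  ca
}

#' Restrict a normalized matrix to annotated hepatocytes
#'
#' @param nm a `NormalizedMatrix`.
#' @param ca an annotated `ClusterAssignment`.
#' @param label the cell-type label to keep (default `"hepatocyte"`).
#' @return the `NormalizedMatrix` restricted to nuclei with that label, with
#'   all nucleus metadata (ploidy, plate, ...) carried through.
#' @export
subset_hepatocytes <- function(nm, ca, label = "hepatocyte") {
  stopifnot(identical(ca$nucleus_id, nm$nuclei$nucleus_id))
  keep <- !is.na(ca$cell_type) & ca$cell_type == label
  if (!any(keep)) stop("no cluster was annotated as '", label, "'")
  nm[keep, ]
}
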