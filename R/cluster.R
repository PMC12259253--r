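#' Phenotype clustering model (PhenoGraph-style)
#'
#' Cells of one population are clustered on their multimarker phenotype:
#' arcsinh-transformed, per-marker z-scored intensities feed an exact
#' Euclidean k-nearest-neighbor graph whose edges are weighted by the
#' Jaccard overlap of neighbor sets (edges with no shared neighbors are
#' dropped), and communities are found by modularity (Louvain) at the
#' configured resolution.
#'
#' @param k_neighbors neighbors per cell for the kNN graph.
#' @param resolution Louvain resolution (1 = plain modularity).
#' @param arcsinh_cofactor cofactor of the `asinh(x / cofactor)` variance-
#'   stabilizing transform (5 is the mass-cytometry convention); `NULL`
#'   skips the transform.
#' @param zscore per-marker standardization after the transform.
#' @param seed RNG seed for the community search.
#' @return An object of class `cluster_model`.
#' @export
cluster_model <- function(k_neighbors = 30, resolution = 1,
                          arcsinh_cofactor = 5, zscore = TRUE, seed = 7) {
  stopifnot(is_count(k_neighbors), k_neighbors >= 1, resolution > 0)
  structure(list(k_neighbors = k_neighbors, resolution = resolution,
                 arcsinh_cofactor = arcsinh_cofactor, zscore = zscore,
                 seed = seed), class = "cluster_model")
}

# Exact kNN by Euclidean distance, chunked to bound memory.
# Returns an n x k matrix of neighbor indices (self excluded).
knn_indices <- function(X, k, chunk = 512L) {
  n <- nrow(X)
  if (k >= n) stopf("k_neighbors (%d) must be < number of cells (%d)", k, n)
  out <- matrix(0L, n, k)
  sq <- rowSums(X^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(X[s:e, , drop = FALSE], X)
    for (i in seq_len(e - s + 1L)) {
      d2[i, s + i - 1L] <- Inf
      out[s + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

transform_intensities <- function(X, model) {
  if (!is.null(model$arcsinh_cofactor)) X <- asinh(X / model$arcsinh_cofactor)
  if (isTRUE(model$zscore)) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0 | !is.finite(attr(X, "scaled:scale"))] <- 0
    X[!is.finite(X)] <- 0
  }
  unname(as.matrix(X))
}

#' Cluster cells of one population
#'
#' @param cells a [cell_table()] restricted to one population.
#' @param markers marker columns to cluster on (e.g. the population's
#'   functional panel); defaults to all markers.
#' @param model a [cluster_model()].
#' @return The cell table with `cluster` filled with contiguous ids
#'   (1, 2, ...); the shared-neighbor graph is attached as attribute
#'   `"graph"` (an igraph object).
#' @export
cluster_cells <- function(cells, markers = NULL, model = cluster_model()) {
  stopifnot(inherits(model, "cluster_model"))
  all_markers <- cell_table_markers(cells)
  if (is.null(markers)) markers <- all_markers
  miss <- setdiff(markers, all_markers)
  if (length(miss)) stopf("unknown clustering markers: %s", paste(miss, collapse = ", "))
  n <- nrow(cells)
  if (n < model$k_neighbors + 1L)
    stopf("need at least k_neighbors + 1 = %d cells, got %d", model$k_neighbors + 1L, n)
  X <- transform_intensities(as.matrix(as.data.frame(cells)[, markers, drop = FALSE]), model)
  nn <- knn_indices(X, model$k_neighbors)
  g <- shared_neighbor_graph(nn)
  set.seed(model$seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = model$resolution)
  memb <- igraph::membership(comm)
  df <- as.data.frame(cells)
  df$cluster <- as.integer(memb)
  out <- cell_table(df, all_markers)
  attr(out, "graph") <- g
  out
}

# Jaccard-weighted shared-nearest-neighbor graph from a kNN index matrix.
shared_neighbor_graph <- function(nn) {
  n <- nrow(nn); k <- ncol(nn)
  ei <- rep(seq_len(n), k); ej <- as.vector(nn)
  sw <- ei > ej
  tmp <- ei[sw]; ei[sw] <- ej[sw]; ej[sw] <- tmp
  keep <- !duplicated(cbind(ei, ej))
  ei <- ei[keep]; ej <- ej[keep]
  sets <- lapply(seq_len(n), function(i) nn[i, ])
  w <- vapply(seq_along(ei), function(t) {
    a <- sets[[ei[t]]]; b <- sets[[ej[t]]]
    inter <- length(intersect(a, b))
    inter / (2L * k - inter)
  }, numeric(1))
  pos <- w > 0
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(pos))
    g <- igraph::add_edges(g, rbind(ei[pos], ej[pos]), weight = w[pos])
  g
}

#' Per-cluster two-group statistics
#'
#' For each cluster: per-group cell counts and proportions (of that group's
#' cells in the clustered population), fold change FC =
#' proportion(group1) / proportion(group2), a two-sided Fisher exact test
#' on the 2x2 table (in-cluster vs not, by group), and Holm-adjusted
#' p-values across clusters.
#'
#' @param cells a clustered [cell_table()].
#' @param manifest a [cohort_manifest()] with two groups.
#' @param group1 fold-change numerator group (default: first manifest
#'   level; the convention is HIV-like group over control).
#' @return data.frame of subclass `cluster_stats`.
#' @export
cluster_group_stats <- function(cells, manifest, group1 = NULL) {
  if (anyNA(cells$cluster)) stopf("cells must carry cluster assignments")
  g <- cell_groups(cells, manifest)
  lv <- group_levels(manifest, group1)
  n1 <- sum(g == lv[1L]); n2 <- sum(g == lv[2L])
  if (n1 == 0L || n2 == 0L)
    stopf("group '%s' has no cells in this population", lv[c(n1, n2) == 0L][1L])
  clusters <- sort(unique(cells$cluster))
  k1 <- vapply(clusters, function(cl) sum(cells$cluster == cl & g == lv[1L]), numeric(1))
  k2 <- vapply(clusters, function(cl) sum(cells$cluster == cl & g == lv[2L]), numeric(1))
  p1 <- k1 / n1; p2 <- k2 / n2
  fisher_p <- vapply(seq_along(clusters), function(i)
    stats::fisher.test(matrix(c(k1[i], n1 - k1[i], k2[i], n2 - k2[i]), 2L),
                       alternative = "two.sided")$p.value, numeric(1))
  out <- data.frame(cluster = clusters,
                    count_1 = k1, count_2 = k2,
                    prop_1 = p1, prop_2 = p2,
                    fold_change = ifelse(p2 > 0, p1 / p2, ifelse(p1 > 0, Inf, NaN)),
                    p = fisher_p,
                    p_adj = stats::p.adjust(fisher_p, "holm"))
  names(out)[2:5] <- c(paste0("count_", lv), paste0("prop_", lv))
  attr(out, "groups") <- lv
  class(out) <- c("cluster_stats", "data.frame")
  out
}

#' Cluster-by-marker heatmap matrix scaled to [0, 1]
#'
#' Cluster mean intensities min-max scaled per marker across clusters
#' (1 = the cluster with the highest mean). Markers constant across
#' clusters map to 0.
#'
#' @param cells a clustered [cell_table()].
#' @param markers markers to include (default: all).
#' @return numeric matrix, clusters in rows, markers in columns.
#' @export
cluster_marker_heatmap <- function(cells, markers = NULL) {
  if (anyNA(cells$cluster)) stopf("cells must carry cluster assignments")
  all_markers <- cell_table_markers(cells)
  if (is.null(markers)) markers <- all_markers
  clusters <- sort(unique(cells$cluster))
  df <- as.data.frame(cells)
  M <- vapply(markers, function(m)
    vapply(clusters, function(cl) mean(df[[m]][df$cluster == cl]), numeric(1)),
    numeric(length(clusters)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(clusters))
  dimnames(M) <- list(clusters, markers)
  apply(M, 2L, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  }) |> matrix(nrow = length(clusters), dimnames = list(clusters, markers))
}
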