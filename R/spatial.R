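#' Minimum distances from one cell type to another
#'
#' For every source-type cell, the Euclidean distance (in micrometers) to
#' the nearest target-type cell of the same ROI; cells in different ROIs
#' (tissue cores) have no meaningful mutual distance, so ROIs are processed
#' independently and the per-cell minima pooled. When source and target
#' types coincide, the cell itself is excluded. ROIs lacking target cells
#' are skipped with a warning.
#'
#' @param cells a [cell_table()] with `population` labels.
#' @param source_type,target_type population labels.
#' @param pixel_size_um micrometers per pixel.
#' @return data.frame with `case_id`, `roi_id`, `cell_id`, `distance_um`.
#' @export
min_distance_distributions <- function(cells, source_type, target_type,
                                       pixel_size_um = 1) {
  pops <- unique(cells$population)
  for (t in unique(c(source_type, target_type)))
    if (!t %in% pops) stopf("unknown cell type '%s'", t)
  df <- as.data.frame(cells)
  out <- list()
  for (roi in split(df, paste(df$case_id, df$roi_id))) {
    src <- roi[roi$population == source_type, , drop = FALSE]
    tgt <- roi[roi$population == target_type, , drop = FALSE]
    if (!nrow(src)) next
    same <- identical(source_type, target_type)
    if (nrow(tgt) < 1L + same) {
      warnf("ROI %s/%s skipped: no valid %s target", roi$case_id[1L],
            roi$roi_id[1L], target_type)
      next
    }
    d2 <- dist2_cross(cbind(src$x_px, src$y_px), cbind(tgt$x_px, tgt$y_px))
    if (same) d2[cbind(seq_len(nrow(src)), seq_len(nrow(tgt)))] <- Inf
    out[[length(out) + 1L]] <- data.frame(
      case_id = src$case_id, roi_id = src$roi_id, cell_id = src$cell_id,
      distance_um = sqrt(apply(d2, 1L, min)) * pixel_size_um)
  }
  if (!length(out))
    return(data.frame(case_id = character(0), roi_id = character(0),
                      cell_id = character(0), distance_um = numeric(0)))
  do.call(rbind, out)
}

#' Compare two groups' minimum-distance samples
#'
#' Two-sided Wilcoxon rank-sum test with tie correction. `Z` is the
#' standardized Mann-Whitney statistic of group 1 (positive when group-1
#' distances are stochastically larger), and the effect size is
#' `r = Z / sqrt(N)` with `N = n1 + n2` the total number of distance
#' measurements. The p-value is exact (rank-sum enumeration) for small
#' untied samples, otherwise the normal approximation of `Z`.
#'
#' @param distances_group1,distances_group2 numeric distance samples (um).
#' @return An object of class `distance_comparison`: list with `U`, `Z`,
#'   `p`, `N`, `n1`, `n2`, `r` and the two samples.
#' @export
compare_distances <- function(distances_group1, distances_group2) {
  d1 <- as.numeric(distances_group1); d2 <- as.numeric(distances_group2)
  if (!length(d1) || !length(d2)) stopf("both groups need at least one distance")
  if (any(c(d1, d2) < 0)) stopf("distances must be >= 0")
  n1 <- length(d1); n2 <- length(d2); n <- n1 + n2
  rk <- rank(c(d1, d2))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  Z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  p <- if (!has_ties && n < 50)
    suppressWarnings(stats::wilcox.test(d1, d2, exact = TRUE)$p.value)
  else
    min(1, 2 * stats::pnorm(-abs(Z)))
  structure(list(U = U, Z = Z, p = p, N = n, n1 = n1, n2 = n2,
                 r = Z / sqrt(n), group1 = d1, group2 = d2),
            class = "distance_comparison")
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat(sprintf("<distance_comparison> n = %d + %d, U = %.1f, Z = %.3f, r = %.3f, p = %.3g\n",
              x$n1, x$n2, x$U, x$Z, x$r, x$p))
  invisible(x)
}

#' Spatial neighbor graph of one ROI
#'
#' Nodes are cells; edges come either from symmetrized k-nearest-neighbors
#' (an edge i-j exists when j is among i's k nearest or vice versa) or from
#' a fixed physical radius. No self-edges.
#'
#' @param cells a [cell_table()] restricted to one ROI (>= 2 cells).
#' @param method `"knn"` or `"radius"`.
#' @param k neighbors for `"knn"` (must be < number of cells; 6 is the
#'   default neighborhood size).
#' @param d_um radius in micrometers for `"radius"`.
#' @param pixel_size_um micrometers per pixel.
#' @return An object of class `spatial_graph`: list with `edges`
#'   (data.frame `i`, `j`, `dist_um`, each undirected pair once, i < j)
#'   and `n`.
#' @export
build_spatial_graph <- function(cells, method = c("knn", "radius"), k = 6,
                                d_um = NULL, pixel_size_um = 1) {
  method <- match.arg(method)
  n <- nrow(cells)
  if (n < 2L) stopf("need at least 2 cells")
  xy <- cbind(cells$x_px, cells$y_px) * pixel_size_um
  d2 <- dist2_cross(xy, xy)
  diag(d2) <- Inf
  if (method == "knn") {
    if (k >= n) stopf("k (%d) must be < number of cells (%d)", k, n)
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d2[i, ])[seq_len(k)]
      cbind(pmin(i, nb), pmax(i, nb))
    }))
  } else {
    if (is.null(d_um) || d_um <= 0) stopf("radius method needs d_um > 0")
    hit <- which(d2 <= d_um^2, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    pairs <- hit
  }
  pairs <- unique(pairs)
  edges <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                      dist_um = sqrt(d2[pairs]))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, method = method),
            class = "spatial_graph")
}

# Symmetric cell-type pair edge-count matrix for one labeling.
pair_counts <- function(edges_i, edges_j, labels, types) {
  k <- length(types)
  m <- matrix(0, k, k, dimnames = list(types, types))
  if (length(edges_i)) {
    a <- match(labels[edges_i], types)
    b <- match(labels[edges_j], types)
    lo <- pmin(a, b); hi <- pmax(a, b)
    tb <- table(factor(lo + (hi - 1L) * k, levels = seq_len(k * k)))
    m[] <- as.vector(tb)                      # counts land in the upper triangle
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  m
}

#' Neighborhood enrichment z-scores
#'
#' For every pair of cell types, the observed number of graph edges joining
#' them is compared with a null built by permuting the labels over nodes
#' with the graph fixed: `z = (observed - null mean) / null SD` (z = 0
#' where the null SD is zero). Positive z means the two types are neighbors
#' more often than expected by chance. `exhaustive = TRUE` enumerates all
#' distinct labelings instead of sampling (only feasible for small label
#' multisets; used as an oracle).
#'
#' @param graph a [build_spatial_graph()] result.
#' @param labels character vector of cell types, one per node.
#' @param n_permutations Monte Carlo permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all distinct labelings (<= `limit`).
#' @param limit cap on the exhaustive enumeration size.
#' @return An object of class `neighborhood_enrichment`: symmetric matrices
#'   `z`, `observed`, `null_mean`, `null_sd`, plus the null parameters.
#' @export
neighborhood_enrichment <- function(graph, labels, n_permutations = 1000,
                                    seed = 1, exhaustive = FALSE, limit = 1e6) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (length(labels) != graph$n)
    stopf("labels (%d) must match graph nodes (%d)", length(labels), graph$n)
  types <- sort(unique(labels))
  ei <- graph$edges$i; ej <- graph$edges$j
  obs <- pair_counts(ei, ej, labels, types)
  if (length(types) < 2L) {
    warnf("single label class: all enrichment z-scores are zero")
    z <- obs * 0
    return(structure(list(z = z, observed = obs, null_mean = obs,
                          null_sd = z, n_permutations = 0L, seed = seed,
                          exhaustive = FALSE),
                     class = "neighborhood_enrichment"))
  }
  if (exhaustive) {
    perms <- distinct_permutations(labels, limit)
    draws <- lapply(perms, function(lb) pair_counts(ei, ej, lb, types))
  } else {
    set.seed(seed)
    draws <- lapply(seq_len(n_permutations), function(...)
      pair_counts(ei, ej, sample(labels), types))
  }
  arr <- simplify2array(draws)
  mu <- apply(arr, c(1L, 2L), mean)
  sd0 <- sqrt(apply(arr, c(1L, 2L), function(v) mean((v - mean(v))^2)))
  z <- ifelse(sd0 > 0, (obs - mu) / sd0, 0)
  structure(list(z = z, observed = obs, null_mean = mu, null_sd = sd0,
                 n_permutations = length(draws), seed = seed,
                 exhaustive = exhaustive),
            class = "neighborhood_enrichment")
}

#' @export
print.neighborhood_enrichment <- function(x, ...) {
  cat(sprintf("<neighborhood_enrichment> %d types, %d null draws%s\n",
              nrow(x$z), x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  print(round(x$z, 3))
  invisible(x)
}
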