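#' PageRank parameters
#'
#' @param alpha damping factor in (0, 1); 0.85 is the classical PageRank
#'   default.
#' @param tol power-iteration convergence tolerance (max absolute change).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return An object of class `pagerank_params`.
#' @export
pagerank_params <- function(alpha = 0.85, tol = 1e-12, max_iter = 1000) {
  stopifnot(alpha > 0 || alpha == 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter),
            class = "pagerank_params")
}

#' Gaussian-kernel graph over one case's patches
#'
#' Nodes are the case's patches. Patch expression vectors are standardized
#' per marker (across the case's patches) and edge weights are
#' `w_ij = exp(-||e_i - e_j||^2 / eps)` with `eps` the median squared
#' pairwise distance (the self-tuning bandwidth); if all patches are
#' identical `eps` falls back to 1, giving a complete graph with equal
#' weights. No self-loops.
#'
#' @param patches a [select_patches()] result (>= 2 patches).
#' @return An object of class `patch_graph`: list with the symmetric
#'   positive weight matrix `W` (zero diagonal), `eps`, and the patch
#'   `info`.
#' @export
case_patch_graph <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  E <- patches$expr
  if (nrow(E) < 2L) stopf("a patch graph needs at least 2 patches")
  Z <- scale(E)
  Z[, !is.finite(attr(Z, "scaled:scale")) | attr(Z, "scaled:scale") == 0] <- 0
  Z[!is.finite(Z)] <- 0
  D2 <- dist2_cross(Z, Z)
  eps <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(eps) || eps <= 0) eps <- 1
  W <- exp(-D2 / eps)
  diag(W) <- 0
  structure(list(W = W, eps = eps, info = patches$info), class = "patch_graph")
}

#' Personalized-PageRank steady-state distribution
#'
#' Solves `s = alpha * t(P) s + (1 - alpha) * t` by power iteration, where
#' `P` is the row-normalized random-walk matrix of the weighted graph and
#' `t` the teleport (restart) distribution, normalized to sum 1. The
#' steady-state distribution (SSD) is a probability vector over patches:
#' entries >= 0 summing to 1.
#'
#' @param graph a [case_patch_graph()] result, or a symmetric non-negative
#'   weight matrix.
#' @param teleport non-negative teleport vector over patches with at least
#'   one positive entry.
#' @param params a [pagerank_params()].
#' @return numeric SSD vector over patches.
#' @export
personalized_pagerank_ssd <- function(graph, teleport, params = pagerank_params()) {
  W <- if (inherits(graph, "patch_graph")) graph$W else as.matrix(graph)
  stopifnot(inherits(params, "pagerank_params"))
  n <- nrow(W)
  if (length(teleport) != n)
    stopf("teleport length (%d) must match patch count (%d)", length(teleport), n)
  if (any(teleport < 0) || all(teleport == 0))
    stopf("teleport must be non-negative with at least one positive entry")
  t0 <- teleport / sum(teleport)
  rs <- rowSums(W)
  if (any(rs == 0)) stopf("graph has an isolated node (zero row sum)")
  PT <- t(W / rs)                      # column-stochastic walk matrix
  s <- t0
  for (it in seq_len(params$max_iter)) {
    s_new <- params$alpha * as.vector(PT %*% s) + (1 - params$alpha) * t0
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < params$tol) return(s / sum(s))
  }
  stopf("PageRank power iteration did not converge in %d iterations (residual %.3g)",
        params$max_iter, delta)
}
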