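#' Diffusion-map embedding of representation columns
#'
#' Columns of `X` (e.g. the patches of a representation matrix) are
#' embedded with a diffusion map: a Gaussian kernel
#' `K_ij = exp(-||x_i - x_j||^2 / eps)` (`eps` = median squared pairwise
#' distance by default), row-normalized to a Markov matrix `P = D^-1 K`,
#' whose top non-trivial right eigenvectors — scaled by their eigenvalues —
#' give the diffusion coordinates. The eigenproblem is solved through the
#' symmetric conjugate `D^-1/2 K D^-1/2`; the leading eigenvalue is 1 with
#' a constant eigenvector, which is excluded from the embedding.
#'
#' @param X numeric matrix, one column per point.
#' @param d number of diffusion coordinates (needs `>= d + 1` columns).
#' @param eps kernel bandwidth; `NULL` = median squared pairwise distance.
#' @return An object of class `diffusion_map`: `coords` (`n x d`),
#'   `eigenvalues` (length `d + 1`, leading 1 first), and the training
#'   state needed for the Nystrom extension.
#' @export
diffusion_embed <- function(X, d = 3, eps = NULL) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < d + 1L) stopf("need at least d + 1 = %d columns, got %d", d + 1L, n)
  P <- t(X)
  D2 <- dist2_cross(P, P)
  if (is.null(eps)) {
    eps <- stats::median(D2[upper.tri(D2)])
    if (!is.finite(eps) || eps <= 0) eps <- 1
  }
  K <- exp(-D2 / eps)
  deg <- rowSums(K)
  A <- K / sqrt(deg %o% deg)
  ei <- eigen(A, symmetric = TRUE)
  if (ei$values[d + 1L] <= sqrt(.Machine$double.eps))
    stopf("requested %d components but the spectrum has fewer non-trivial directions", d)
  psi <- ei$vectors / sqrt(deg)        # right eigenvectors of the Markov matrix
  # deterministic sign: largest-magnitude entry positive
  for (k in seq_len(d + 1L)) {
    i <- which.max(abs(psi[, k]))
    if (psi[i, k] < 0) psi[, k] <- -psi[, k]
  }
  lam <- ei$values[seq_len(d + 1L)]
  coords <- sweep(psi[, 2:(d + 1L), drop = FALSE], 2L, lam[-1L], `*`)
  structure(list(coords = coords, eigenvalues = lam,
                 psi = psi[, seq_len(d + 1L), drop = FALSE],
                 X = X, eps = eps, d = d), class = "diffusion_map")
}

#' Nystrom out-of-sample extension
#'
#' Embeds new columns into a fitted diffusion map without refitting: the
#' kernel of each new point to the training points is normalized to a
#' transition row and projected onto the training eigenbasis. Extending a
#' training column reproduces its fitted coordinates.
#'
#' @param object a [diffusion_embed()] fit.
#' @param newX matrix of new columns (same row dimension as the training
#'   data).
#' @param ... unused.
#' @return `ncol(newX) x d` coordinate matrix.
#' @export
predict.diffusion_map <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  if (nrow(newX) != nrow(object$X))
    stopf("new columns have %d rows; training had %d", nrow(newX), nrow(object$X))
  k <- exp(-dist2_cross(t(newX), t(object$X)) / object$eps)
  p <- k / rowSums(k)
  p %*% object$psi[, -1L, drop = FALSE]
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat(sprintf("<diffusion_map> %d points, d = %d, eps = %.3g, spectrum: %s\n",
              ncol(x$X), x$d, x$eps,
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}
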