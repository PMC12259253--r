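# Internal helpers shared across the pipeline.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# Squared Euclidean cross-distances between rows of a and rows of b.
dist2_cross <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Mean over a centered side x side window via integral image.
# Entries whose window is not fully inside the image are NA.
box_mean_filter <- function(mat, side) {
  stopifnot(side >= 1, side %% 2 == 1)
  h <- nrow(mat); w <- ncol(mat)
  if (side > h || side > w) stopf("box filter side %d exceeds image size %dx%d", side, h, w)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(apply(mat, 2L, cumsum), 1L, cumsum) |> t()
  r <- side %/% 2L
  ri <- (r + 1L):(h - r); ci <- (r + 1L):(w - r)
  out <- matrix(NA_real_, h, w)
  out[ri, ci] <- (S[ri + r + 1L, ci + r + 1L, drop = FALSE] -
                  S[ri - r,      ci + r + 1L, drop = FALSE] -
                  S[ri + r + 1L, ci - r,      drop = FALSE] +
                  S[ri - r,      ci - r,      drop = FALSE]) / (side * side)
  out
}

# Integer offsets (di, dj) with di^2 + dj^2 <= r^2 (a Euclidean disk).
disk_offsets <- function(radius) {
  r <- as.integer(floor(radius))
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
  g[order(g$di^2 + g$dj^2, g$di, g$dj), , drop = FALSE]
}

# All distinct permutations of a label multiset (exhaustive null for small n).
distinct_permutations <- function(labels, limit = 1e6) {
  n_distinct <- count_distinct_permutations(labels)
  if (n_distinct > limit)
    stopf("%s distinct labelings exceed the exhaustive limit (%g)",
          format(n_distinct, big.mark = ","), limit)
  lv <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = lv)))
  res <- vector("list", n_distinct)
  k <- 0L
  cur <- character(length(labels))
  rec <- function(pos, counts) {
    if (pos > length(labels)) {
      k <<- k + 1L
      res[[k]] <<- cur
      return(invisible())
    }
    for (i in seq_along(lv)) {
      if (counts[i] > 0L) {
        cur[pos] <<- lv[i]
        counts[i] <- counts[i] - 1L
        rec(pos + 1L, counts)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  rec(1L, counts)
  res
}

count_distinct_permutations <- function(labels) {
  counts <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1))) |> round()
}
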