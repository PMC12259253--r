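# Shared fixture builders; everything is generated in code.

make_test_panel <- function(markers = c("A", "B", "C"), pixel_size_um = 1,
                            thresholds = numeric()) {
  panel_config(data.frame(name = markers, channel = seq_along(markers),
                          role = "functional"),
               gate_thresholds = thresholds, pixel_size_um = pixel_size_um)
}

make_cells <- function(n, markers, seed = 1, case_id = "case1", roi_id = "r1") {
  set.seed(seed)
  M <- matrix(stats::rlnorm(n * length(markers)), nrow = n,
              ncol = length(markers), dimnames = list(NULL, markers))
  cell_table(data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                        case_id = rep(case_id, n), roi_id = rep(roi_id, n),
                        x_px = stats::runif(n, 0, 100),
                        y_px = stats::runif(n, 0, 100),
                        area_px = sample(1:40, n, replace = TRUE),
                        M, check.names = FALSE), markers)
}

# Greedy 1:1 matching of two point sets by increasing distance; returns the
# matched index pairs with distances <= max_dist.
greedy_match <- function(a, b, max_dist = Inf) {
  if (!nrow(a) || !nrow(b)) return(data.frame(i = integer(0), j = integer(0)))
  d <- sqrt(outer(a[, 1]^2 + a[, 2]^2, b[, 1]^2 + b[, 2]^2, "+") -
              2 * tcrossprod(as.matrix(a), as.matrix(b)))
  out <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist || !is.finite(d[m])) break
    ij <- arrayInd(m, dim(d))
    out[[length(out) + 1L]] <- data.frame(i = ij[1], j = ij[2], dist = d[m])
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
  }
  do.call(rbind, c(out, list(data.frame(i = integer(0), j = integer(0),
                                        dist = numeric(0)))))
}

# Two-sided Fisher p by hypergeometric enumeration (oracle).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# All distinct permutations of a small label vector (oracle enumerator,
# independent of the package's internal generator).
enum_perms <- function(labels) {
  if (length(labels) <= 1L) return(list(labels))
  out <- list()
  for (v in unique(labels)) {
    rest <- labels[-match(v, labels)]
    for (p in enum_perms(rest)) out[[length(out) + 1L]] <- c(v, p)
  }
  unique(out)
}
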