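#' Markers-by-patches representation matrix of PageRank SSD features
#'
#' For each case, one Gaussian-kernel graph over its patches; for each
#' marker `m`, a personalized-PageRank steady-state distribution with
#' teleport proportional to marker `m`'s per-patch mean expression. Entry
#' `R[m, p]` is marker `m`'s SSD mass on patch `p`, so within every case
#' each marker's row restricted to that case's patches sums to 1. Markers
#' with zero expression on every patch of a case fall back to a uniform
#' teleport (noted with a warning).
#'
#' @param patch_sets list of [select_patches()] results (one or more per
#'   case; patches of the same case are pooled into one graph).
#' @param manifest a [cohort_manifest()] supplying the group of each case.
#' @param params a [pagerank_params()].
#' @return An object of class `representation_matrix`: list with `R`
#'   (`M x P` matrix, markers in rows), `meta` (per-column `case_id`,
#'   `group`, `patch`), and `markers`.
#' @export
build_representation_matrix <- function(patch_sets, manifest,
                                        params = pagerank_params()) {
  if (inherits(patch_sets, "patch_set")) patch_sets <- list(patch_sets)
  markers <- colnames(patch_sets[[1L]]$expr)
  case_of <- vapply(patch_sets, function(p) p$info$case_id[1L], character(1))
  cases <- unique(case_of)
  cols <- list(); meta <- list()
  for (cs in cases) {
    ps <- patch_sets[case_of == cs]
    expr <- do.call(rbind, lapply(ps, `[[`, "expr"))
    info <- do.call(rbind, lapply(ps, `[[`, "info"))
    if (nrow(expr) < 2L) stopf("case '%s' has fewer than 2 patches", cs)
    g <- case_patch_graph(structure(list(expr = expr, info = info),
                                    class = "patch_set"))
    S <- matrix(0, length(markers), nrow(expr),
                dimnames = list(markers, NULL))
    for (m in markers) {
      tp <- pmax(expr[, m], 0)
      if (all(tp == 0)) {
        warnf("marker '%s' has zero expression on all patches of case '%s'; uniform teleport",
              m, cs)
        tp <- rep(1, nrow(expr))
      }
      S[m, ] <- personalized_pagerank_ssd(g, tp, params)
    }
    cols[[cs]] <- S
    meta[[cs]] <- data.frame(case_id = cs,
                             group = manifest$group[match(cs, manifest$case_id)],
                             patch = seq_len(nrow(expr)))
  }
  meta <- do.call(rbind, meta)
  if (anyNA(meta$group)) stopf("cases missing from the manifest: %s",
                               paste(unique(meta$case_id[is.na(meta$group)]), collapse = ", "))
  rownames(meta) <- NULL
  structure(list(R = do.call(cbind, cols), meta = meta, markers = markers),
            class = "representation_matrix")
}

#' @export
print.representation_matrix <- function(x, ...) {
  cat(sprintf("<representation_matrix> %d markers x %d patches (%d cases)\n",
              nrow(x$R), ncol(x$R), length(unique(x$meta$case_id))))
  invisible(x)
}

#' Rank markers by the L1 distance between group-level SSDs
#'
#' Patch identities are not comparable across cases, so each marker's SSD
#' is sorted in decreasing order within every case (aligning patches by
#' rank), the sorted vectors are averaged within each group, and the
#' marker's score is the L1 distance between the two group averages.
#' Markers are ranked by decreasing distance; the top-ranked markers are
#' the ones whose spatial expression concentration differs most between
#' groups. Cases with unequal patch counts are aligned on the common
#' minimum count with a warning.
#'
#' @param rep a [build_representation_matrix()] result.
#' @param group1 group taken first in the (order-independent) distance;
#'   defaults to the first group present.
#' @return data.frame of subclass `marker_ranking` with columns `marker`,
#'   `l1_distance`, `rank`.
#' @export
rank_markers <- function(rep, group1 = NULL) {
  stopifnot(inherits(rep, "representation_matrix"))
  groups <- unique(rep$meta$group)
  if (length(groups) != 2L) stopf("marker ranking needs exactly two groups")
  if (!is.null(group1)) groups <- c(group1, setdiff(groups, group1))
  per_case <- table(rep$meta$case_id)
  n_align <- min(per_case)
  if (length(unique(per_case)) > 1L)
    warnf("cases have unequal patch counts; aligning on the smallest (%d)", n_align)
  sorted_of_case <- function(cs) {
    cols <- which(rep$meta$case_id == cs)
    t(apply(rep$R[, cols, drop = FALSE], 1L, function(v)
      sort(v, decreasing = TRUE)[seq_len(n_align)]))
  }
  group_mean <- function(g) {
    cs <- unique(rep$meta$case_id[rep$meta$group == g])
    Reduce(`+`, lapply(cs, sorted_of_case)) / length(cs)
  }
  d <- rowSums(abs(group_mean(groups[1L]) - group_mean(groups[2L])))
  ord <- order(-d, rep$markers)
  out <- data.frame(marker = rep$markers[ord], l1_distance = d[ord],
                    rank = seq_along(d))
  class(out) <- c("marker_ranking", "data.frame")
  out
}
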