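#' Single-marker two-group comparison with patient random effects
#'
#' For every requested marker, two complementary tests of a group
#' difference in per-cell mean intensity:
#'
#' * a pooled rank-based two-group test (Wilcoxon rank-sum) over all cells,
#'   matching the marginal comparisons of per-marker expression panels;
#' * a linear mixed-effects model `intensity ~ group + (1 | case)` with a
#'   random intercept per case to absorb between-individual variability
#'   (fit with lmerTest; Satterthwaite p for the group effect). Singular
#'   fits (case variance estimated at zero) are flagged, not dropped.
#'
#' Both p-value sets are Holm-adjusted across the marker panel.
#'
#' @param cells a [cell_table()] (typically one gated population).
#' @param markers markers to compare (default: all marker columns).
#' @param manifest a [cohort_manifest()] with two groups and >= 2 cases per
#'   group.
#' @param group1 group whose mean is reported first and whose effect sign
#'   is positive when elevated (default: first manifest level).
#' @return data.frame of subclass `marker_comparison` with columns
#'   `marker`, `mean_<group1>`, `mean_<group2>`, `rank_stat`, `rank_p`,
#'   `rank_p_adj`, `mm_estimate` (group1 - group2), `mm_se`, `mm_p`,
#'   `mm_p_adj`, `singular`.
#' @export
marker_group_comparison <- function(cells, markers = NULL, manifest, group1 = NULL) {
  all_markers <- cell_table_markers(cells)
  if (is.null(markers)) markers <- all_markers
  miss <- setdiff(markers, all_markers)
  if (length(miss)) stopf("unknown markers: %s", paste(miss, collapse = ", "))
  g <- cell_groups(cells, manifest)
  lv <- group_levels(manifest, group1)
  for (l in lv)
    if (length(unique(cells$case_id[g == l])) < 2L)
      stopf("group '%s' needs at least 2 cases", l)
  df <- as.data.frame(cells)
  # reference level = group2 so the fixed effect is the group1 shift
  gf <- factor(g, levels = c(lv[2L], lv[1L]))
  res <- lapply(markers, function(m) {
    v <- df[[m]]
    wt <- suppressWarnings(stats::wilcox.test(v[gf == lv[1L]], v[gf == lv[2L]],
                                              correct = FALSE))
    fit <- suppressMessages(lmerTest::lmer(y ~ g + (1 | case),
      data = data.frame(y = v, g = gf, case = df$case_id),
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    co <- stats::coef(summary(fit))
    data.frame(marker = m,
               mean_1 = mean(v[gf == lv[1L]]), mean_2 = mean(v[gf == lv[2L]]),
               rank_stat = unname(wt$statistic), rank_p = wt$p.value,
               mm_estimate = co[2L, "Estimate"], mm_se = co[2L, "Std. Error"],
               mm_p = co[2L, "Pr(>|t|)"],
               singular = lme4::isSingular(fit))
  })
  out <- do.call(rbind, res)
  out$rank_p_adj <- stats::p.adjust(out$rank_p, "holm")
  out$mm_p_adj <- stats::p.adjust(out$mm_p, "holm")
  names(out)[2:3] <- paste0("mean_", lv)
  out <- out[, c("marker", paste0("mean_", lv), "rank_stat", "rank_p",
                 "rank_p_adj", "mm_estimate", "mm_se", "mm_p", "mm_p_adj",
                 "singular")]
  attr(out, "groups") <- lv
  class(out) <- c("marker_comparison", "data.frame")
  out
}
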