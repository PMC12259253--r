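#' Rule-based gating scheme
#'
#' Ordered positivity/negativity rules, evaluated first-match-wins: each
#' rule names a population and lists the markers that must be above
#' (`positive`) or at/below (`negative`) their panel gate thresholds. Cells
#' matching no rule are labeled `"unassigned"`, so gating always partitions
#' the table.
#'
#' @param rules list of `list(population=, positive=, negative=)` entries.
#' @return An object of class `gating_scheme`.
#' @export
gating_scheme <- function(rules) {
  for (r in rules)
    if (is.null(r$population) || (is.null(r$positive) && is.null(r$negative)))
      stopf("each gating rule needs a population and at least one marker requirement")
  structure(list(rules = rules), class = "gating_scheme")
}

#' @export
print.gating_scheme <- function(x, ...) {
  for (r in x$rules)
    cat(sprintf("%-10s %s\n", r$population, paste(
      c(paste0(r$positive, "+"), paste0(r$negative, "-")), collapse = " ")))
  invisible(x)
}

#' Default lineage gating scheme
#'
#' The four-population scheme of the emulated study (CD4 T: CK-CD68-CD20-
#' CD3+CD4+CD8-; CD8 T: CK-CD68-CD20-CD3+CD4-CD8+; TAM: CK-CD68+CD20-CD3-;
#' tumor: CK+CD68-CD20-CD3-) plus a CD20+ B-cell rule.
#'
#' @return A [gating_scheme()].
#' @export
default_gating_scheme <- function() {
  gating_scheme(list(
    list(population = "CD4T", positive = c("CD3", "CD4"),
         negative = c("CK", "CD68", "CD20", "CD8")),
    list(population = "CD8T", positive = c("CD3", "CD8"),
         negative = c("CK", "CD68", "CD20", "CD4")),
    list(population = "TAM", positive = "CD68",
         negative = c("CK", "CD20", "CD3")),
    list(population = "tumor", positive = "CK",
         negative = c("CD68", "CD20", "CD3")),
    list(population = "B", positive = "CD20",
         negative = c("CK", "CD68", "CD3"))))
}

#' Gate cells into lineage populations
#'
#' @param cells a [cell_table()].
#' @param scheme a [gating_scheme()]; default [default_gating_scheme()].
#' @param thresholds named positivity thresholds; defaults to the panel
#'   thresholds stored in `panel`.
#' @param panel a [panel_config()] supplying thresholds when `thresholds`
#'   is not given.
#' @return The cell table with `population` filled in; the per-label counts
#'   are attached as attribute `"gate_counts"`.
#' @export
gate_populations <- function(cells, scheme = default_gating_scheme(),
                             thresholds = NULL, panel = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"))
  markers <- cell_table_markers(cells)
  if (is.null(thresholds)) {
    if (is.null(panel)) panel <- default_panel()
    thresholds <- panel$gate_thresholds
  }
  used <- unique(unlist(lapply(scheme$rules, function(r) c(r$positive, r$negative))))
  miss <- setdiff(used, markers)
  if (length(miss)) stopf("gating rules reference unknown markers: %s",
                          paste(miss, collapse = ", "))
  nothr <- setdiff(used, names(thresholds))
  if (length(nothr)) stopf("no gate threshold for markers: %s",
                           paste(nothr, collapse = ", "))
  pop <- rep("unassigned", nrow(cells))
  open <- rep(TRUE, nrow(cells))
  df <- as.data.frame(cells)
  for (r in scheme$rules) {
    ok <- open
    for (m in r$positive) ok <- ok & df[[m]] > thresholds[[m]]
    for (m in r$negative) ok <- ok & df[[m]] <= thresholds[[m]]
    pop[ok] <- r$population
    open <- open & !ok
  }
  df$population <- pop
  out <- cell_table(df, markers)
  attr(out, "gate_counts") <- table(pop)
  out
}
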