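#' Per-cell measurement table
#'
#' The hub data structure joining segmentation, phenotyping and spatial
#' stages: one row per cell with identifiers, 0-based pixel centroid, area,
#' one mean-intensity column per marker (named by the marker), and optional
#' `population` / `cluster` assignments.
#'
#' Canonical column order is `cell_id, case_id, roi_id, x_px, y_px, area_px,
#' population, cluster, <markers...>`.
#'
#' @param df data.frame holding at least the identifier/geometry columns and
#'   the marker columns.
#' @param markers character vector of marker column names, in panel order.
#' @return A validated `data.frame` of subclass `cell_table` with attribute
#'   `markers`.
#' @export
cell_table <- function(df, markers) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("cell_id", "case_id", "roi_id", "x_px", "y_px", "area_px")
  miss <- setdiff(c(req, markers), names(df))
  if (length(miss)) stopf("cell table is missing columns: %s", paste(miss, collapse = ", "))
  if (any(markers %in% c(req, "population", "cluster")))
    stopf("marker names clash with reserved cell-table columns")
  if (!"population" %in% names(df)) df$population <- rep(NA_character_, nrow(df))
  if (!"cluster" %in% names(df)) df$cluster <- rep(NA_integer_, nrow(df))
  extras <- setdiff(names(df), c(req, "population", "cluster", markers))
  df <- df[, c(req, "population", "cluster", markers, extras)]
  validate_cell_table(df, markers)
  structure(df, markers = markers, class = c("cell_table", "data.frame"))
}

validate_cell_table <- function(df, markers) {
  if (nrow(df) == 0L) return(invisible(df))
  key <- paste(df$case_id, df$roi_id, df$cell_id)
  if (anyDuplicated(key)) {
    dup <- df$cell_id[duplicated(key)]
    stopf("duplicated cell_id within ROI: %s", paste(unique(dup), collapse = ", "))
  }
  num <- c("x_px", "y_px", "area_px", markers)
  for (cn in num) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stopf("malformed cell table: column '%s' has missing or non-numeric entries", cn)
  }
  if (any(df$x_px < 0) || any(df$y_px < 0)) stopf("cell centroids must be >= 0")
  if (any(df$area_px < 1)) stopf("cell areas must be >= 1 pixel")
  for (m in markers)
    if (any(df[[m]] < 0)) stopf("negative mean intensity in marker '%s'", m)
  invisible(df)
}

cell_table_markers <- function(cells) {
  m <- attr(cells, "markers")
  if (is.null(m)) stopf("not a cell_table (no markers attribute)")
  m
}

#' Write a cell table to CSV
#'
#' Columns are written in the canonical order so files are diffable; floats
#' use full precision (roundtrips are exact to < 1e-9).
#'
#' @param cells a [cell_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  markers <- cell_table_markers(cells)
  df <- as.data.frame(cells)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' @param path CSV written by [write_cell_table()] (or matching its schema).
#' @param markers marker column names; by default every column after
#'   `cluster` is treated as a marker, so pass `markers` explicitly for
#'   files carrying extra trailing columns (e.g. simulation ground truth).
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, markers = NULL) {
  if (!file.exists(path)) stopf("cell table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(markers)) {
    i <- match("cluster", names(df))
    if (is.na(i)) stopf("malformed cell table file (no 'cluster' column): %s", path)
    markers <- names(df)[seq_len(ncol(df)) > i]
  }
  if (nrow(df) == 0L) {
    # read.csv types header-only columns as logical; restore the schema
    for (cn in c("cell_id", "case_id", "roi_id", "population"))
      df[[cn]] <- character(0)
    for (cn in c("x_px", "y_px", "area_px", markers))
      df[[cn]] <- numeric(0)
    df$cluster <- integer(0)
  } else {
    df$population <- as.character(df$population)
    df$cluster <- as.integer(df$cluster)
  }
  cell_table(df, markers)
}

#' Cohort manifest: case-to-group assignment
#'
#' @param df data.frame with columns `case_id` and `group`; extra columns
#'   are kept as covariates.
#' @return A `data.frame` of subclass `cohort_manifest`.
#' @export
cohort_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("case_id", "group") %in% names(df)))
    stopf("manifest needs columns case_id and group")
  if (anyDuplicated(df$case_id))
    stopf("duplicated case_id in manifest: %s",
          paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "))
  structure(df, class = c("cohort_manifest", "data.frame"))
}

#' @rdname cohort_manifest
#' @param path CSV path.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  cohort_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname cohort_manifest
#' @param manifest a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

# Map each cell to its case's group; errors on unknown cases or != 2 groups.
cell_groups <- function(cells, manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  g <- manifest$group[match(cells$case_id, manifest$case_id)]
  if (anyNA(g))
    stopf("cells reference cases missing from the manifest: %s",
          paste(unique(cells$case_id[is.na(g)]), collapse = ", "))
  if (length(unique(manifest$group)) != 2L)
    stopf("two-group statistics need exactly two group levels (found: %s)",
          paste(unique(manifest$group), collapse = ", "))
  g
}

# Resolve the (group1, group2) orientation; group1 defaults to the first
# manifest level and is the numerator of fold changes.
group_levels <- function(manifest, group1 = NULL) {
  lv <- unique(manifest$group)
  if (length(lv) != 2L) stopf("manifest must contain exactly two groups")
  if (is.null(group1)) group1 <- lv[1L]
  if (!group1 %in% lv) stopf("group1 '%s' not a manifest group", group1)
  c(group1, setdiff(lv, group1))
}
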