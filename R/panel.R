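#' Antibody panel configuration
#'
#' A panel binds marker names to image channels, assigns each marker a role
#' (lineage, functional, structural or nuclear), and carries the positivity
#' thresholds used for gating plus the physical pixel size.
#'
#' @param markers data.frame with columns `name`, `channel` (1-based channel
#'   index into the image stack) and `role` (one of `"lineage"`,
#'   `"functional"`, `"structural"`, `"nuclear"`).
#' @param gate_thresholds named numeric vector of positivity thresholds
#'   (mean-intensity units); names must be marker names. Markers without an
#'   entry cannot be used in gating rules.
#' @param pixel_size_um micrometers per pixel (positive).
#'
#' @return An object of class `panel_config`.
#' @seealso [default_panel()], [read_panel_config()]
#' @export
panel_config <- function(markers, gate_thresholds = numeric(), pixel_size_um = 1) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  req <- c("name", "channel", "role")
  if (!all(req %in% names(markers)))
    stopf("panel markers need columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(markers$name))
    stopf("duplicate marker names: %s",
          paste(unique(markers$name[duplicated(markers$name)]), collapse = ", "))
  if (anyDuplicated(markers$channel))
    stopf("duplicate channel indices in panel")
  roles <- c("lineage", "functional", "structural", "nuclear")
  if (!all(markers$role %in% roles))
    stopf("marker roles must be one of: %s", paste(roles, collapse = ", "))
  gate_thresholds <- unlist(gate_thresholds)
  if (length(gate_thresholds)) {
    if (is.null(names(gate_thresholds)) || !all(names(gate_thresholds) %in% markers$name))
      stopf("gate_thresholds must be named by panel markers")
    if (any(gate_thresholds < 0)) stopf("gate thresholds must be >= 0")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stopf("pixel_size_um must be a positive scalar")
  structure(
    list(markers = markers[, req],
         gate_thresholds = gate_thresholds,
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> %d markers, %.3g um/px\n",
              nrow(x$markers), x$pixel_size_um))
  for (r in split(x$markers$name, x$markers$role))
    cat(" ", paste(r, collapse = " "), "\n")
  invisible(x)
}

panel_marker_names <- function(panel) panel$markers$name

#' Default 27-marker NSCLC tumor microenvironment panel
#'
#' The analysis panel used throughout the package: nuclear markers (DNA
#' intercalator, histone H3), six lineage markers (CK for epithelial tumor
#' cells; CD3/CD4/CD8 for T cells; CD68 for macrophages; CD20 for B cells),
#' vimentin as a structural stromal marker, and functional/immunoregulatory
#' markers (PD-1, PD-L1, PD-L2, LAG3, TIM3, VISTA, IDO1, B7-H3, B7-H4,
#' CD25, CD45RO, FOXP3, TBET, KI67, GRZB, B2M, CD47, GAPDH).
#'
#' Default gate thresholds are on the synthetic-cohort "ion count" intensity
#' scale (see [simulation_config()]): a mean of 5 counts over the cell mask
#' separates rendered lineage signal from Poisson background.
#'
#' @param pixel_size_um micrometers per pixel (IMC acquisitions are 1 um/px).
#' @return A [panel_config()].
#' @export
default_panel <- function(pixel_size_um = 1) {
  name <- c("DNA", "VIM", "TBET", "CD47", "CK", "CD45RO", "PDL1", "GAPDH",
            "B7H3", "LAG3", "TIM3", "FOXP3", "CD4", "B7H4", "CD68", "PD1",
            "CD20", "CD8", "CD25", "VISTA", "KI67", "B2M", "CD3", "IDO1",
            "PDL2", "GRZB", "H3")
  role <- rep("functional", length(name))
  role[name %in% c("DNA", "H3")] <- "nuclear"
  role[name %in% c("CK", "CD3", "CD4", "CD8", "CD68", "CD20")] <- "lineage"
  role[name == "VIM"] <- "structural"
  thr <- stats::setNames(rep(5, 6), c("CK", "CD3", "CD4", "CD8", "CD68", "CD20"))
  panel_config(data.frame(name = name, channel = seq_along(name), role = role),
               gate_thresholds = thr, pixel_size_um = pixel_size_um)
}

#' Read a panel configuration from YAML or JSON
#'
#' The file must contain `markers` (list of `name`/`channel`/`role`
#' records), and may contain `gate_thresholds` (marker -> threshold map) and
#' `pixel_size_um`.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return A [panel_config()].
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stopf("unsupported panel format '.%s' (use YAML or JSON)", ext))
  markers <- do.call(rbind, lapply(raw$markers, function(m)
    data.frame(name = m$name, channel = m$channel, role = m$role)))
  panel_config(markers,
               gate_thresholds = unlist(raw$gate_thresholds),
               pixel_size_um = if (is.null(raw$pixel_size_um)) 1 else raw$pixel_size_um)
}

#' Write a panel configuration to YAML
#'
#' @param panel a [panel_config()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "panel_config"))
  out <- list(
    markers = lapply(seq_len(nrow(panel$markers)), function(i)
      as.list(panel$markers[i, ])),
    gate_thresholds = as.list(panel$gate_thresholds),
    pixel_size_um = panel$pixel_size_um)
  yaml::write_yaml(out, path)
  invisible(path)
}
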