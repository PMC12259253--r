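#' Segmentation parameters
#'
#' @param dna_channels marker names summed to form the nuclear signal.
#' @param smoothing_sigma_px Gaussian pre-smoothing width (0 = none).
#' @param nucleus_threshold absolute intensity threshold on the smoothed
#'   nuclear signal; `NULL` selects Otsu's threshold automatically.
#' @param min_nucleus_area_px components smaller than this are dropped.
#' @param expansion_radius_px Euclidean expansion radius from the nucleus
#'   to the cell boundary (the standard choice is 3 px).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(dna_channels = c("DNA", "H3"),
                                smoothing_sigma_px = 1,
                                nucleus_threshold = NULL,
                                min_nucleus_area_px = 5,
                                expansion_radius_px = 3) {
  stopifnot(length(dna_channels) >= 1L, smoothing_sigma_px >= 0,
            min_nucleus_area_px >= 1, expansion_radius_px >= 0)
  structure(list(dna_channels = dna_channels,
                 smoothing_sigma_px = smoothing_sigma_px,
                 nucleus_threshold = nucleus_threshold,
                 min_nucleus_area_px = min_nucleus_area_px,
                 expansion_radius_px = expansion_radius_px),
            class = "segmentation_params")
}

label_mask <- function(labels, centroids) {
  structure(list(labels = labels, centroids = centroids), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %dx%d px, %d objects\n",
              nrow(x$labels), ncol(x$labels), nrow(x$centroids)))
  invisible(x)
}

# Contiguous relabeling + centroid bookkeeping for an integer mask.
finalize_mask <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    map <- integer(max(ids)); map[ids] <- seq_along(ids)
    pos <- lab > 0
    lab[pos] <- map[lab[pos]]
  }
  idx <- which(lab > 0)
  if (length(idx)) {
    l <- lab[idx]
    x <- (idx - 1L) %/% nrow(lab)        # 0-based column
    y <- (idx - 1L) %% nrow(lab)         # 0-based row
    cent <- data.frame(label = sort(unique(l)),
                       x_px = as.vector(tapply(x, l, mean)),
                       y_px = as.vector(tapply(y, l, mean)),
                       area_px = as.vector(tapply(x, l, length)))
  } else {
    cent <- data.frame(label = integer(0), x_px = numeric(0),
                       y_px = numeric(0), area_px = numeric(0))
  }
  label_mask(lab, cent)
}

#' Detect nuclei on the DNA channels
#'
#' Sums the configured nuclear channels, Gaussian-smooths, thresholds
#' (Otsu by default), labels 4-connected components and removes those below
#' the minimum area. An image with no pixel above threshold yields an empty
#' mask with a warning.
#'
#' @param image a [multichannel_image()].
#' @param params a [segmentation_params()].
#' @return A `label_mask`: integer `H x W` matrix (0 = background, k > 0 =
#'   nucleus k) plus a centroid table (0-based pixel coordinates).
#' @export
detect_nuclei <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(params, "segmentation_params"))
  miss <- setdiff(params$dna_channels, image$channel_names)
  if (length(miss)) stopf("DNA channels missing from image: %s", paste(miss, collapse = ", "))
  dna <- Reduce(`+`, lapply(params$dna_channels, function(ch) get_channel(image, ch)))
  if (params$smoothing_sigma_px > 0)
    dna <- EBImage::gblur(dna, sigma = params$smoothing_sigma_px)
  thr <- params$nucleus_threshold
  if (is.null(thr)) {
    mx <- max(dna)
    thr <- if (mx <= 0) Inf else EBImage::otsu(dna / mx, range = c(0, 1)) * mx
  }
  bw <- dna > thr
  if (!any(bw)) {
    warnf("no pixel above the nuclear threshold; returning an empty mask")
    return(finalize_mask(matrix(0L, nrow(dna), ncol(dna))))
  }
  lab <- EBImage::bwlabel(bw)   # 4-connected components
  area <- tabulate(lab[lab > 0])
  drop <- which(area < params$min_nucleus_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  finalize_mask(lab)
}

#' Expand nuclei to cell objects by fixed-radius Voronoi growth
#'
#' Every background pixel within `expansion_radius_px` (Euclidean) of a
#' nucleus joins a cell. Pixels reachable from two or more nuclei are
#' assigned to the nucleus with the nearest centroid, which places the
#' inter-cell boundary at the perpendicular bisector — the locus at the
#' median distance between the two nuclei. Exactly equidistant pixels go to
#' the lowest label. Nucleus pixels always keep their own label, so
#' expansion never merges, splits or deletes objects.
#'
#' @param nuclei a `label_mask` from [detect_nuclei()].
#' @param params a [segmentation_params()].
#' @return The cell `label_mask` (same labels, same centroid table).
#' @export
expand_to_cells <- function(nuclei, params = segmentation_params()) {
  stopifnot(inherits(nuclei, "label_mask"))
  lab <- nuclei$labels
  r <- params$expansion_radius_px
  if (r == 0 || nrow(nuclei$centroids) == 0L) return(nuclei)
  H <- nrow(lab); W <- ncol(lab)
  cx <- cy <- rep(NA_real_, max(nuclei$centroids$label))
  cx[nuclei$centroids$label] <- nuclei$centroids$x_px
  cy[nuclei$centroids$label] <- nuclei$centroids$y_px
  off <- disk_offsets(r)
  rowm <- matrix(seq_len(H) - 1L, H, W)          # 0-based y
  colm <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)  # 0-based x
  best_d2 <- matrix(Inf, H, W)
  best_lab <- matrix(0L, H, W)
  bg <- lab == 0L
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    src_r <- intersect(seq_len(H), seq_len(H) + di)
    src_c <- intersect(seq_len(W), seq_len(W) + dj)
    if (!length(src_r) || !length(src_c)) next
    shifted <- matrix(0L, H, W)
    shifted[src_r - di, src_c - dj] <- lab[src_r, src_c]
    cand <- which(shifted > 0L & bg)
    if (!length(cand)) next
    L <- shifted[cand]
    d2 <- (colm[cand] - cx[L])^2 + (rowm[cand] - cy[L])^2
    cur_d2 <- best_d2[cand]; cur_lab <- best_lab[cand]
    upd <- d2 < cur_d2 - 1e-9 |
      (abs(d2 - cur_d2) <= 1e-9 & (cur_lab == 0L | L < cur_lab))
    if (any(upd)) {
      best_d2[cand[upd]] <- d2[upd]
      best_lab[cand[upd]] <- L[upd]
    }
  }
  out <- lab
  grown <- best_lab > 0L
  out[grown] <- best_lab[grown]
  label_mask(out, nuclei$centroids)
}

#' Per-cell mean marker intensities
#'
#' One row per label: `mean_intensity[m]` is the mean of channel `m` over
#' the cell's pixel set; the centroid and area refer to the full cell mask.
#'
#' @param mask a cell `label_mask` (same shape as the image).
#' @param image a [multichannel_image()].
#' @return A [cell_table()] (populations and clusters unset).
#' @export
quantify_cells <- function(mask, image) {
  stopifnot(inherits(mask, "label_mask"), inherits(image, "multichannel_image"))
  d <- dim(image$data)
  if (!all(dim(mask$labels) == d[1:2]))
    stopf("mask (%dx%d) and image (%dx%d) shapes differ",
          nrow(mask$labels), ncol(mask$labels), d[1L], d[2L])
  idx <- which(mask$labels > 0L)
  markers <- image$channel_names
  if (!length(idx)) {
    empty <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(markers)), markers))
    return(cell_table(data.frame(cell_id = character(0), case_id = character(0),
                                 roi_id = character(0), x_px = numeric(0),
                                 y_px = numeric(0), area_px = numeric(0),
                                 empty, check.names = FALSE), markers))
  }
  l <- mask$labels[idx]
  ids <- sort(unique(l))
  lf <- factor(l, levels = ids)
  area <- as.vector(table(lf))
  x <- (idx - 1L) %/% d[1L]
  y <- (idx - 1L) %% d[1L]
  means <- vapply(seq_along(markers), function(mi) {
    v <- image$data[, , mi][idx]
    as.vector(rowsum(v, lf)) / area
  }, numeric(length(ids)))
  if (is.null(dim(means))) means <- matrix(means, nrow = length(ids))
  colnames(means) <- markers
  cell_table(data.frame(
    cell_id = sprintf("c%04d", ids),
    case_id = image$case_id, roi_id = image$roi_id,
    x_px = as.vector(tapply(x, lf, mean)),
    y_px = as.vector(tapply(y, lf, mean)),
    area_px = area, means, check.names = FALSE), markers)
}

#' Segment and quantify one ROI
#'
#' Convenience wrapper: [detect_nuclei()], [expand_to_cells()],
#' [quantify_cells()].
#'
#' @inheritParams detect_nuclei
#' @return A [cell_table()].
#' @export
segment_roi <- function(image, params = segmentation_params()) {
  nuclei <- detect_nuclei(image, params)
  cells <- expand_to_cells(nuclei, params)
  quantify_cells(cells, image)
}
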