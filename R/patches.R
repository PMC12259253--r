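#' Patch selection parameters
#'
#' @param n_patches patches per case (14 micro-patches is the standard
#'   setting).
#' @param patch_side_um physical side length of the square patch (35 um).
#' @param selection_marker marker whose local mean drives the selection
#'   (CK, so patches center on the strongest tumor signal).
#' @param allow_overlap permit overlapping patches.
#' @return An object of class `patch_params`.
#' @export
patch_params <- function(n_patches = 14, patch_side_um = 35,
                         selection_marker = "CK", allow_overlap = FALSE) {
  stopifnot(is_count(n_patches), n_patches >= 1, patch_side_um > 0)
  structure(list(n_patches = n_patches, patch_side_um = patch_side_um,
                 selection_marker = selection_marker,
                 allow_overlap = allow_overlap), class = "patch_params")
}

#' Select expression patches at successive maxima of a marker
#'
#' The selection-marker channel is smoothed with a patch-sized box filter;
#' patch centers are chosen greedily at successive maxima of the filtered
#' map (ties broken row-major), skipping — unless overlap is allowed —
#' any center whose patch would overlap an already-selected patch. Every
#' patch must lie fully inside the ROI. The per-patch mean expression of
#' all markers is computed over the patch square.
#'
#' @param image a [multichannel_image()].
#' @param params a [patch_params()].
#' @return An object of class `patch_set`: list with `info` (data.frame
#'   `case_id`, `roi_id`, `center_x`, `center_y`, `side_px`, `score`) and
#'   `expr` (`n_patches x M` matrix of per-patch mean marker expression,
#'   columns in image channel order).
#' @export
select_patches <- function(image, params = patch_params()) {
  stopifnot(inherits(image, "multichannel_image"), inherits(params, "patch_params"))
  side <- round(params$patch_side_um / image$pixel_size_um)
  if (side %% 2 == 0) side <- side + 1L      # odd side so the center pixel is defined
  d <- dim(image$data)
  if (side > d[1L] || side > d[2L])
    stopf("ROI (%dx%d px) is smaller than one %d px patch", d[1L], d[2L], side)
  sel <- get_channel(image, params$selection_marker)
  score <- box_mean_filter(sel, side)
  cand <- which(!is.na(score))
  # row-major tie-break: order by -score, then row, then column
  cr <- (cand - 1L) %% d[1L]; cc <- (cand - 1L) %/% d[1L]
  ord <- cand[order(-score[cand], cr, cc)]
  chosen <- integer(0)
  ch_r <- integer(0); ch_c <- integer(0)
  for (i in ord) {
    if (length(chosen) == params$n_patches) break
    r <- (i - 1L) %% d[1L]; cl <- (i - 1L) %/% d[1L]
    if (!params$allow_overlap && length(chosen) &&
        any(abs(ch_r - r) < side & abs(ch_c - cl) < side)) next
    chosen <- c(chosen, i); ch_r <- c(ch_r, r); ch_c <- c(ch_c, cl)
  }
  if (length(chosen) < params$n_patches)
    stopf("patch shortfall: only %d of %d non-overlapping %d px patches fit in %s/%s",
          length(chosen), params$n_patches, side, image$case_id, image$roi_id)
  expr <- vapply(seq_len(d[3L]), function(mi) {
    f <- box_mean_filter(image$data[, , mi], side)
    f[chosen]
  }, numeric(length(chosen)))
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = length(chosen))
  colnames(expr) <- image$channel_names
  structure(list(
    info = data.frame(case_id = image$case_id, roi_id = image$roi_id,
                      center_x = ch_c, center_y = ch_r,    # 0-based pixel coords
                      side_px = side, score = score[chosen]),
    expr = expr), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %s/%s: %d patches of %d px, %d markers\n",
              x$info$case_id[1L], x$info$roi_id[1L], nrow(x$info),
              x$info$side_px[1L], ncol(x$expr)))
  invisible(x)
}
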