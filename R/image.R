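#' Multichannel IMC image
#'
#' An in-memory region-of-interest (ROI) intensity stack: one channel per
#' metal-conjugated antibody, stored as an `H x W x C` array of finite,
#' non-negative intensities ("ion counts"). Channels are ordered as in the
#' bound panel; this order defines the marker order of every downstream
#' matrix.
#'
#' @param data numeric `H x W x C` array (or `H x W` matrix for C = 1).
#' @param channel_names length-C character vector of marker names.
#' @param case_id,roi_id identifiers carried through the pipeline.
#' @param pixel_size_um micrometers per pixel.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(data, channel_names, case_id = "case", roi_id = "roi",
                               pixel_size_um = 1) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("image data must be an H x W x C array")
  if (dim(data)[3L] != length(channel_names))
    stopf("channel count (%d) does not match channel_names (%d)",
          dim(data)[3L], length(channel_names))
  bad <- which(!is.finite(data) | data < 0)
  if (length(bad)) {
    ix <- arrayInd(bad[1L], dim(data))
    stopf("invalid pixel value at (row %d, col %d) of channel '%s' (%s)",
          ix[1L], ix[2L], channel_names[ix[3L]],
          format(data[bad[1L]]))
  }
  dimnames(data) <- list(NULL, NULL, channel_names)
  structure(list(data = data, channel_names = channel_names,
                 case_id = case_id, roi_id = roi_id,
                 pixel_size_um = pixel_size_um),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multichannel_image> %s/%s %dx%d px, %d channels, %.3g um/px\n",
              x$case_id, x$roi_id, d[1L], d[2L], d[3L], x$pixel_size_um))
  invisible(x)
}

#' Extract one channel as a matrix
#' @param image a [multichannel_image()].
#' @param channel marker name.
#' @return `H x W` numeric matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!channel %in% image$channel_names)
    stopf("channel '%s' not in image (channels: %s)", channel,
          paste(image$channel_names, collapse = ", "))
  image$data[, , channel]
}

#' Read a multipage TIFF stack against a panel
#'
#' Pages are matched to panel markers by the panel's `channel` indices, so
#' the returned image always carries channels in panel marker order.
#' Integer TIFFs are read as raw counts (no [0,1] rescaling); float TIFFs
#' are read as stored. Negative or non-finite pixels are rejected with the
#' offending channel and coordinates.
#'
#' @param path multipage TIFF file.
#' @param panel a [panel_config()]; the page count must equal the panel size.
#' @param case_id,roi_id identifiers to attach.
#' @return A [multichannel_image()].
#' @export
read_image_stack <- function(path, panel, case_id = "case", roi_id = "roi") {
  stopifnot(inherits(panel, "panel_config"))
  if (!file.exists(path)) stopf("image file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) 32L else as.integer(b)
  }, integer(1))
  # 8/16-bit pages hold integer counts (re-read raw); 32-bit pages hold
  # floats (already read as stored)
  if (all(bits <= 16L)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  m <- nrow(panel$markers)
  if (length(pages) != m)
    stopf("channel mismatch: file '%s' has %d pages, panel has %d markers",
          path, length(pages), m)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  data <- array(0, c(h, w, m))
  for (i in seq_len(m)) data[, , i] <- pages[[panel$markers$channel[i]]]
  multichannel_image(data, panel$markers$name, case_id = case_id,
                     roi_id = roi_id, pixel_size_um = panel$pixel_size_um)
}

#' Write a multichannel image as a 16-bit multipage TIFF
#'
#' Intensities must be integer-valued and below 2^16 (the IMC count scale);
#' pages are written in the image's channel order.
#'
#' @param image a [multichannel_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  d <- image$data
  if (max(abs(d - round(d))) > 1e-8)
    stopf("image intensities must be integer-valued counts for 16-bit storage")
  if (max(d) > 65535) stopf("image intensities exceed the 16-bit range")
  pages <- lapply(seq_len(dim(d)[3L]), function(i) round(d[, , i]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
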