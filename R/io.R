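# TIFF and table I/O.  Channels are stored one 16-bit grayscale TIFF per
# channel with a JSON sidecar carrying the pixel size, intensity scale and
# section metadata; masks and band maps are stored as 8-bit label TIFFs.

#' Write a multiplex image to a directory of TIFFs
#'
#' One 16-bit grayscale TIFF per channel plus `metadata.json` (pixel size,
#' per-channel intensity scale, section metadata).  Intensities are mapped
#' to the 16-bit grid; quantization error is bounded by `scale / 65535`.
#'
#' @param image A `multiplex_image`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiplex <- function(image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- vapply(image$channels, function(ch) max(ch, 1e-9), numeric(1))
  for (nm in names(image$channels)) {
    ch <- pmin(pmax(image$channels[[nm]] / scales[[nm]], 0), 1)
    # tiff expects row-major [y, x]
    tiff::writeTIFF(t(ch), file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(pixel_size_um = image$pixel_size_um,
               channels = as.list(scales), meta = image$meta)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multiplex image written by [write_multiplex()]
#'
#' @param dir Directory containing channel TIFFs and `metadata.json`.
#' @return A `multiplex_image`.
#' @export
read_multiplex <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  channels <- list()
  for (nm in names(meta$channels)) {
    m <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")))
    channels[[nm]] <- t(m) * meta$channels[[nm]]
  }
  structure(list(channels = channels, pixel_size_um = meta$pixel_size_um,
                 meta = as.list(meta$meta)),
            class = "multiplex_image")
}

#' Write a label image (mask or band map) as an 8-bit TIFF
#'
#' @param labels Integer matrix with values 0..255 (band indices or 0/1
#'   masks).
#' @param path Output file.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 255) stopf("label image exceeds 8-bit range")
  tiff::writeTIFF(t(labels / 255), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#' @param path TIFF file.
#' @return Integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- round(t(tiff::readTIFF(path)) * 255)
  storage.mode(m) <- "integer"
  m
}
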