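# TIFF I/O. Fields are written as one multi-page TIFF (one page per
# channel) with a key=value sidecar recording channel order and the
# intensity scale used to map photon counts onto the [0, 1] range that
# TIFF storage expects; masks are single-page 8-bit TIFFs (0/255).

#' Write a field image as a multi-page TIFF with sidecar
#'
#' @param field A `field_image`.
#' @param path Output TIFF path.
#' @param sidecar Path of the key=value sidecar (default `path` +
#'   `".cfg"`).
#' @param scale Intensity divisor applied before writing; defaults to the
#'   maximum intensity over all channels (or 1 for an all-zero field).
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, sidecar = paste0(path, ".cfg"),
                             scale = NULL) {
  stopifnot(inherits(field, "field_image"))
  if (is.null(scale)) {
    scale <- max(1, vapply(field$channels, max, numeric(1)))
  }
  pages <- lapply(field$channels, function(x) pmin(x / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  lines <- c(
    paste0("channels=", paste(names(field$channels), collapse = ",")),
    paste0("scale=", format(scale, digits = 17))
  )
  writeLines(lines, sidecar)
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' @param path TIFF path.
#' @param sidecar Sidecar path (default `path` + `".cfg"`).
#' @return A `field_image`.
#' @export
read_field_tiff <- function(path, sidecar = paste0(path, ".cfg")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  kv <- read_sidecar(sidecar)
  chans <- strsplit(kv[["channels"]], ",")[[1]]
  scale <- as.numeric(kv[["scale"]])
  stopifnot(length(pages) == length(chans))
  channels <- lapply(pages, function(pg) pg * scale)
  names(channels) <- chans
  structure(list(channels = channels), class = "field_image")
}

read_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask TIFF
#'
#' @param path TIFF path.
#' @return Logical matrix.
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0.5
}
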