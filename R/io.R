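# Image input/output. EBImage stores images as (x, y[, channel]); this
# package works in matrix orientation (row, col), so readers and writers
# transpose.

#' Read a fundus image
#'
#' Reads PNG/TIFF/JPEG. RGB images are returned as H x W x 3 arrays in
#' [0, 1]; grayscale ones as H x W matrices. An alpha channel, if present,
#' is dropped.
#'
#' @param path image file.
#' @export
read_fundus_image <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 2L) return(t(a))
  a <- aperm(a, c(2L, 1L, 3L))
  if (dim(a)[3] >= 3L) a[, , 1:3, drop = FALSE][, , 1:3] else a[, , 1L]
}

#' Read a binary mask (PNG/GIF/TIFF)
#'
#' Multi-channel masks are collapsed to their first channel; values above
#' 0.5 become 1.
#'
#' @param path mask file.
#' @export
read_mask <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- t(a)
  (m > 0.5) * 1L
}

#' Write a probability map as an image
#'
#' \code{.tif} files are written with 16 bits per sample; \code{.png} with 8
#' (the png codec available here does not write 16-bit). Use
#' \code{\link{write_npy}} when full float precision is required.
#'
#' @param map H x W matrix in [0, 1].
#' @param path output file (.png or .tif).
#' @export
write_probability_map <- function(map, path) {
  img <- EBImage::Image(t(pmin(pmax(map, 0), 1)))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    EBImage::writeImage(img, path, bits.per.sample = 16L)
  else
    EBImage::writeImage(img, path)
  invisible(path)
}

#' Write a numeric array in NumPy .npy format
#'
#' Minimal v1.0 writer (little-endian float64, C order) so probability maps
#' can be consumed by Python tooling.
#'
#' @param x numeric vector, matrix or array.
#' @param path output file.
#' @export
write_npy <- function(x, path) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  # C order: fastest-varying index last; R arrays are Fortran order
  xr <- if (length(dims) > 1L) aperm(x, rev(seq_along(dims))) else x
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1L) ",", ")")
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape)
  pad <- (64L - ((10L + nchar(header) + 1L) %% 64L)) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(as.numeric(xr)), con, size = 8L, endian = "little")
  invisible(path)
}
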