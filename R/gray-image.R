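#' Grayscale thermogram raster
#'
#' A thin container for a single-channel intensity image: an integer matrix
#' plus its bit depth. All preprocessing and segmentation functions in
#' thermofuse operate on this type. Plain matrices are accepted everywhere and
#' coerced with an assumed bit depth of 8.
#'
#' @param pixels integer matrix of intensities, values in `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `gray_image`: the pixel matrix with a
#'   `bit_depth` attribute.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), bit_depth = 8)
#' max_gray(img)
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one pixel", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  px <- round(pixels)
  lim <- 2^bit_depth - 1
  if (anyNA(px) || min(px) < 0 || max(px) > lim) {
    stop("pixel values must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(px, bit_depth = as.integer(bit_depth), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, range [%d, %d]>\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Coerce to a gray_image
#'
#' @param x matrix or `gray_image`.
#' @param bit_depth assumed bit depth when `x` is a plain matrix.
#' @return a `gray_image`.
#' @export
as_gray_image <- function(x, bit_depth = 8L) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, bit_depth = bit_depth)
}

#' Bit depth and maximum representable gray level
#'
#' @param img a `gray_image` (or matrix, assumed 8-bit).
#' @return `bit_depth()` returns the integer bit depth; `max_gray()` returns
#'   `2^bit_depth - 1`.
#' @export
bit_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 8L else bd
}

#' @rdname bit_depth
#' @export
max_gray <- function(img) 2L^bit_depth(img) - 1L

#' Read and write grayscale images
#'
#' PNG and TIFF readers/writers for single-channel rasters. Multi-channel
#' files are collapsed to luminance by averaging channels. Binary masks are
#' written as 0/255 PNG and read back as 0/1 matrices.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param bit_depth bit depth to decode into (8 or 16).
#' @return `read_gray()` returns a `gray_image`; `read_mask()` a 0/1 integer
#'   matrix; the writers return `path` invisibly.
#' @export
read_gray <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  gray_image(round(arr * (2^bit_depth - 1)), bit_depth = bit_depth)
}

#' @rdname read_gray
#' @param img a `gray_image` (or matrix) to write.
#' @export
write_gray <- function(img, path) {
  img <- as_gray_image(img)
  norm <- as.matrix(img) / max_gray(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(norm, target = path),
    tif = ,
    tiff = tiff::writeTIFF(norm, where = path,
                           bits.per.sample = bit_depth(img)),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' @rdname read_gray
#' @param mask 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 1)))
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' @rdname read_gray
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  m <- (arr >= 0.5) * 1L
  dim(m) <- dim(arr)[1:2]
  m
}

# clamp a numeric vector/matrix into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
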