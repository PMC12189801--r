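#' Read an RGB image from PNG or TIFF
#'
#' Images are returned as plain base-R arrays of doubles in `[0, 1]` with
#' dimensions height x width x 3 (rows are the vertical axis, origin at the
#' top-left). 8-bit and 16-bit inputs are rescaled by their full bit range;
#' grayscale files are replicated across the three channels and any alpha
#' channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric H x W x 3 array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    input_error(sprintf("unsupported image format: .%s", ext))
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  x <- pmin(pmax(x, 0), 1)
  storage.mode(x) <- "double"
  x
}

#' Write an RGB image as PNG
#'
#' @param image Numeric H x W x 3 array in `[0, 1]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image, target = path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Write an integer label map as a 16-bit TIFF
#'
#' Labels are stored divided by 65535 so that readers recover the integer
#' label as `round(pixel * 65535)`; [read_label_map()] does this.
#'
#' @param labels Integer matrix (0 = background).
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) input_error("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, where = path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path Path to a 16-bit TIFF.
#' @return Integer matrix of labels.
#' @export
read_label_map <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Write / read a real-valued field (e.g. a distance transform)
#'
#' TIFF storage is defined on `[0, 1]`, so the field is divided by its
#' maximum before writing (32-bit samples) and the scale is recorded in a
#' small YAML sidecar next to the image; [read_field()] undoes this.
#'
#' @param field Numeric matrix with nonnegative values.
#' @param path Output path (`.tif`).
#' @return `path`, invisibly (write); the numeric matrix (read).
#' @export
write_field <- function(field, path) {
  if (min(field) < 0) input_error("`field` must be nonnegative")
  scale <- max(field, 1e-12)
  tiff::writeTIFF(field / scale, where = path, bits.per.sample = 32L)
  yaml::write_yaml(list(scale = scale), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  scale <- yaml::read_yaml(paste0(path, ".yaml"))$scale
  matrix(as.numeric(x) * scale, nrow(x), ncol(x))
}
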