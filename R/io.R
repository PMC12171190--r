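# Image file I/O. Intensity images and binary masks are exchanged as 8-bit
# grayscale PNG (the png package has no 16-bit writer); masks use {0, 255}.

#' Write an intensity image as 8-bit grayscale PNG
#' @param image H x W matrix in \[0,1\].
#' @param path output file path.
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a grayscale PNG as an H x W matrix in \[0,1\]
#' @param path PNG file path.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a binary mask as 8-bit PNG with values \{0, 255\}
#' @param mask H x W matrix with values in \{0, 1\}.
#' @param path output file path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a binary mask PNG as an H x W \{0, 1\} matrix
#' @param path PNG file path.
#' @export
read_mask_png <- function(path) {
  m <- read_image_png(path)
  (m >= 0.5) * 1
}
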