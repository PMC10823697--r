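#' Plate image container
#'
#' A `plate_image` wraps a 2D matrix of pixel intensities in `[0, 1]` together
#' with its plate identity, replicate number and processing stage. The stage
#' records where the image sits in the densitometry pipeline: `"raw"` (as
#' photographed: colonies dark on a light membrane), `"inverted"` (signal
#' positive: more oxidized ABTS product means higher intensity) or
#' `"background_subtracted"` (illumination field removed).
#'
#' @param pixels numeric matrix of intensities; all values must be finite and
#'   non-negative.
#' @param plate_id character scalar identifying the plate.
#' @param replicate integer replicate number.
#' @param stage one of `"raw"`, `"inverted"`, `"background_subtracted"`.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, plate_id = "plate", replicate = 1L,
                        stage = c("raw", "inverted", "background_subtracted")) {
  stage <- match.arg(stage)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a 2D numeric matrix")
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) {
    stop("`pixels` must be non-empty")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and non-negative")
  }
  structure(
    list(pixels = pixels, plate_id = as.character(plate_id),
         replicate = as.integer(replicate), stage = stage),
    class = "plate_image"
  )
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %s replicate %d, %d x %d px, stage: %s\n",
              x$plate_id, x$replicate, nrow(x$pixels), ncol(x$pixels), x$stage))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)

#' Read a plate image from a TIFF or PNG file
#'
#' Reads an 8- or 16-bit grayscale (or RGB, converted to grayscale by the
#' Rec. 709 luma weights) image. Camera RAW formats are not handled; convert
#' to TIFF/PNG beforehand.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @inheritParams plate_image
#' @return A `plate_image` at stage `"raw"`.
#' @export
read_plate_image <- function(path, plate_id = basename(path), replicate = 1L,
                             stage = "raw") {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  )
  px <- to_grayscale(px)
  plate_image(px, plate_id = plate_id, replicate = replicate, stage = stage)
}

#' Write a plate image to a 16-bit TIFF or PNG file
#'
#' @param image a `plate_image`.
#' @param path output path; format chosen by extension.
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

# Collapse an RGB(A) array to grayscale; pass matrices through.
to_grayscale <- function(px) {
  if (is.matrix(px)) return(px)
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    if (nch >= 3L) {
      return(0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L])
    }
    return(px[, , 1L])
  }
  stop("image must be a 2D matrix or 3D RGB array")
}
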