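#' Slide sources and image patches
#'
#' A slide source wraps a large RGB image (a whole-slide image at its base
#' resolution, or a synthetic stand-in) behind a rectangle accessor in
#' level-0 pixel coordinates. Coordinates are 0-based with `x` the column
#' and `y` the row; extents are half-open, so a patch of side `s` at origin
#' `(x, y)` covers `[x, x+s) x [y, y+s)`.
#'
#' @param image numeric array `H x W x 3` with intensities in `[0, 1]`.
#' @param id slide identifier string.
#' @return An object of class `pcead_slide`.
#' @export
slide_source <- function(image, id = "slide") {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("slide image must be an H x W x 3 RGB array")
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("slide intensities must lie in [0, 1]")
  structure(list(id = as.character(id), image = image),
            class = "pcead_slide")
}

#' @export
print.pcead_slide <- function(x, ...) {
  cat(sprintf("<pcead_slide '%s' %d x %d px>\n",
              x$id, slide_width(x), slide_height(x)))
  invisible(x)
}

#' @rdname slide_source
#' @param slide a `pcead_slide`.
#' @export
slide_width <- function(slide) dim(slide$image)[2]

#' @rdname slide_source
#' @export
slide_height <- function(slide) dim(slide$image)[1]

#' Read an RGB rectangle from a slide
#'
#' @param slide a `pcead_slide`.
#' @param x,y 0-based level-0 origin (column, row).
#' @param w,h rectangle width and height in pixels.
#' @return `h x w x 3` array in `[0, 1]`.
#' @export
slide_region <- function(slide, x, y, w, h) {
  if (x < 0 || y < 0 || x + w > slide_width(slide) ||
      y + h > slide_height(slide))
    stop("requested region extends outside the slide bounds")
  slide$image[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
}

#' Read a slide image from a PNG or TIFF file
#'
#' Grayscale and RGBA inputs are promoted/cropped to 3-channel RGB.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param id slide identifier; defaults to the file name without extension.
#' @return A `pcead_slide`.
#' @export
read_slide <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF slides requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported slide format: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  slide_source(img, id)
}

#' Write a slide image to a PNG or TIFF file
#'
#' @param slide a `pcead_slide`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(slide$image, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF slides requires the 'tiff' package")
      tiff::writeTIFF(slide$image, path)
    },
    stop("unsupported slide format: ", ext)
  )
  invisible(path)
}

#' Construct an image patch
#'
#' A patch is a square RGB tile carrying its provenance: the slide it came
#' from, its level-0 origin, and the level-0 extent (`span`) it covers.
#' For a patch extracted at base resolution `span == size`; for downsampled
#' pyramid levels `span` stays at the extraction size while `size` shrinks,
#' so `span / size` is the level-0 pixels represented by one patch pixel.
#'
#' @param image `s x s x 3` array in `[0, 1]`.
#' @param slide slide identifier string.
#' @param x,y 0-based level-0 origin.
#' @param span level-0 pixels covered along each side (default: patch side).
#' @return An object of class `pcead_patch`.
#' @export
new_patch <- function(image, slide = "slide", x = 0L, y = 0L,
                      span = nrow(image)) {
  d <- dim(image)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 3L)
    stop("patch image must be a square s x s x 3 array")
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("patch intensities must lie in [0, 1]")
  structure(list(image = image, slide = as.character(slide),
                 x = as.integer(x), y = as.integer(y),
                 size = d[1], span = as.integer(span)),
            class = "pcead_patch")
}

#' @export
print.pcead_patch <- function(x, ...) {
  cat(sprintf("<pcead_patch %dpx @(%d,%d) span %d slide '%s'>\n",
              x$size, x$x, x$y, x$span, x$slide))
  invisible(x)
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
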