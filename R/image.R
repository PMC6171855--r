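#' Face image container
#'
#' A raster face image: a height x width matrix of intensities in `[0, 1]`
#' (grayscale; RGB input is converted to luma on read) plus the angular size
#' the face subtends, which the blur simulator needs to convert cycles per
#' degree into pixels.
#'
#' @param pixels numeric matrix (rows = y, columns = x), values in `[0, 1]`.
#' @param width_deg degrees of visual angle subtended along the horizontal
#'   (default 18.11, a real head viewed at 54 cm). `NA` if unknown.
#' @return an object of class `face_image`.
#' @export
face_image <- function(pixels, width_deg = 18.11) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("`pixels` must be numeric", call. = FALSE)
  if (anyNA(pixels)) stop("`pixels` contains NA", call. = FALSE)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  structure(list(pixels = pmin(pmax(pixels, 0), 1),
                 width_deg = width_deg),
            class = "face_image")
}

#' @export
print.face_image <- function(x, ...) {
  cat(sprintf("Face image %d x %d px, %s deg wide, range [%.3f, %.3f]\n",
              ncol(x$pixels), nrow(x$pixels),
              ifelse(is.na(x$width_deg), "?", format(x$width_deg)),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.face_image <- function(x, ...) x$pixels

#' Pixels per degree of visual angle
#'
#' @param image a `face_image` with known `width_deg`.
#' @return pixels per degree along the horizontal.
#' @export
pixels_per_degree <- function(image) {
  stopifnot(inherits(image, "face_image"))
  if (is.na(image$width_deg))
    stop("image has no angular-size metadata (width_deg is NA)", call. = FALSE)
  ncol(image$pixels) / image$width_deg
}

#' Read a face image from a PNG or TIFF file
#'
#' 8- or 16-bit grayscale and RGB files are accepted; RGB is converted to
#' luma (Rec. 601 weights). Reading TIFF requires the `tiff` package.
#'
#' @param path file to read (`.png`, `.tif`/`.tiff`).
#' @param width_deg angular size metadata to attach (default 18.11).
#' @return a `face_image`.
#' @export
read_face_image <- function(path, width_deg = 18.11) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    a <- tiff::readTIFF(path)
  } else {
    a <- png::readPNG(path)
  }
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    a <- if (ch >= 3) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
         else a[, , 1]
  }
  face_image(a, width_deg = width_deg)
}

#' Write a face image to a PNG or TIFF file
#'
#' @param image a `face_image`.
#' @param path output file; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_face_image <- function(image, path) {
  stopifnot(inherits(image, "face_image"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package", call. = FALSE)
    tiff::writeTIFF(image$pixels, path)
  } else {
    png::writePNG(image$pixels, path)
  }
  invisible(path)
}

## Run code with a private RNG stream: the global .Random.seed is restored
## afterwards, so simulation helpers are reproducible without trampling the
## caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Bilinear sampling of matrix `img` at fractional pixel coordinates
## (x, y), 0-based; coordinates are clamped to the image border.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}
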