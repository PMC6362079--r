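#' Linear-light RGB image container
#'
#' Images throughout the package are linear-light RGB arrays with values in
#' \code{[0, 1]}: synthesis, calibration and scoring all operate before any
#' display gamma, and camera gamma encoding is inverted on load. A
#' `linear_image` wraps the pixel array together with an optional region of
#' interest (ROI) mask and the identifiers of the camera/lighting condition
#' that produced it (used to guard against applying a calibration model to an
#' image from a different condition).
#'
#' @param pixels numeric array \code{H x W x 3} with values in \code{[0, 1]}.
#' @param roi_mask optional logical \code{H x W} matrix; \code{TRUE} marks
#'   pixels eligible for scoring.
#' @param camera_id,lighting_id optional condition identifiers.
#' @return an object of class `linear_image`.
#' @export
linear_image <- function(pixels, roi_mask = NULL, camera_id = NULL,
                         lighting_id = NULL) {
  pixels <- as_pixel_array(pixels)
  if (!is.null(roi_mask)) {
    roi_mask <- as_mask(roi_mask)
    if (!identical(dim(roi_mask), dim(pixels)[1:2])) {
      stop("roi_mask dimensions must match the image", call. = FALSE)
    }
  }
  structure(
    list(pixels = pixels, roi_mask = roi_mask,
         camera_id = camera_id, lighting_id = lighting_id),
    class = "linear_image"
  )
}

#' @export
print.linear_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<linear_image %dx%d, range [%.4f, %.4f]%s%s>\n",
              d[1], d[2], min(x$pixels), max(x$pixels),
              if (is.null(x$roi_mask)) "" else
                sprintf(", ROI %d px", sum(x$roi_mask)),
              if (is.null(x$camera_id)) "" else
                sprintf(", %s/%s", x$camera_id, x$lighting_id)))
  invisible(x)
}

# Coerce to an H x W x 3 numeric array; a plain matrix is treated as gray.
as_pixel_array <- function(x) {
  if (inherits(x, "linear_image")) return(x$pixels)
  if (inherits(x, "scene_truth")) return(x$reflectance)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!(is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)) {
    stop("expected an H x W x 3 numeric array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

as_mask <- function(m) {
  if (is.matrix(m) && !is.logical(m)) m <- m > 0.5
  if (!(is.matrix(m) && is.logical(m))) {
    stop("expected a logical H x W mask matrix", call. = FALSE)
  }
  m
}

# Pixel matrix view: N x 3, rows in column-major image order.
pixel_matrix <- function(img) {
  px <- as_pixel_array(img)
  dim(px) <- c(prod(dim(px)[1:2]), 3L)
  px
}

matrix_to_image <- function(m, h, w) {
  array(m, dim = c(h, w, 3L))
}

#' Write and read linear images
#'
#' Linear images are stored as 16-bit TIFF (values scaled to
#' \code{[0, 65535]}); ROI masks as 8-bit PNG where any nonzero value marks an
#' included pixel. `read_linear_image` also accepts 8/16-bit PNG and can undo
#' a display gamma at load time so downstream code always sees linear light.
#'
#' @param image a `linear_image` or pixel array.
#' @param path file path (`.tif`/`.tiff` for images, `.png` for masks).
#' @param gamma encoding exponent of the stored file; pixel values are raised
#'   to this power on load (1 = already linear).
#' @return `read_linear_image` returns a `linear_image`; writers return the
#'   path invisibly.
#' @export
write_linear_image <- function(image, path) {
  px <- as_pixel_array(image)
  if (min(px) < 0 || max(px) > 1) stop("pixel values must lie in [0, 1]",
                                       call. = FALSE)
  tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_linear_image
#' @export
read_linear_image <- function(path, gamma = 1) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  px <- as_pixel_array(px)
  if (gamma != 1) px <- px^gamma
  linear_image(px)
}

#' @rdname write_linear_image
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1.0, path)
  invisible(path)
}

#' @rdname write_linear_image
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
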