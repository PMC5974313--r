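#' Construct a labeled 2-D point pattern
#'
#' A point pattern is an ordered set of cell localizations in micrometres,
#' with a population label (e.g. `"venus"`, `"hspc"`, `"random"`) and an
#' optional analysis window attached. Duplicate coordinates are permitted
#' (two cells can share a centroid at pixel resolution); non-finite
#' coordinates are not.
#'
#' @param x,y coordinate vectors in micrometres (equal length, finite).
#' @param label population name (single string).
#' @param window optional [make_window()] object.
#' @return an object of class `point_pattern` with fields `x`, `y`,
#'   `label`, `window`.
#' @export
#' @examples
#' p <- point_pattern(c(0, 3), c(0, 4), label = "venus")
#' npoints(p)
point_pattern <- function(x = numeric(0), y = numeric(0),
                          label = "points", window = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && !all(is.finite(x) & is.finite(y)))
    stop("coordinates must be finite (no NA/NaN/Inf)")
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.null(window)) stopifnot(inherits(window, "spatial_window"))
  structure(list(x = x, y = y, label = label, window = window),
            class = "point_pattern")
}

#' Number of points in a pattern
#' @param pattern a [point_pattern()].
#' @return integer count.
#' @export
npoints <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  length(pattern$x)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern '%s': %d point(s)\n", x$label, npoints(x)))
  if (!is.null(x$window))
    cat(sprintf("  window: %.6g x %.6g um\n", x$window$width, x$window$height))
  invisible(x)
}

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  data.frame(x = x$x, y = x$y, label = rep(x$label, length(x$x)))
}

#' Read a coordinate table of cell localizations
#'
#' Reads a comma-delimited table with mandatory header columns `x`, `y` and
#' an optional `label` column. Coordinates are returned in micrometres;
#' tables recorded in pixel units are converted by multiplying by
#' `pixel_size`.
#'
#' @param path path to a CSV file.
#' @param units `"um"` (default) or `"pixel"`.
#' @param pixel_size micrometres per pixel; required when `units = "pixel"`.
#' @param label population label to assign when the table has no `label`
#'   column; when the column is present its first value is used.
#' @param window optional window to attach.
#' @return a [point_pattern()], row order preserved.
#' @export
read_points <- function(path, units = c("um", "pixel"), pixel_size = NULL,
                        label = NULL, window = NULL) {
  units <- match.arg(units)
  if (units == "pixel" && is.null(pixel_size))
    stop("pixel units require `pixel_size` (um per pixel)")
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(d)))
    stop("coordinate table must have header columns x, y: ", path)
  if (!is.numeric(d$x) || !is.numeric(d$y))
    stop("non-numeric coordinates in ", path)
  scale <- if (units == "pixel") pixel_size else 1
  lab <- if (!is.null(label)) label
         else if ("label" %in% names(d) && nrow(d) > 0) as.character(d$label[1])
         else "points"
  point_pattern(d$x * scale, d$y * scale, label = lab, window = window)
}

#' Write a point pattern as a coordinate table
#'
#' Writes a comma-delimited table with header `x,y,label` at full double
#' precision, re-readable by [read_points()] (round-trip identity on
#' coordinates).
#'
#' @param pattern a [point_pattern()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_points <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  d <- as.data.frame(pattern)
  d$x <- format(d$x, digits = 17, trim = TRUE, scientific = FALSE)
  d$y <- format(d$y, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a label image
#'
#' A 2-D integer raster in which 0 is background and positive values are
#' foreground (or precomputed region ids), together with its physical pixel
#' size. Row 1 of the matrix is the top image row; [extract_centroids()]
#' flips the y axis so that returned coordinates grow upward.
#'
#' @param pixels integer/numeric matrix, non-empty.
#' @param pixel_size micrometres per pixel (> 0).
#' @return an object of class `label_image`.
#' @export
label_image <- function(pixels, pixel_size = 1) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix")
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "label_image")
}

#' Read a binary/label raster image from TIFF or PNG
#'
#' Pixel intensities above `threshold` are foreground. Requires the
#' `tiff` or `png` package for the respective format.
#'
#' @param path path to a `.tif/.tiff` or `.png` file.
#' @param pixel_size micrometres per pixel.
#' @param threshold foreground threshold on the (0, 1]-scaled intensity.
#' @return a [label_image()].
#' @export
read_label_image <- function(path, pixel_size = 1, threshold = 0.5) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the `tiff` package")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the `png` package")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  label_image((raw >= threshold) * 1L, pixel_size = pixel_size)
}

#' Extract centroids of connected components from a label image
#'
#' Labels 8-connected foreground components, filters them by pixel area,
#' and returns one point per surviving component at its area centroid in
#' micrometres. Components touching the image border are kept. The pixel at
#' (row i, column j), 0-based, has centre `x = (j + 0.5) * s`,
#' `y = (nrow - i - 0.5) * s` with `s` the pixel size: the image y axis is
#' flipped so that y grows upward from the bottom of the field.
#'
#' @param image a [label_image()].
#' @param min_area,max_area inclusive component-area bounds in pixels.
#' @param label population label for the resulting pattern.
#' @return a [point_pattern()] in micrometres; empty if no component passes.
#' @export
extract_centroids <- function(image, min_area = 1, max_area = Inf,
                              label = "centroids") {
  stopifnot(inherits(image, "label_image"))
  if (min_area < 1 || max_area < min_area)
    stop("need 1 <= min_area <= max_area")
  lab <- label8_cpp(image$pixels)
  k <- max(lab)
  if (k == 0L)
    return(point_pattern(label = label))
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  area <- tabulate(comp, nbins = k)
  ci <- vapply(split(idx[, 1], comp), mean, 0)  # mean row per component
  cj <- vapply(split(idx[, 2], comp), mean, 0)
  keep <- area >= min_area & area <= max_area
  s <- image$pixel_size
  nr <- nrow(image$pixels)
  # matrix indices are 1-based; pixel centre of row i1 is (i1 - 0.5)
  point_pattern(x = (cj[keep] - 0.5) * s,
                y = (nr - (ci[keep] - 0.5)) * s,
                label = label)
}

#' Read an exclusion mask as a spatial window
#'
#' Two mask encodings are supported. A CSV of circles (columns `x`, `y`,
#' `r`, micrometres) produces disc exclusions; `width`/`height` must then be
#' given. A raster image (TIFF/PNG, or a [label_image()]) is used directly
#' as a lookup field: nonzero pixels are excluded, the window rectangle is
#' the raster extent, and no disc fitting is attempted.
#'
#' @param path path to a circle CSV or raster image, or a [label_image()].
#' @param pixel_size micrometres per pixel (raster masks).
#' @param width,height window extent in micrometres (circle masks).
#' @param id optional window identifier.
#' @return a [make_window()] object.
#' @export
read_mask <- function(path, pixel_size = 1, width = NULL, height = NULL,
                      id = NULL) {
  img <- NULL
  if (inherits(path, "label_image")) {
    img <- path
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("csv", "txt")) {
      d <- read.csv(path, stringsAsFactors = FALSE)
      if (!all(c("x", "y", "r") %in% names(d)))
        stop("circle mask file must have header columns x, y, r")
      if (is.null(width) || is.null(height))
        stop("circle masks need an explicit window `width` and `height`")
      return(make_window(width, height, follicles = d, id = id))
    }
    img <- read_label_image(path, pixel_size = pixel_size)
  }
  w <- ncol(img$pixels) * img$pixel_size
  h <- nrow(img$pixels) * img$pixel_size
  make_window(w, h, mask = img, id = id)
}
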