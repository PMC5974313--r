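#' Construct a rectangular analysis window with circular exclusion regions
#'
#' The analysis domain is a rectangle (in micrometres, origin at the
#' lower-left corner, x rightward, y upward) minus a set of circular
#' exclusion regions modeling white-pulp follicles. All spatial statistics
#' in the package operate on the *usable* area: the rectangle with the
#' exclusions removed.
#'
#' @param width,height rectangle dimensions in micrometres (> 0).
#' @param follicles exclusion discs: a data frame or matrix with columns
#'   `x`, `y`, `r` (centre and radius, micrometres), or a list of length-3
#'   numeric vectors. Centres must lie inside the rectangle; radii >= 0.
#'   Discs may overlap one another and may extend past the rectangle edge.
#' @param mask optional raster exclusion field: a [label_image()] whose
#'   nonzero pixels are excluded (used as a lookup field in addition to
#'   any discs); its extent must match `width` x `height`.
#' @param id optional window identifier (character), carried into results.
#' @return an object of class `spatial_window` with fields `width`,
#'   `height`, `exclusions` (data frame x, y, r) and optionally `mask`
#'   (raster exclusion field, see [read_mask()]).
#' @export
#' @examples
#' w <- make_window(150, 150, follicles = list(c(75, 75, 30)))
#' usable_area(w)
make_window <- function(width, height, follicles = list(), mask = NULL,
                        id = NULL) {
  stopifnot(is.numeric(width), is.numeric(height),
            length(width) == 1L, length(height) == 1L)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("window dimensions must be positive and finite")
  excl <- normalize_follicles(follicles)
  if (nrow(excl) > 0) {
    if (any(excl$r < 0)) stop("follicle radii must be >= 0")
    inside <- excl$x >= 0 & excl$x <= width & excl$y >= 0 & excl$y <= height
    if (!all(inside))
      stop("follicle centres must lie inside the window rectangle")
  }
  mask_field <- NULL
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "label_image"))
    px <- mask$pixel_size
    if (abs(ncol(mask$pixels) * px - width) > px / 2 ||
        abs(nrow(mask$pixels) * px - height) > px / 2)
      stop("mask raster extent does not match the window dimensions")
    if (any(mask$pixels != 0))
      mask_field <- list(excluded = mask$pixels != 0, pixel_size = px)
  }
  w <- structure(
    list(width = width, height = height, exclusions = excl,
         mask = mask_field, id = id),
    class = "spatial_window")
  if (usable_area(w) <= 0)
    stop("usable area is not positive: exclusions cover the whole window")
  w
}

normalize_follicles <- function(follicles) {
  if (is.null(follicles) || (is.list(follicles) && length(follicles) == 0L))
    return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)))
  if (is.matrix(follicles)) follicles <- as.data.frame(follicles)
  if (is.data.frame(follicles)) {
    nm <- names(follicles)
    if (!all(c("x", "y") %in% nm)) names(follicles) <- c("x", "y", "r")[seq_along(nm)]
    if (!"r" %in% names(follicles)) stop("follicles need columns x, y, r")
    excl <- follicles[, c("x", "y", "r")]
  } else if (is.list(follicles)) {
    if (!all(vapply(follicles, length, 1L) == 3L))
      stop("each follicle must be (x, y, radius)")
    m <- do.call(rbind, lapply(follicles, as.numeric))
    excl <- data.frame(x = m[, 1], y = m[, 2], r = m[, 3])
  } else if (is.numeric(follicles) && length(follicles) == 3L) {
    excl <- data.frame(x = follicles[1], y = follicles[2], r = follicles[3])
  } else stop("cannot interpret `follicles`")
  rownames(excl) <- NULL
  excl
}

#' Test whether points lie in the usable area of a window
#'
#' A point is usable when it lies inside the rectangle (boundary included)
#' and strictly outside every exclusion disc (and, for raster-masked
#' windows, on a zero pixel of the mask).
#'
#' @param window a [make_window()] object.
#' @param x,y coordinate vectors in micrometres (equal length).
#' @return logical vector.
#' @export
in_usable <- function(window, x, y) {
  stopifnot(inherits(window, "spatial_window"), length(x) == length(y))
  ok <- x >= 0 & x <= window$width & y >= 0 & y <= window$height
  excl <- window$exclusions
  if (nrow(excl) > 0) {
    for (k in seq_len(nrow(excl))) {
      if (excl$r[k] <= 0) next
      ok <- ok & ((x - excl$x[k])^2 + (y - excl$y[k])^2 >= excl$r[k]^2)
    }
  }
  if (!is.null(window$mask)) {
    px <- window$mask$pixel_size
    nr <- nrow(window$mask$excluded)
    nc <- ncol(window$mask$excluded)
    # lookup pixel containing (x, y); y axis is flipped (row 0 at the top)
    j <- pmin(pmax(floor(x / px), 0), nc - 1)
    i <- pmin(pmax(floor((window$height - y) / px), 0), nr - 1)
    ok <- ok & !window$mask$excluded[cbind(i + 1, j + 1)]
  }
  ok
}

#' Usable area of a window
#'
#' Computes the area of the rectangle minus the union of its exclusion
#' regions. `method = "grid"` integrates the excluded cross-section length
#' over x on a fine grid (exact up to discretization; overlapping discs are
#' not double-counted). `method = "mc"` estimates the area by uniform
#' Monte-Carlo sampling, which serves as an independent cross-check.
#' Raster-masked windows count non-excluded pixels instead.
#'
#' @param window a [make_window()] object.
#' @param method `"grid"` (default) or `"mc"`.
#' @param n grid resolution or Monte-Carlo sample size.
#' @param seed optional integer seed for `method = "mc"`.
#' @return area in square micrometres.
#' @export
usable_area <- function(window, method = c("grid", "mc"), n = NULL,
                        seed = NULL) {
  stopifnot(inherits(window, "spatial_window"))
  method <- match.arg(method)
  W <- window$width; H <- window$height
  if (!is.null(window$mask)) {
    # evaluate combined membership (mask + discs) at every pixel centre
    px <- window$mask$pixel_size
    nr <- nrow(window$mask$excluded); nc <- ncol(window$mask$excluded)
    xc <- (rep(seq_len(nc), each = nr) - 0.5) * px
    yc <- H - (rep(seq_len(nr), times = nc) - 0.5) * px
    return(sum(in_usable(window, xc, yc)) * px^2)
  }
  excl <- window$exclusions
  excl <- excl[excl$r > 0, , drop = FALSE]
  if (nrow(excl) == 0) return(W * H)
  if (method == "mc") {
    if (is.null(n)) n <- 1e6
    with_seed(seed, {
      x <- runif(n, 0, W); y <- runif(n, 0, H)
      W * H * mean(in_usable(window, x, y))
    })
  } else {
    if (is.null(n)) n <- 50001L
    xs <- seq(0, W, length.out = n)
    ex <- vapply(xs, function(x) excluded_cross_section(excl, x, H), 0)
    excluded <- (sum(ex) - (ex[1] + ex[n]) / 2) * (W / (n - 1))
    W * H - excluded
  }
}

# total length of the union of excluded y-intervals at abscissa x,
# clipped to [0, H]
excluded_cross_section <- function(excl, x, H) {
  dx2 <- (x - excl$x)^2
  hit <- dx2 < excl$r^2
  if (!any(hit)) return(0)
  s <- sqrt(excl$r[hit]^2 - dx2[hit])
  lo <- pmax(excl$y[hit] - s, 0)
  hi <- pmin(excl$y[hit] + s, H)
  keep <- hi > lo
  if (!any(keep)) return(0)
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] > cur_hi) {
      tot <- tot + (cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    } else cur_hi <- max(cur_hi, hi[k])
  }
  tot + (cur_hi - cur_lo)
}

#' @export
print.spatial_window <- function(x, ...) {
  cat(sprintf("spatial window: %.6g x %.6g um", x$width, x$height))
  if (!is.null(x$id)) cat(sprintf(" [%s]", x$id))
  cat("\n")
  if (!is.null(x$mask)) {
    cat(sprintf("  raster exclusion mask: %d x %d px at %.6g um/px\n",
                nrow(x$mask$excluded), ncol(x$mask$excluded),
                x$mask$pixel_size))
  } else if (nrow(x$exclusions) > 0) {
    cat(sprintf("  %d exclusion disc(s), radii %s um\n",
                nrow(x$exclusions),
                paste(signif(x$exclusions$r, 4), collapse = ", ")))
  } else cat("  no exclusions\n")
  cat(sprintf("  usable area: %.6g um^2\n", usable_area(x)))
  invisible(x)
}
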