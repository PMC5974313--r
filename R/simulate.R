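# Synthetic tissue scenes: CSR fields, perifollicular clustering bands, and
# a target population attracted to a reference population. All constrained
# uniform draws use rejection sampling against the window's usable area,
# with a hard cap of 1e6 proposals per requested point (guards degenerate
# geometry such as a fully excluded band).

MAX_REJECTIONS_PER_POINT <- 1e6

# n uniform points on the usable area; consumes the current RNG stream
sample_usable <- function(n, window) {
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0; cap <- MAX_REJECTIONS_PER_POINT * max(n, 1)
  while (length(xs) < n) {
    batch <- max(2L * (n - length(xs)), 64L)
    attempts <- attempts + batch
    if (attempts > cap)
      stop("rejection-sampling cap exceeded: usable area too small or empty")
    x <- runif(batch, 0, window$width)
    y <- runif(batch, 0, window$height)
    ok <- in_usable(window, x, y)
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Simulate complete spatial randomness (CSR) on a window
#'
#' Places exactly `n` points uniformly on the usable area of the window
#' (rectangle minus exclusion regions) by rejection sampling. This is the
#' null model for both the Hopkins clustering-tendency analysis and the
#' proximity test: a homogeneous random field with no interaction between
#' points.
#'
#' @param n number of points (>= 0).
#' @param window a [make_window()] object.
#' @param seed optional integer seed; identical `(n, window, seed)` give
#'   identical coordinates. `NULL` consumes the current RNG stream.
#' @param label population label.
#' @return a [point_pattern()] with the window attached.
#' @export
#' @examples
#' w <- make_window(150, 150)
#' p <- simulate_csr(40, w, seed = 1)
simulate_csr <- function(n, window, seed = NULL, label = "csr") {
  stopifnot(inherits(window, "spatial_window"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative count")
  n <- as.integer(n)
  xy <- with_seed(seed, sample_usable(n, window))
  point_pattern(xy[, 1], xy[, 2], label = label, window = window)
}

#' Simulate a perifollicular clustered pattern
#'
#' Generates a two-component mixture emulating cells that accumulate in the
#' annular band of red pulp around white-pulp follicles: a fraction
#' `clustered_fraction` of the points (rounded up) is uniform on the band
#' \{distance to the nearest follicle boundary <= `band_width`, outside the
#' follicle\}, the remainder is CSR on the usable area. Band points are
#' drawn by proposing from per-follicle annuli and thinning by the number
#' of annuli covering the proposal, so overlapping bands are not
#' over-weighted; proposals falling outside the window or inside any
#' exclusion are rejected.
#'
#' @param n total number of points.
#' @param window a window with at least one exclusion disc (the follicle).
#' @param band_width band width in micrometres (> 0).
#' @param clustered_fraction fraction of points in the band, in \[0, 1\].
#' @param seed optional integer seed.
#' @param label population label.
#' @return a [point_pattern()].
#' @export
simulate_perifollicular <- function(n, window, band_width = 10,
                                    clustered_fraction = 0.8, seed = NULL,
                                    label = "niche") {
  stopifnot(inherits(window, "spatial_window"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative count")
  n <- as.integer(n)
  p <- clustered_fraction
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("clustered_fraction must be in [0, 1]")
  if (!is.numeric(band_width) || band_width <= 0)
    stop("band_width must be > 0")
  foll <- window$exclusions
  if (p > 0 && nrow(foll) == 0)
    stop("window has no follicle: perifollicular simulation needs >= 1 exclusion disc")
  n_band <- as.integer(ceiling(p * n))
  n_bg <- n - n_band
  with_seed(seed, {
    bg <- sample_usable(n_bg, window)
    band <- sample_band(n_band, window, foll, band_width)
    # band first, then background: fixed order for reproducibility
    point_pattern(c(band[, 1], bg[, 1]), c(band[, 2], bg[, 2]),
                  label = label, window = window)
  })
}

sample_band <- function(n, window, foll, w) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  r_in <- foll$r
  r_out <- foll$r + w
  wts <- pi * (r_out^2 - r_in^2)
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0; cap <- MAX_REJECTIONS_PER_POINT * n
  nf <- nrow(foll)
  while (length(xs) < n) {
    batch <- max(4L * (n - length(xs)), 64L)
    attempts <- attempts + batch
    if (attempts > cap)
      stop("empty perifollicular band: no usable area within band_width of a follicle boundary")
    f <- if (nf == 1L) rep(1L, batch) else
      sample.int(nf, batch, replace = TRUE, prob = wts)
    rad <- sqrt(runif(batch, r_in[f]^2, r_out[f]^2))
    th <- runif(batch, 0, 2 * pi)
    x <- foll$x[f] + rad * cos(th)
    y <- foll$y[f] + rad * sin(th)
    # thin by multiplicity of covering annuli -> uniform on the union
    k <- integer(batch)
    for (g in seq_len(nf)) {
      d2 <- (x - foll$x[g])^2 + (y - foll$y[g])^2
      k <- k + (d2 >= r_in[g]^2 & d2 <= r_out[g]^2)
    }
    k[k < 1L] <- 1L
    ok <- (runif(batch) < 1 / k) & in_usable(window, x, y)
    xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Simulate a population attracted to a reference population
#'
#' Emulates a target population (e.g. hematopoietic stem/progenitor cells)
#' localizing near a reference population (e.g. niche cells): a fraction
#' `1 - background_fraction` of the `n` points (rounded up) is placed by
#' choosing a reference point uniformly at random and displacing it by an
#' isotropic Gaussian offset of scale `attraction_scale`, re-drawing the
#' offset until the point lands in the usable area; the remaining points
#' are CSR.
#'
#' @param reference a non-empty [point_pattern()] with a window attached
#'   (or pass `window`).
#' @param n number of target points.
#' @param attraction_scale Gaussian displacement scale sigma, micrometres
#'   (> 0).
#' @param background_fraction CSR admixture fraction b in \[0, 1\].
#' @param seed optional integer seed.
#' @param window window override; defaults to `reference$window`.
#' @param label population label.
#' @return a [point_pattern()].
#' @export
simulate_attracted <- function(reference, n, attraction_scale = 5,
                               background_fraction = 0, seed = NULL,
                               window = NULL, label = "target") {
  stopifnot(inherits(reference, "point_pattern"))
  if (is.null(window)) window <- reference$window
  stopifnot(inherits(window, "spatial_window"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative count")
  n <- as.integer(n)
  b <- background_fraction
  if (!is.numeric(b) || b < 0 || b > 1)
    stop("background_fraction must be in [0, 1]")
  if (!is.numeric(attraction_scale) || attraction_scale <= 0)
    stop("attraction_scale must be > 0")
  n_att <- as.integer(ceiling((1 - b) * n))
  n_bg <- n - n_att
  if (n_att > 0 && npoints(reference) == 0)
    stop("reference pattern is empty (required unless background_fraction = 1)")
  with_seed(seed, {
    att <- sample_attracted(n_att, reference, window, attraction_scale)
    bg <- sample_usable(n_bg, window)
    point_pattern(c(att[, 1], bg[, 1]), c(att[, 2], bg[, 2]),
                  label = label, window = window)
  })
}

sample_attracted <- function(n, reference, window, sigma) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  anchor <- sample.int(npoints(reference), n, replace = TRUE)
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  attempts <- 0; cap <- MAX_REJECTIONS_PER_POINT * n
  while (length(todo)) {
    m <- length(todo)
    attempts <- attempts + m
    if (attempts > cap)
      stop("rejection-sampling cap exceeded while displacing attracted points")
    px <- reference$x[anchor[todo]] + rnorm(m, 0, sigma)
    py <- reference$y[anchor[todo]] + rnorm(m, 0, sigma)
    ok <- in_usable(window, px, py)
    x[todo[ok]] <- px[ok]; y[todo[ok]] <- py[ok]
    todo <- todo[!ok]
  }
  cbind(x = x, y = y)
}

#' Density-matched random points
#'
#' The Monte-Carlo null of the proximity analysis: a CSR pattern with
#' exactly the same number of points as `template`, on the same usable
#' area. Observed localizations are compared against such randomly
#' distributed points of equal density.
#'
#' @param template the observed [point_pattern()] whose count is matched.
#' @param window window; defaults to `template$window`.
#' @param seed optional integer seed.
#' @return a [point_pattern()] labeled `"random"`.
#' @export
simulate_equal_density_random <- function(template, window = NULL,
                                          seed = NULL) {
  stopifnot(inherits(template, "point_pattern"))
  if (is.null(window)) window <- template$window
  simulate_csr(npoints(template), window, seed = seed, label = "random")
}

#' Generate a complete synthetic tissue scene
#'
#' Builds a window with follicle exclusions, a niche population with
#' perifollicular clustering, and a target population attracted to the
#' niche — a ground-truth stand-in for a stained tissue section. Each
#' population draws from its own RNG sub-stream derived from the scene
#' seed (see [derive_seed()]; niche = offset 1, target = offset 2), so
#' changing one population's size never perturbs the other's coordinates.
#'
#' @param window a [make_window()] object.
#' @param n_niche,n_target population sizes.
#' @param clustered_fraction fraction of niche points in the
#'   perifollicular band (0 gives CSR niche cells).
#' @param band_width perifollicular band width, micrometres.
#' @param attraction_scale target displacement scale sigma, micrometres.
#' @param background_fraction CSR admixture among target points.
#' @param seed integer scene seed (required: scenes are reproducible).
#' @return an object of class `synthetic_scene` with fields `window`,
#'   `niche`, `target`, `params`.
#' @export
#' @examples
#' w <- make_window(150, 150, follicles = list(c(75, 75, 40)))
#' sc <- simulate_scene(w, n_niche = 120, n_target = 40, seed = 7)
simulate_scene <- function(window, n_niche = 120, n_target = 40,
                           clustered_fraction = 0.8, band_width = 10,
                           attraction_scale = 5, background_fraction = 0,
                           seed) {
  stopifnot(inherits(window, "spatial_window"))
  if (missing(seed) || !is.numeric(seed))
    stop("simulate_scene requires an integer `seed`")
  seed <- as.integer(seed)
  niche <- if (clustered_fraction > 0) {
    simulate_perifollicular(n_niche, window, band_width = band_width,
                            clustered_fraction = clustered_fraction,
                            seed = derive_seed(seed, 1L), label = "niche")
  } else {
    simulate_csr(n_niche, window, seed = derive_seed(seed, 1L),
                 label = "niche")
  }
  target <- simulate_attracted(niche, n_target,
                               attraction_scale = attraction_scale,
                               background_fraction = background_fraction,
                               seed = derive_seed(seed, 2L),
                               label = "target")
  params <- list(n_niche = n_niche, n_target = n_target,
                 clustered_fraction = clustered_fraction,
                 band_width = band_width,
                 attraction_scale = attraction_scale,
                 background_fraction = background_fraction, seed = seed)
  structure(list(window = window, niche = niche, target = target,
                 params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("synthetic tissue scene\n")
  cat(sprintf("  window: %.6g x %.6g um, %d follicle(s)\n",
              x$window$width, x$window$height, nrow(x$window$exclusions)))
  cat(sprintf("  niche: %d points (clustered fraction %.2f, band %.4g um)\n",
              npoints(x$niche), x$params$clustered_fraction,
              x$params$band_width))
  cat(sprintf("  target: %d points (sigma %.4g um, background %.2f)\n",
              npoints(x$target), x$params$attraction_scale,
              x$params$background_fraction))
  cat(sprintf("  seed: %d\n", x$params$seed))
  invisible(x)
}

#' Write / read a scene configuration
#'
#' Scene parameters (window geometry, follicle discs, population sizes,
#' mixture fractions, seed) serialize to a flat YAML mapping, so a scene
#' can be regenerated exactly from its config.
#'
#' @param scene a [simulate_scene()] object (or a parameter list with a
#'   `window` entry).
#' @param path output YAML path.
#' @return `write_scene_config`: invisibly, the path;
#'   `read_scene_config`: a parameter list suitable for
#'   [simulate_scene_from_config()].
#' @export
write_scene_config <- function(scene, path) {
  if (inherits(scene, "synthetic_scene")) {
    cfg <- scene$params
    cfg$width <- scene$window$width
    cfg$height <- scene$window$height
    ex <- scene$window$exclusions
    cfg$follicles <- if (nrow(ex)) apply(ex, 1, as.list) else list()
  } else cfg <- scene
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  read_config_yaml(path)
}

# YAML 1.1 resolves bare keys `y`/`n` to booleans; our configs use them as
# coordinate and count keys, so map the resolved names back recursively.
read_config_yaml <- function(path) {
  fix <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (!is.null(nm)) {
      nm[nm == "TRUE"] <- "y"
      nm[nm == "FALSE"] <- "n"
      names(x) <- nm
    }
    lapply(x, fix)
  }
  fix(yaml::read_yaml(path))
}

#' @rdname write_scene_config
#' @export
simulate_scene_from_config <- function(path) {
  cfg <- if (is.character(path)) read_scene_config(path) else path
  need <- c("width", "height", "seed")
  if (!all(need %in% names(cfg)))
    stop("scene config must define: ", paste(need, collapse = ", "))
  foll <- cfg$follicles
  if (!is.null(foll) && length(foll))
    foll <- lapply(foll, function(f) as.numeric(unlist(f)[c("x", "y", "r")]))
  else foll <- list()
  w <- make_window(cfg$width, cfg$height, follicles = foll)
  defaults <- formals(simulate_scene)
  g <- function(nm) if (!is.null(cfg[[nm]])) cfg[[nm]] else eval(defaults[[nm]])
  simulate_scene(w,
                 n_niche = g("n_niche"), n_target = g("n_target"),
                 clustered_fraction = g("clustered_fraction"),
                 band_width = g("band_width"),
                 attraction_scale = g("attraction_scale"),
                 background_fraction = g("background_fraction"),
                 seed = cfg$seed)
}
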