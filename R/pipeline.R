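# Orchestration: tile a section into analysis windows, run the
# simulate -> Hopkins -> proximity chain from a config, and write
# machine-readable reports.

new_window_unchecked <- function(width, height, excl, id = NULL) {
  structure(list(width = width, height = height, exclusions = excl,
                 mask = NULL, id = id),
            class = "spatial_window")
}

#' Tile a section into square analysis windows
#'
#' Splits a rectangular section into a non-overlapping grid of square
#' tiles of side `window_size` (partial tiles at the far edges are
#' dropped) and, when a pattern is supplied, keeps only tiles containing
#' at least `min_points` pattern points in their usable area. A point at
#' coordinate v belongs to the tile of index `floor(v / window_size)`;
#' points exactly on the far edge of the tiled region are assigned to the
#' last tile.
#'
#' @param section a [make_window()] describing the whole section
#'   (exclusions are inherited by the tiles).
#' @param window_size tile side in micrometres (<= both section
#'   dimensions).
#' @param pattern optional [point_pattern()] used for the density filter.
#' @param min_points minimum points per retained tile (default 1 when a
#'   pattern is given, 0 otherwise).
#' @return a list of tiles; each tile is a list with `ix`, `iy` (grid
#'   indices, 0-based), `x0`, `y0` (lower-left corner in section
#'   coordinates), `window` (a `spatial_window` in tile coordinates,
#'   exclusion discs shifted and filtered to those intersecting the tile)
#'   and `n_points`.
#' @seealso [clip_pattern()] to express a pattern in tile coordinates.
#' @export
#' @examples
#' sec <- make_window(600, 600)
#' length(tile_windows(sec, 150))  # 16
tile_windows <- function(section, window_size, pattern = NULL,
                         min_points = if (is.null(pattern)) 0L else 1L) {
  stopifnot(inherits(section, "spatial_window"),
            is.numeric(window_size), window_size > 0)
  if (window_size > section$width || window_size > section$height)
    stop("window_size exceeds the section extent")
  nx <- as.integer(floor(section$width / window_size))
  ny <- as.integer(floor(section$height / window_size))
  s <- window_size
  has_pat <- !is.null(pattern) && npoints(pattern) > 0
  if (has_pat) {
    px_idx <- tile_index(pattern$x, s, nx)
    py_idx <- tile_index(pattern$y, s, ny)
    usable <- in_usable(section, pattern$x, pattern$y)
  }
  tiles <- list()
  for (iy in seq_len(ny) - 1L) {
    for (ix in seq_len(nx) - 1L) {
      x0 <- ix * s; y0 <- iy * s
      ex <- section$exclusions
      if (nrow(ex)) {
        # keep discs whose circle intersects the tile square
        cx <- pmin(pmax(ex$x, x0), x0 + s)
        cy <- pmin(pmax(ex$y, y0), y0 + s)
        hit <- (cx - ex$x)^2 + (cy - ex$y)^2 < ex$r^2
        ex <- ex[hit, , drop = FALSE]
        ex$x <- ex$x - x0
        ex$y <- ex$y - y0
      }
      tw <- new_window_unchecked(s, s, ex,
                                 id = sprintf("tile_%d_%d", ix, iy))
      if (usable_area(tw) <= 0) next
      n_pts <- if (has_pat) sum(px_idx == ix & py_idx == iy & usable) else 0L
      if (n_pts < min_points) next
      tiles[[length(tiles) + 1L]] <-
        list(ix = ix, iy = iy, x0 = x0, y0 = y0, window = tw,
             n_points = as.integer(n_pts))
    }
  }
  tiles
}

tile_index <- function(v, s, k) pmin(floor(v / s), k - 1L)

#' Clip a point pattern to a tile
#'
#' Selects the pattern points belonging to a tile (same membership rule as
#' [tile_windows()]) and shifts them into tile coordinates.
#'
#' @param pattern a [point_pattern()] in section coordinates.
#' @param tile one element of [tile_windows()]'s result.
#' @param nx,ny grid dimensions of the tiling; inferred from the section
#'   when it is supplied instead.
#' @param section optional parent [make_window()]; when given, points
#'   outside its usable area are dropped too and `nx`/`ny` are derived.
#' @return a [point_pattern()] in tile coordinates with the tile window
#'   attached.
#' @export
clip_pattern <- function(pattern, tile, section = NULL, nx = NULL,
                         ny = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  s <- tile$window$width
  if (!is.null(section)) {
    nx <- as.integer(floor(section$width / s))
    ny <- as.integer(floor(section$height / s))
  }
  if (is.null(nx)) nx <- tile$ix + 1L
  if (is.null(ny)) ny <- tile$iy + 1L
  keep <- tile_index(pattern$x, s, max(nx, tile$ix + 1L)) == tile$ix &
          tile_index(pattern$y, s, max(ny, tile$iy + 1L)) == tile$iy
  if (!is.null(section))
    keep <- keep & in_usable(section, pattern$x, pattern$y)
  point_pattern(pattern$x[keep] - tile$x0, pattern$y[keep] - tile$y0,
                label = pattern$label, window = tile$window)
}

#' Run the full simulate-analyze-report pipeline
#'
#' Executes, deterministically for a given config + seed, the chain:
#' generate (or load) point patterns per analysis window, run the
#' resampled Hopkins protocol on the niche population of every window
#' against a shared CSR envelope, run the proximity test of the target
#' population against the niche, and aggregate per-window results
#' (optionally across two experimental groups with a Student's t
#' comparison).
#'
#' The config is a nested list (or path to a YAML file) with entries:
#' \describe{
#'   \item{seed}{integer; every random stage derives a sub-seed from it.}
#'   \item{window}{`width`, `height`, optional `follicles` (list of
#'     `x`/`y`/`r` mappings).}
#'   \item{niche}{either `file` (coordinate CSV) or simulation parameters
#'     `n`, `clustered_fraction`, `band_width`.}
#'   \item{target}{either `file` or `n`, `attraction_scale`,
#'     `background_fraction`; omit for a Hopkins-only run.}
#'   \item{n_windows}{replicate scenes per group (synthetic runs only;
#'     default 1).}
#'   \item{hopkins}{`m`, `reps`, `variant`, `envelope_sims` (0 disables
#'     the envelope).}
#'   \item{proximity}{`n_null`, `mode`, `pixel_size`.}
#'   \item{groups}{optional named list of per-group overrides of
#'     `niche`/`target`; with exactly two groups a t test on per-window
#'     Hopkins means is added.}
#' }
#'
#' @param config nested list or YAML file path.
#' @param out optional path; when given the report is written as JSON
#'   ([write_report()]) and a plain-text summary next to it.
#' @return an object of class `analysis_report` (nested list; see
#'   [write_report()]).
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- read_config_yaml(config)
  if (is.null(config$seed)) stop("config error: `seed` is required")
  seed <- as.integer(config$seed)
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  wcfg <- config$window
  if (is.null(wcfg$width) || is.null(wcfg$height))
    stop("config error: window.width and window.height are required")
  foll <- wcfg$follicles
  foll <- if (is.null(foll) || !length(foll)) list() else
    lapply(foll, function(f) as.numeric(unlist(f)[c("x", "y", "r")]))
  window <- make_window(wcfg$width, wcfg$height, follicles = foll)

  hcfg <- config$hopkins
  h_m <- hcfg$m %||% 40L
  h_reps <- hcfg$reps %||% 1000L
  h_var <- hcfg$variant %||% "plain"
  h_sims <- hcfg$envelope_sims %||% 100L
  pcfg <- config$proximity
  p_nnull <- pcfg$n_null %||% 999L
  p_mode <- pcfg$mode %||% "point_nn"
  p_px <- pcfg$pixel_size %||% 1
  n_windows <- config$n_windows %||% 1L

  groups <- config$groups
  if (is.null(groups)) groups <- list(all = list())

  run_group <- function(gname, gcfg, goff) {
    ncfg <- modifyList(config$niche %||% list(), gcfg$niche %||% list())
    tcfg <- modifyList(config$target %||% list(), gcfg$target %||% list())
    windows_out <- list()
    h_means <- numeric(0)
    for (wi in seq_len(n_windows)) {
      sseed <- derive_seed(seed, goff * 1000L + wi)
      note("group %s window %d: scene seed %d", gname, wi, sseed)
      if (!is.null(ncfg$file)) {
        niche <- read_points(ncfg$file, label = "niche", window = window)
      } else {
        nn <- ncfg$n %||% 120L
        cf <- ncfg$clustered_fraction %||% 0
        niche <- if (cf > 0) {
          simulate_perifollicular(nn, window,
                                  band_width = ncfg$band_width %||% 10,
                                  clustered_fraction = cf,
                                  seed = derive_seed(sseed, 1L))
        } else simulate_csr(nn, window, seed = derive_seed(sseed, 1L),
                            label = "niche")
      }
      target <- NULL
      if (!is.null(tcfg$file)) {
        target <- read_points(tcfg$file, label = "target", window = window)
      } else if (!is.null(tcfg$n)) {
        target <- simulate_attracted(
          niche, tcfg$n,
          attraction_scale = tcfg$attraction_scale %||% 5,
          background_fraction = tcfg$background_fraction %||% 0,
          seed = derive_seed(sseed, 2L), window = window)
      }
      if (npoints(niche) < 2)
        stop("data error: window ", wi, " of group ", gname,
             " has < 2 niche points")
      hseed <- derive_seed(sseed, 3L)
      hop <- hopkins_resampled(niche, window, m = h_m, reps = h_reps,
                               variant = h_var, seed = hseed)
      h_means <- c(h_means, hop$mean)
      wrec <- list(window = wi,
                   n_niche = npoints(niche),
                   hopkins = list(mean = hop$mean, sd = hop$sd,
                                  m = hop$config$m, reps = hop$config$reps,
                                  per_rep = hop$per_rep))
      if (!is.null(target)) {
        prox <- proximity_test(target, niche, window, n_null = p_nnull,
                               seed = derive_seed(sseed, 4L),
                               mode = p_mode, pixel_size = p_px)
        wrec$n_target <- npoints(target)
        wrec$proximity <- list(
          observed_mean = prox$observed_mean,
          observed_sd = prox$observed_sd,
          null_mean = mean(prox$null_means),
          null_sd = sd(prox$null_means),
          p_value = prox$p_value, n_null = prox$n_null, mode = prox$mode,
          observed_distances = prox$observed_distances,
          null_means = prox$null_means)
      }
      windows_out[[wi]] <- wrec
    }
    list(windows = windows_out,
         hopkins_mean = mean(h_means),
         hopkins_sd = if (length(h_means) > 1) sd(h_means) else NA_real_,
         window_means = h_means)
  }

  group_res <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    group_res[[gname]] <- run_group(gname, groups[[gi]], gi)
  }

  envelope <- NULL
  if (h_sims >= 20) {
    env_n <- hcfg$envelope_n %||%
      (config$niche$n %||% group_res[[1]]$windows[[1]]$n_niche)
    eseed <- derive_seed(seed, 7L)
    note("CSR envelope: n %d, %d sims, seed %d", env_n, h_sims, eseed)
    env <- csr_envelope(env_n, window, m = h_m, reps = h_reps,
                        variant = h_var, sims = h_sims, seed = eseed)
    envelope <- list(lo = env$lo, hi = env$hi, sims = env$sims, n = env$n,
                     null_means = env$null_means)
    for (gname in names(group_res)) {
      group_res[[gname]]$classification <- vapply(
        group_res[[gname]]$window_means,
        function(hm) classify_hopkins(hm, env), "")
    }
  }

  comparison <- NULL
  if (length(group_res) == 2 &&
      all(vapply(group_res, function(g) length(g$window_means), 0L) >= 2)) {
    gs <- hopkins_group_summary(lapply(group_res, `[[`, "window_means"))
    comparison <- list(groups = gs$groups, t = gs$t, df = gs$df,
                       p_value = gs$p_value)
  }

  report <- structure(list(
    meta = list(package = "nichespat",
                version = as.character(utils::packageVersion("nichespat")),
                seed = seed,
                config = config),
    window = list(width = window$width, height = window$height,
                  n_follicles = nrow(window$exclusions),
                  usable_area = usable_area(window)),
    envelope = envelope,
    groups = group_res,
    comparison = comparison,
    log = log), class = "analysis_report")
  if (!is.null(out)) {
    write_report(report, out)
    writeLines(utils::capture.output(print(report)),
               paste0(tools::file_path_sans_ext(out), ".txt"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as JSON
#'
#' Serializes a [run_pipeline()] report with fixed key order and 12
#' significant digits, so reruns of an identical config produce
#' byte-identical files.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(12), pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("nichespat analysis report\n")
  cat(sprintf("  seed %d; window %.6g x %.6g um, %d follicle(s)\n",
              x$meta$seed, x$window$width, x$window$height,
              x$window$n_follicles))
  if (!is.null(x$envelope))
    cat(sprintf("  CSR envelope of mean H: [%.4f, %.4f] (%d sims, n = %d)\n",
                x$envelope$lo, x$envelope$hi, x$envelope$sims,
                x$envelope$n))
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    cat(sprintf("  group %s: Hopkins %.2f +/- %.2f over %d window(s)",
                gname, g$hopkins_mean,
                if (is.na(g$hopkins_sd)) 0 else g$hopkins_sd,
                length(g$windows)))
    if (!is.null(g$classification))
      cat(sprintf(" [%s]", paste(g$classification, collapse = ", ")))
    cat("\n")
    for (w in g$windows) {
      if (!is.null(w$proximity))
        cat(sprintf(
          "    window %d proximity: observed %.2f um vs random %.2f um, p = %.4g\n",
          w$window, w$proximity$observed_mean, w$proximity$null_mean,
          w$proximity$p_value))
    }
  }
  if (!is.null(x$comparison))
    cat(sprintf("  group comparison: t = %.3f, p = %.4g\n",
                x$comparison$t, x$comparison$p_value))
  invisible(x)
}
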