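#' Hopkins clustering-tendency statistic for one subsample
#'
#' Compares distances from random sampling origins to the data against
#' nearest-neighbor distances within the data. `m` sampling origins are
#' drawn uniformly on the usable area of the window (origins never fall in
#' exclusion regions, which would inflate the origin distances) and `m`
#' data points are sampled without replacement from the pattern. With
#' `u_i` the distance from origin i to its nearest pattern point and `w_i`
#' the distance from sampled data point i to its nearest *other* pattern
#' point,
#' \deqn{h = \frac{\sum u_i^k}{\sum u_i^k + \sum w_i^k}}
#' with exponent k = 1 (`variant = "plain"`, the default) or k = 2
#' (`variant = "powered"`, the dimension-d form for d = 2). Under complete
#' spatial randomness h concentrates near 0.5; h > 0.5 indicates
#' clustering, h < 0.5 regularity. If both sums are zero h is undefined
#' and 0.5 is returned.
#'
#' For deterministic verification, `origins` (an m x 2 matrix) and
#' `data_idx` (m indices into the pattern) may be injected instead of
#' being drawn.
#'
#' @param pattern a [point_pattern()] with >= 2 points.
#' @param window a [make_window()] object; defaults to `pattern$window`.
#' @param m subset size (1 <= m <= number of points).
#' @param variant `"plain"` (k = 1) or `"powered"` (k = 2).
#' @param origins,data_idx optional injected sampling origins / data
#'   subsample (both must be given together).
#' @param seed optional integer seed.
#' @return a single Hopkins value in \[0, 1\].
#' @seealso [hopkins_resampled()] for the repeated-subsample protocol.
#' @export
hopkins_statistic <- function(pattern, window = NULL, m = 40,
                              variant = c("plain", "powered"),
                              origins = NULL, data_idx = NULL, seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  variant <- match.arg(variant)
  if (is.null(window)) window <- pattern$window
  stopifnot(inherits(window, "spatial_window"))
  n <- npoints(pattern)
  if (n < 2) stop("Hopkins statistic needs >= 2 pattern points")
  if (m < 1 || m > n) stop("need 1 <= m <= number of pattern points")
  m <- as.integer(m)
  if (xor(is.null(origins), is.null(data_idx)))
    stop("inject both `origins` and `data_idx`, or neither")
  with_seed(seed, {
    if (is.null(origins)) {
      origins <- sample_usable(m, window)
      data_idx <- sample.int(n, m, replace = FALSE)
    } else {
      origins <- as.matrix(origins)
      stopifnot(nrow(origins) == m, ncol(origins) == 2,
                length(data_idx) == m)
    }
    u <- nncross_cpp(origins[, 1], origins[, 2], pattern$x, pattern$y)
    w <- nnself_cpp(pattern$x, pattern$y)[data_idx]
    hopkins_from_uw(u, w, variant)
  })
}

hopkins_from_uw <- function(u, w, variant) {
  k <- if (variant == "powered") 2 else 1
  su <- sum(u^k); sw <- sum(w^k)
  if (su + sw == 0) return(0.5)
  su / (su + sw)
}

#' Resampled Hopkins protocol for one window
#'
#' Repeats [hopkins_statistic()] `reps` times on a window, drawing fresh
#' sampling origins *and* a fresh data subsample of size `m` at every
#' repetition, and summarizes the per-repetition values. The defaults
#' (`m = 40`, `reps = 1000`) correspond to analyzing random subsets of 40
#' localizations 1000 times within a 150 x 150 um window. When the
#' pattern holds fewer than `m` points, `m` is reduced to the pattern
#' count with a warning rather than failing, since real sections vary in
#' density.
#'
#' @param pattern a [point_pattern()].
#' @param window window; defaults to `pattern$window`.
#' @param m subset size per repetition (default 40).
#' @param reps number of repetitions R (default 1000).
#' @param variant distance exponent, see [hopkins_statistic()].
#' @param seed optional integer seed.
#' @return an object of class `hopkins_result`: list with `per_rep`
#'   (numeric, length `reps`), `mean`, `sd` (SD of per-repetition values),
#'   `config` (m, reps, variant, seed) and `window_id`.
#' @export
#' @examples
#' w <- make_window(150, 150)
#' p <- simulate_csr(200, w, seed = 1)
#' hopkins_resampled(p, m = 40, reps = 100, seed = 2)
hopkins_resampled <- function(pattern, window = NULL, m = 40, reps = 1000,
                              variant = c("plain", "powered"), seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  variant <- match.arg(variant)
  if (is.null(window)) window <- pattern$window
  stopifnot(inherits(window, "spatial_window"))
  n <- npoints(pattern)
  if (n < 2) stop("Hopkins analysis needs >= 2 pattern points")
  if (reps < 1) stop("reps must be >= 1")
  reps <- as.integer(reps)
  if (m > n) {
    warning(sprintf("pattern has %d points < m = %d; reducing m to %d",
                    n, m, n))
    m <- n
  }
  m <- as.integer(m)
  per_rep <- with_seed(seed, {
    # nearest-other distances never change across repetitions
    w_all <- nnself_cpp(pattern$x, pattern$y)
    origins <- sample_usable(m * reps, window)
    idx <- vapply(seq_len(reps), function(r) sample.int(n, m),
                  integer(m))
    u <- matrix(nncross_cpp(origins[, 1], origins[, 2],
                            pattern$x, pattern$y),
                nrow = m, ncol = reps)
    k <- if (variant == "powered") 2 else 1
    su <- .colSums(u^k, m, reps)
    sw <- .colSums(matrix(w_all[idx]^k, m, reps), m, reps)
    h <- su / (su + sw)
    h[su + sw == 0] <- 0.5
    h
  })
  structure(list(per_rep = per_rep, mean = mean(per_rep), sd = sd(per_rep),
                 config = list(m = m, reps = reps, variant = variant,
                               seed = seed),
                 window_id = window$id),
            class = "hopkins_result")
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf(
    "Hopkins analysis (m = %d, R = %d, %s variant)%s\n",
    x$config$m, x$config$reps, x$config$variant,
    if (is.null(x$window_id)) "" else paste0(" [", x$window_id, "]")))
  cat(sprintf("  mean H = %.4f (SD of repetitions %.4f)\n", x$mean, x$sd))
  cat("  H > 0.5: clustered; H ~ 0.5: random; H < 0.5: regular\n")
  invisible(x)
}

#' Monte-Carlo CSR envelope for the resampled Hopkins mean
#'
#' Simulates `sims` CSR patterns of size `n` on the window, runs the
#' resampled Hopkins protocol on each, and returns the 2.5% / 97.5%
#' quantiles of the null distribution of mean H. An observed mean above
#' `hi` is flagged clustered, below `lo` regular.
#'
#' @param n points per CSR pattern (matched to the observed density).
#' @param window a [make_window()] object.
#' @param m,reps,variant protocol parameters, see [hopkins_resampled()].
#' @param sims number of CSR simulations (>= 20).
#' @param seed optional integer seed (sub-seeds derived per simulation).
#' @param probs envelope quantiles (default `c(0.025, 0.975)`).
#' @return an object of class `csr_envelope`: list with `lo`, `hi`,
#'   `null_means` and the protocol parameters.
#' @export
csr_envelope <- function(n, window, m = 40, reps = 1000,
                         variant = c("plain", "powered"), sims = 200,
                         seed = NULL, probs = c(0.025, 0.975)) {
  variant <- match.arg(variant)
  if (sims < 20) stop("need sims >= 20 for a quantile envelope")
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  null_means <- vapply(seq_len(sims), function(s) {
    s_pat <- if (is.null(base_seed)) NULL else derive_seed(base_seed, 2L * s)
    s_hop <- if (is.null(base_seed)) NULL else derive_seed(base_seed, 2L * s + 1L)
    p <- simulate_csr(n, window, seed = s_pat)
    hopkins_resampled(p, window, m = m, reps = reps, variant = variant,
                      seed = s_hop)$mean
  }, 0)
  q <- quantile(null_means, probs, names = FALSE, type = 7)
  structure(list(lo = q[1], hi = q[2], null_means = null_means,
                 n = n, m = m, reps = reps, variant = variant,
                 sims = sims, probs = probs),
            class = "csr_envelope")
}

#' @export
print.csr_envelope <- function(x, ...) {
  cat(sprintf("CSR envelope for mean Hopkins (n = %d, m = %d, R = %d, %d sims)\n",
              x$n, x$m, x$reps, x$sims))
  cat(sprintf("  [%.1f%%, %.1f%%] envelope: [%.4f, %.4f]\n",
              100 * x$probs[1], 100 * x$probs[2], x$lo, x$hi))
  invisible(x)
}

#' Classify an observed Hopkins mean against a CSR envelope
#'
#' @param observed an observed mean H (or a `hopkins_result`).
#' @param envelope a [csr_envelope()].
#' @return `"clustered"`, `"random"` or `"regular"`.
#' @export
classify_hopkins <- function(observed, envelope) {
  stopifnot(inherits(envelope, "csr_envelope"))
  if (inherits(observed, "hopkins_result")) observed <- observed$mean
  if (observed > envelope$hi) "clustered"
  else if (observed < envelope$lo) "regular"
  else "random"
}

#' Group summary and two-sample comparison of per-window Hopkins means
#'
#' Aggregates per-window mean Hopkins values by experimental group
#' (reported as mean +/- SD across windows, the convention of figure
#' legends) and, for exactly two groups, compares them with a two-tailed
#' Student's t test (pooled variance by default; set `welch = TRUE` for
#' the unequal-variance form).
#'
#' @param results_by_group named list mapping group name to a list of
#'   `hopkins_result` objects (or a numeric vector of window means).
#' @param welch use Welch's t instead of pooled Student's t.
#' @return an object of class `hopkins_group_summary`: list with `groups`
#'   (data frame: group, n_windows, mean, sd), `t`, `df`, `p_value`.
#' @export
#' @examples
#' hopkins_group_summary(list(tg = c(0.59, 0.62, 0.56),
#'                            ctr = c(0.50, 0.49, 0.51)))
hopkins_group_summary <- function(results_by_group, welch = FALSE) {
  if (!is.list(results_by_group) || is.null(names(results_by_group)) ||
      any(names(results_by_group) == ""))
    stop("results_by_group must be a named list of groups")
  vals <- lapply(results_by_group, function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(r) {
      if (inherits(r, "hopkins_result")) r$mean
      else if (is.numeric(r) && length(r) == 1L) r
      else stop("group elements must be hopkins_result objects or numbers")
    }, 0)
  })
  if (length(vals) < 2) stop("need >= 2 groups")
  if (any(lengths(vals) == 0)) stop("empty group")
  groups <- data.frame(
    group = names(vals),
    n_windows = lengths(vals),
    mean = vapply(vals, mean, 0),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else NA_real_, 0),
    row.names = NULL)
  tt <- NULL
  if (length(vals) == 2) {
    if (any(lengths(vals) < 2))
      stop("two-sample comparison needs >= 2 windows per group")
    tt <- t.test(vals[[1]], vals[[2]], var.equal = !welch)
  } else warning("more than 2 groups: summaries only, no t test")
  structure(list(groups = groups,
                 t = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
                 df = if (!is.null(tt)) unname(tt$parameter) else NA_real_,
                 p_value = if (!is.null(tt)) tt$p.value else NA_real_,
                 welch = welch),
            class = "hopkins_group_summary")
}

#' @export
print.hopkins_group_summary <- function(x, ...) {
  cat("Hopkins group summary (per-window means)\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s: %.2f +/- %.2f (n = %d windows)\n",
                g$group, g$mean, g$sd, g$n_windows))
  }
  if (!is.na(x$t))
    cat(sprintf("  %s t = %.3f, df = %.4g, two-tailed p = %.4g\n",
                if (x$welch) "Welch" else "Student's", x$t, x$df, x$p_value))
  invisible(x)
}
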