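test_that("CSR simulation respects count, containment and seed", {
  w <- follicle_window()
  expect_equal(npoints(simulate_csr(0, w, seed = 1)), 0)
  expect_error(simulate_csr(-1, w), "non-negative")

  p <- simulate_csr(500, w, seed = 42)
  expect_equal(npoints(p), 500)
  expect_true(all(in_usable(w, p$x, p$y)))          # containment, exact
  expect_equal(sum((p$x - 75)^2 + (p$y - 75)^2 < 40^2), 0)

  p2 <- simulate_csr(500, w, seed = 42)
  expect_identical(p$x, p2$x)                        # seed determinism
  expect_identical(p$y, p2$y)
  p3 <- simulate_csr(500, w, seed = 43)
  expect_false(identical(p$x, p3$x))
})

test_that("CSR point counts follow the usable-area measure", {
  # one exclusion disc of ~20% window area; quadrant counts must match
  # each quadrant's usable-area share within binomial error
  r <- sqrt(0.2 * 150^2 / pi)
  w <- make_window(150, 150, follicles = list(c(50, 50, r)))
  n <- 4000
  p <- simulate_csr(n, w, seed = 7)
  quad <- 1 + (p$x > 75) + 2 * (p$y > 75)
  share <- vapply(1:4, function(q) {
    qw <- list(c(0, 0), c(75, 0), c(0, 75), c(75, 75))[[q]]
    xs <- runif(2e5, qw[1], qw[1] + 75)
    ys <- runif(2e5, qw[2], qw[2] + 75)
    mean(in_usable(w, xs, ys)) * 75^2
  }, 0)
  share <- share / sum(share)
  for (q in 1:4) {
    se <- sqrt(share[q] * (1 - share[q]) / n)
    expect_lt(abs(mean(quad == q) - share[q]), 5 * se)
  }
})

test_that("CSR is uniform: chi-square on an equal-area binning", {
  w <- plain_window()
  n_seeds <- 100
  pvals <- vapply(seq_len(n_seeds), function(s) {
    p <- simulate_csr(10000, w, seed = 1000 + s)
    bx <- cut(p$x, breaks = seq(0, 150, length.out = 6))
    by <- cut(p$y, breaks = seq(0, 150, length.out = 6))
    suppressWarnings(stats::chisq.test(table(bx, by))$p.value)
  }, 0)
  expect_gte(sum(pvals > 0.01), 98)
})

test_that("perifollicular band points lie within band_width of a boundary", {
  w <- follicle_window()
  p <- simulate_perifollicular(200, w, band_width = 10,
                               clustered_fraction = 1, seed = 5)
  d_boundary <- abs(sqrt((p$x - 75)^2 + (p$y - 75)^2) - 40)
  expect_true(all(d_boundary <= 10))
  expect_true(all(in_usable(w, p$x, p$y)))
})

test_that("perifollicular mixture honors the clustered fraction", {
  w <- follicle_window()
  p <- simulate_perifollicular(100, w, band_width = 10,
                               clustered_fraction = 0.73, seed = 9)
  expect_equal(npoints(p), 100)
  # ceil(0.73 * 100) = 73 band points, generated first
  d <- abs(sqrt((p$x - 75)^2 + (p$y - 75)^2) - 40)
  expect_true(all(d[1:73] <= 10))
})

test_that("degenerate fractions reduce to CSR exactly under a shared seed", {
  w <- follicle_window()
  ref <- simulate_csr(150, w, seed = 77)
  p0 <- simulate_perifollicular(150, w, band_width = 10,
                                clustered_fraction = 0, seed = 77)
  expect_identical(p0$x, ref$x)
  expect_identical(p0$y, ref$y)

  niche <- simulate_csr(30, w, seed = 3)
  b1 <- simulate_attracted(niche, 150, attraction_scale = 5,
                           background_fraction = 1, seed = 77)
  expect_identical(b1$x, ref$x)
  expect_identical(b1$y, ref$y)
})

test_that("perifollicular simulation rejects degenerate geometry", {
  w <- plain_window()  # no follicle
  expect_error(simulate_perifollicular(10, w, clustered_fraction = 0.5),
               "no follicle")
  # a raster mask swallowing the whole band -> rejection cap must trip
  ii <- matrix(rep(1:150, times = 150), 150)
  jj <- matrix(rep(1:150, each = 150), 150)
  d <- sqrt((jj - 0.5 - 75)^2 + (150 - ii + 0.5 - 75)^2)
  ring <- (d >= 29 & d <= 37) * 1L
  w2 <- make_window(150, 150, follicles = list(c(75, 75, 30)),
                    mask = label_image(ring, 1))
  expect_error(
    simulate_perifollicular(1, w2, band_width = 5, clustered_fraction = 1,
                            seed = 1),
    "band")
})

test_that("attracted points hug the reference at vanishing displacement", {
  w <- plain_window()
  ref <- simulate_csr(300, w, seed = 21)
  targ <- simulate_attracted(ref, 100, attraction_scale = 0.01,
                             background_fraction = 0, seed = 22)
  expect_lt(mean(nearest_distances(targ, ref)), 0.1)
  expect_true(all(in_usable(w, targ$x, targ$y)))
  expect_error(simulate_attracted(point_pattern(), 10, window = w),
               "empty")
})

test_that("attracted targets beat the equal-density null in nearly all scenes", {
  w <- make_window(600, 600)
  hits <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    ref <- simulate_csr(100, w, seed = derive_seed(500, 2 * s))
    targ <- simulate_attracted(ref, 50, attraction_scale = 5,
                               background_fraction = 0,
                               seed = derive_seed(500, 2 * s + 1))
    nullp <- simulate_equal_density_random(targ, w,
                                           seed = derive_seed(501, s))
    obs <- mean(nearest_distances(targ, ref))
    nul <- mean(nearest_distances(nullp, ref))
    if (obs < nul) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("equal-density null matches the template count and seed contract", {
  w <- follicle_window()
  tmpl <- simulate_csr(93, w, seed = 2)
  r1 <- simulate_equal_density_random(tmpl, seed = 10)
  expect_equal(npoints(r1), 93)
  expect_identical(r1$label, "random")
  r2 <- simulate_equal_density_random(tmpl, seed = 10)
  expect_identical(r1$x, r2$x)
  empty <- simulate_equal_density_random(point_pattern(window = w), w,
                                         seed = 1)
  expect_equal(npoints(empty), 0)
})

test_that("scenes are reproducible and populations use independent streams", {
  w <- follicle_window()
  s1 <- simulate_scene(w, n_niche = 60, n_target = 20, seed = 99)
  s2 <- simulate_scene(w, n_niche = 60, n_target = 20, seed = 99)
  expect_identical(s1$niche$x, s2$niche$x)
  expect_identical(s1$target$y, s2$target$y)
  expect_true(all(in_usable(w, s1$target$x, s1$target$y)))
  # resizing the target population must not move the niche
  s3 <- simulate_scene(w, n_niche = 60, n_target = 35, seed = 99)
  expect_identical(s1$niche$x, s3$niche$x)
})

test_that("scene configs round-trip through YAML", {
  w <- follicle_window()
  sc <- simulate_scene(w, n_niche = 50, n_target = 15,
                       clustered_fraction = 0.6, band_width = 12,
                       attraction_scale = 4, seed = 31)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(sc, path)
  sc2 <- simulate_scene_from_config(path)
  expect_identical(sc$niche$x, sc2$niche$x)
  expect_identical(sc$target$x, sc2$target$x)
  expect_equal(sc$params, sc2$params)
})
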