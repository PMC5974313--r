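test_that("hand-computed Hopkins value on a 4-point square", {
  w <- make_window(10, 10)
  p <- point_pattern(c(0, 10, 0, 10), c(0, 0, 10, 10), window = w)
  origins <- rbind(c(5, 5), c(1, 1))
  idx <- c(1, 4)  # data subsample (0,0) and (10,10)
  # u = (sqrt(50), sqrt(2)); w = (10, 10)
  h_expect <- (sqrt(50) + sqrt(2)) / (sqrt(50) + sqrt(2) + 20)
  h <- hopkins_statistic(p, m = 2, origins = origins, data_idx = idx)
  expect_equal(h, h_expect, tolerance = 1e-15)
  # powered variant: squared distances
  h2_expect <- (50 + 2) / (50 + 2 + 200)
  expect_equal(hopkins_statistic(p, m = 2, variant = "powered",
                                 origins = origins, data_idx = idx),
               h2_expect, tolerance = 1e-15)
})

test_that("coincident pattern attains the clustered extreme H = 1", {
  w <- make_window(100, 100)
  p <- point_pattern(rep(20, 12), rep(30, 12), window = w)
  expect_identical(hopkins_statistic(p, m = 5, seed = 1), 1)
  hr <- hopkins_resampled(p, m = 5, reps = 50, seed = 2)
  expect_identical(hr$mean, 1)
  expect_identical(hr$sd, 0)
})

test_that("hopkins_statistic equals the brute-force oracle exactly", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    m <- sample(2:min(10, n), 1)
    w <- make_window(runif(1, 50, 200), runif(1, 50, 200))
    p <- simulate_csr(n, w)
    origins <- cbind(runif(m, 0, w$width), runif(m, 0, w$height))
    idx <- sample.int(n, m)
    variant <- sample(c("plain", "powered"), 1)
    expect_equal(hopkins_statistic(p, m = m, variant = variant,
                                   origins = origins, data_idx = idx),
                 brute_hopkins(p, origins, idx, variant),
                 tolerance = 0)
  }
})

test_that("Hopkins is scale invariant and always in [0, 1]", {
  w <- follicle_window()
  p <- simulate_perifollicular(60, w, seed = 4)
  for (const in c(4, 3.7)) {
    wb <- make_window(150 * const, 150 * const,
                      follicles = list(c(75, 75, 40) * const))
    pb <- point_pattern(p$x * const, p$y * const, window = wb)
    for (variant in c("plain", "powered")) {
      origins <- cbind(runif(10, 0, 150), runif(10, 0, 150))
      idx <- sample.int(60, 10)
      h1 <- hopkins_statistic(p, m = 10, variant = variant,
                              origins = origins, data_idx = idx)
      h2 <- hopkins_statistic(pb, m = 10, variant = variant,
                              origins = origins * const, data_idx = idx)
      expect_equal(h1, h2, tolerance = 1e-12)
      expect_gte(h1, 0); expect_lte(h1, 1)
    }
  }
})

test_that("resampling protocol is reproducible and validates inputs", {
  w <- plain_window()
  p <- simulate_csr(100, w, seed = 1)
  r1 <- hopkins_resampled(p, m = 40, reps = 100, seed = 5)
  r2 <- hopkins_resampled(p, m = 40, reps = 100, seed = 5)
  expect_identical(r1$per_rep, r2$per_rep)
  expect_length(r1$per_rep, 100)
  expect_equal(r1$mean, mean(r1$per_rep))
  expect_true(all(r1$per_rep >= 0 & r1$per_rep <= 1))

  expect_error(hopkins_statistic(p, m = 101), "m <=")
  expect_error(hopkins_statistic(point_pattern(1, 1, window = w), m = 1),
               ">= 2")
  # sparse window: m reduced with a warning instead of failing
  sparse <- simulate_csr(25, w, seed = 2)
  expect_warning(rs <- hopkins_resampled(sparse, m = 40, reps = 10,
                                         seed = 3),
                 "reducing m")
  expect_equal(rs$config$m, 25)
})

test_that("CSR patterns score near 0.5, clustered patterns higher (paired)", {
  w <- follicle_window()
  means_csr <- vapply(1:5, function(s) {
    p <- simulate_csr(200, plain_window(), seed = derive_seed(60, s))
    hopkins_resampled(p, m = 40, reps = 300,
                      seed = derive_seed(61, s))$mean
  }, 0)
  expect_gt(mean(means_csr), 0.46)
  expect_lt(mean(means_csr), 0.54)
  # seed-matched clustered vs CSR comparison at equal n on the same window
  wins <- vapply(1:20, function(s) {
    pc <- simulate_perifollicular(120, w, band_width = 10,
                                  clustered_fraction = 0.9,
                                  seed = derive_seed(70, s))
    pr <- simulate_csr(120, w, seed = derive_seed(71, s))
    hs <- derive_seed(72, s)
    hopkins_resampled(pc, m = 40, reps = 200, seed = hs)$mean >
      hopkins_resampled(pr, m = 40, reps = 200, seed = hs)$mean
  }, NA)
  expect_true(all(wins))
})

test_that("mean Hopkins increases with the clustered fraction", {
  w <- follicle_window()
  n_seeds <- 50
  mono <- vapply(seq_len(n_seeds), function(s) {
    h <- vapply(c(0, 0.4, 0.8), function(p) {
      pat <- simulate_perifollicular(
        120, w, band_width = 10, clustered_fraction = p,
        seed = derive_seed(80 + round(100 * p), s))
      hopkins_resampled(pat, m = 40, reps = 300,
                        seed = derive_seed(90, s))$mean
    }, 0)
    h[1] < h[2] && h[2] < h[3]
  }, NA)
  expect_gte(sum(mono), 0.9 * n_seeds)
})

test_that("CSR envelope straddles 0.5 and flags clustering", {
  w <- follicle_window()
  env <- csr_envelope(120, w, m = 40, reps = 200, sims = 40, seed = 13)
  expect_lt(env$lo, 0.5)
  expect_gt(env$hi, 0.5)
  pc <- simulate_perifollicular(120, w, band_width = 10,
                                clustered_fraction = 0.9, seed = 14)
  hc <- hopkins_resampled(pc, m = 40, reps = 200, seed = 15)
  expect_identical(classify_hopkins(hc, env), "clustered")
  expect_error(csr_envelope(120, w, sims = 10), "sims")
})

test_that("group summary matches the textbook pooled t formula", {
  a <- c(0.59, 0.62, 0.56)
  b <- c(0.50, 0.49, 0.51)
  gs <- hopkins_group_summary(list(tg = a, ctr = b))
  expect_equal(gs$groups$mean, c(mean(a), mean(b)))
  expect_equal(gs$groups$sd, c(sd(a), sd(b)))
  # pooled two-sample t, computed from first principles
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(gs$t, t_hand, tolerance = 1e-12)
  expect_equal(gs$df, 4)
  expect_equal(gs$p_value, p_hand, tolerance = 1e-12)

  same <- hopkins_group_summary(list(a = c(0.5, 0.6), b = c(0.5, 0.6)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(hopkins_group_summary(list(a = 1:3)), ">= 2 groups")
  expect_error(hopkins_group_summary(list(a = 1:3, b = numeric(0))),
               "empty")
})

test_that("simulated condition vs control separates at alpha = 0.05", {
  w <- follicle_window()
  n_rej <- 0
  for (trial in 1:20) {
    tg <- vapply(1:6, function(k) {
      p <- simulate_perifollicular(120, w, band_width = 10,
                                   clustered_fraction = 0.8,
                                   seed = derive_seed(3000 + trial, k))
      hopkins_resampled(p, m = 40, reps = 200,
                        seed = derive_seed(4000 + trial, k))$mean
    }, 0)
    ctr <- vapply(1:6, function(k) {
      p <- simulate_csr(120, w, seed = derive_seed(5000 + trial, k))
      hopkins_resampled(p, m = 40, reps = 200,
                        seed = derive_seed(6000 + trial, k))$mean
    }, 0)
    gs <- hopkins_group_summary(list(tg = tg, ctr = ctr))
    if (gs$p_value < 0.05) n_rej <- n_rej + 1
  }
  expect_gte(n_rej, 18)  # >= 90% power
})
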