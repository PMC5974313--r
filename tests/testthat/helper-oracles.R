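# Independent brute-force oracles used to cross-check the accelerated
# implementations. Deliberately naive O(n^2) scans.

brute_nncross <- function(px, py, qx, qy) {
  vapply(seq_along(px), function(i) {
    sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }, 0)
}

brute_nnself <- function(x, y) {
  vapply(seq_along(x), function(i) {
    d2 <- (x[i] - x)^2 + (y[i] - y)^2
    d2[i] <- Inf
    sqrt(min(d2))
  }, 0)
}

# Hopkins statistic from first principles, given injected origins and
# data-subsample indices.
brute_hopkins <- function(pattern, origins, data_idx, variant = "plain") {
  u <- brute_nncross(origins[, 1], origins[, 2], pattern$x, pattern$y)
  w <- brute_nnself(pattern$x, pattern$y)[data_idx]
  k <- if (variant == "powered") 2 else 1
  su <- sum(u^k)
  sw <- sum(w^k)
  if (su + sw == 0) return(0.5)
  su / (su + sw)
}

# standard 150 x 150 um windows used across tests
plain_window <- function() make_window(150, 150)
follicle_window <- function() make_window(150, 150,
                                          follicles = list(c(75, 75, 40)))
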