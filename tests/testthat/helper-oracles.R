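# Shared fixtures and independent oracles used across the suite.

make_dg <- function(N, B = 2, c = 1) game_spec("dg", N = N, B = B, c = c)

make_pgg <- function(N, c = 1, r = 2, n = min(4, N)) {
  game_spec("pgg", N = N, c = c, r = r, n = n)
}

# Brute-force PGG payoffs: explicit multivariate hypergeometric sums over
# the number of cooperating co-players i, independent of the closed forms
# in the package. choose() already returns 0 outside sampling support.
oracle_pgg_payoffs <- function(c, r, n, N, j) {
  i <- 0:(n - 1)
  wC <- choose(j - 1, i) * choose(N - j, n - 1 - i) / choose(N - 1, n - 1)
  wD <- choose(j, i) * choose(N - 1 - j, n - 1 - i) / choose(N - 1, n - 1)
  c(PiC = sum(wC * ((i + 1) * r * c / n - c)),
    PiD = sum(wD * (i * r * c / n)))
}

# Exact integer polynomial recurrence for the sojourn coefficients:
# p_j = p_{j-1} - shift(p_{j-2}), carried as integer coefficient vectors.
oracle_poly_coefficients <- function(j) {
  p0 <- 1; p1 <- 1
  if (j == 0 || j == 1) return(1)
  for (m in 2:j) {
    shifted <- c(0, p0)
    len <- max(length(p1), length(shifted))
    p <- c(p1, rep(0, len - length(p1))) - c(shifted, rep(0, len - length(shifted)))
    p0 <- p1; p1 <- p
  }
  p1
}

# Neutral-drift sojourn values via the alternating binomial sum at
# bd = 1/4 (the form stated with the limit results).
oracle_PQ_sum <- function(j) {
  k <- 0:(j %/% 2)
  sum((-1)^k * choose(j - k, k) * 0.25^k)
}

grid_params <- function(N, beta, start = "equal", mu = 0) {
  evolution_params(N, beta = beta, mu = mu, start = start)
}
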