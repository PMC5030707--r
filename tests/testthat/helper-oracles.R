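# Independent oracles, deliberately naive: brute-force numerics that share
# no code with the package's closed-form / vectorized implementations.

# Powder-averaged dephasing by trapezoid quadrature of the instantaneous
# dipolar frequency on a dense (beta, gamma) grid.
oracle_dephasing <- function(delta_hz, mas_hz, t1, n_beta = 120L,
                             n_gamma = 120L, n_t = 4000L) {
  beta <- (seq_len(n_beta) - 0.5) * pi / n_beta
  gam <- (seq_len(n_gamma) - 1) * 2 * pi / n_gamma
  gr <- expand.grid(b = beta, g = gam)
  w <- sin(gr$b)
  w <- w / sum(w)
  wr <- 2 * pi * mas_hz
  vapply(t1, function(tt) {
    if (tt == 0) return(1)
    ts <- seq(0, tt, length.out = n_t)
    dt <- ts[2] - ts[1]
    phi <- numeric(nrow(gr))
    for (i in seq_along(ts)) {
      om <- pi * delta_hz * (sqrt(2) * sin(2 * gr$b) * cos(wr * ts[i] + gr$g) -
                               sin(gr$b)^2 * cos(2 * wr * ts[i] + 2 * gr$g))
      phi <- phi + om * dt * (if (i == 1L || i == n_t) 0.5 else 1)
    }
    sum(w * cos(phi))
  }, numeric(1))
}

# Numerical quadrature (composite Simpson) of the phase for one orientation
# (checks the closed-form integral).
oracle_phase <- function(delta_hz, mas_hz, t1, beta, gamma, n_t = 20001L) {
  if (t1 == 0) return(0)
  wr <- 2 * pi * mas_hz
  ts <- seq(0, t1, length.out = n_t)
  om <- pi * delta_hz * (sqrt(2) * sin(2 * beta) * cos(wr * ts + gamma) -
                           sin(beta)^2 * cos(2 * wr * ts + 2 * gamma))
  h <- ts[2] - ts[1]
  coef <- rep(c(2, 4), length.out = n_t)
  coef[c(1, n_t)] <- 1
  sum(coef * om) * h / 3
}

# Textbook Pearson coefficient computed with an explicit loop.
oracle_pearson <- function(x, y) {
  x <- unname(x)
  y <- unname(y)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0
  sxx <- 0
  syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Minimal labelled-residue shift table used across contact tests: shifts
# spaced far apart so every peak is unambiguous.
well_separated_assignments <- function() {
  shift_table(res_index = c(19L, 19L, 22L, 22L, 31L, 31L, 34L, 34L),
              res_type = c("F", "F", "E", "E", "I", "I", "L", "L"),
              nucleus = rep(c("CA", "CB"), 4),
              shift_ppm = c(55, 41, 58, 29.5, 62, 37, 52.5, 44.5))
}
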