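test_that("zero coupling gives a flat curve and any coupling refocuses at the rotor echo", {
  flat <- simulate_dephasing(0, 5000, 16)
  expect_equal(flat$intensity, rep(1, 16))
  for (d in c(1000, 5000, 13000)) {
    cv <- simulate_dephasing(d, 5000, 32)
    expect_equal(cv$intensity[1], 1)
    expect_lt(abs(cv$intensity[32] - 1), 1e-6) # full-period phase integral vanishes
  }
})

test_that("closed-form phase integral matches numerical quadrature per orientation", {
  set.seed(3)
  pw <- powder_scheme()
  for (k in 1:6) {
    beta <- runif(1, 0.1, pi - 0.1)
    gamma <- runif(1, 0, 2 * pi)
    t1 <- runif(1, 1e-5, 2e-4)
    sch <- structure(list(beta = beta, gamma = gamma, weight = 1),
                     class = "powder_scheme")
    phi_closed <- fibrilnmr:::unit_phase_matrix(t1, 5000, sch)[1, 1] * 7000
    phi_num <- oracle_phase(7000, 5000, t1, beta, gamma)
    expect_lt(abs(phi_closed - phi_num) / max(abs(phi_num), 1e-12), 1e-8)
  }
})

test_that("powder-averaged intensities match the dense-grid brute-force oracle", {
  cv <- simulate_dephasing(5000, 5000, 64)
  probe <- c(17L, 33L, 49L) # quarter, half, three-quarter rotor period
  ora <- oracle_dephasing(5000, 5000, cv$t1_s[probe])
  expect_lt(max(abs(cv$intensity[probe] - ora)), 1e-3)
})

test_that("the dephasing curve has rotor time-reversal symmetry and is sign-convention invariant", {
  for (d in c(2000, 8000, 13000)) {
    cv <- simulate_dephasing(d, 5000, 64)
    expect_lt(max(abs(cv$intensity - rev(cv$intensity))), 1e-6)
  }
  # negating the dipolar frequency negates every accumulated phase; the
  # cosine average is untouched for any scheme
  pw <- powder_scheme()
  P <- fibrilnmr:::unit_phase_matrix(seq(0, 2e-4, length.out = 16), 5000, pw)
  i_pos <- as.vector(cos(6000 * P) %*% pw$weight)
  i_neg <- as.vector(cos(-6000 * P) %*% pw$weight)
  expect_identical(i_pos, i_neg)
  # shifting every gamma by a constant (redefining the rotor phase origin):
  # exact once gamma covers the full circle uniformly
  pwg <- powder_scheme("grid", n_beta = 48L, n_gamma = 32L)
  for (shift in c(pi, 0.83)) {
    pw2 <- pwg
    pw2$gamma <- (pwg$gamma + shift) %% (2 * pi)
    a <- simulate_dephasing(6000, 5000, 16, powder = pwg)
    b <- simulate_dephasing(6000, 5000, 16, powder = pw2)
    expect_lt(max(abs(a$intensity - b$intensity)), 1e-9)
  }
})

test_that("curve depth grows monotonically with the coupling", {
  depth <- vapply(seq(500, 6000, by = 500), function(d) {
    1 - min(simulate_dephasing(d, 5000, 32)$intensity)
  }, numeric(1))
  expect_true(all(diff(depth) > 0))
})

test_that("fit_coupling recovers noiseless couplings within 1% and a flat curve as zero", {
  for (d in c(3000, 8000, 13100)) {
    cv <- simulate_dephasing(d, 5000, 16)
    fit <- fit_coupling(cv, 25000)
    expect_lt(abs(fit$delta_eff_hz - d) / d, 0.01)
    expect_true(fit$converged)
  }
  flat <- dipshift_curve(seq(0, 2e-4, length.out = 16), rep(1, 16), 5000)
  expect_equal(fit_coupling(flat, 25000)$delta_eff_hz, 0)
})

test_that("fit_coupling recovers a 10 kHz coupling from a 2% noisy curve within 5%", {
  cv <- simulate_dephasing(10000, 5000, 16)
  cv$intensity <- cv$intensity + fibrilnmr:::with_seed(9, rnorm(16, 0, 0.02))
  fit <- fit_coupling(cv, 25000)
  expect_lt(abs(fit$delta_eff_hz - 10000) / 10000, 0.05)
})

test_that("fit_coupling rejects malformed curves", {
  cv <- simulate_dephasing(5000, 5000, 16)
  bad <- cv
  bad$intensity[4] <- NA
  expect_error(fit_coupling(bad, 25000), class = "fibrilnmr_bad_input")
  expect_error(dipshift_curve(c(0, 3e-5, 2e-5, 2e-4), rep(1, 4), 5000),
               class = "fibrilnmr_bad_input")
})

test_that("order parameters are the coupling over kappa times the rigid limit", {
  kap <- 1 / sqrt(3)
  expect_equal(order_parameter(kap * 22700, 22700, kap)$S, 1)
  expect_equal(order_parameter(0, 22700, kap)$S, 0)
  expect_equal(order_parameter(0.5 * kap * 22700, 22700, kap)$S, 0.5)
  # marginal overshoot clipped with flag; gross overshoot rejected
  marginal <- order_parameter(1.03 * kap * 22700, 22700, kap)
  expect_equal(marginal$S, 1)
  expect_true(marginal$clipped)
  expect_error(order_parameter(1.2 * kap * 22700, 22700, kap),
               class = "fibrilnmr_unphysical")
})

test_that("order-parameter sets are compared site-wise with uncertainty flags", {
  mk <- function(sites, S, u = NA_real_) {
    do.call(rbind, lapply(seq_along(sites), function(i) {
      order_parameter(S[i] * 22700 / sqrt(3), site = sites[i],
                      uncertainty = if (length(u) > 1) u[i] else u)
    }))
  }
  a <- mk(c("F4.CA", "I31.CA", "L34.CA"), c(0.5, 0.95, 0.9), 0.03)
  expect_identical(compare_order_params(a, a)$table$dS, rep(0, 3))
  expect_false(any(compare_order_params(a, a)$table$flagged))
  expect_equal(compare_order_params(a, a)$r, 1)

  # one site raised beyond combined errors: exactly that site flagged
  b <- mk(c("F4.CA", "I31.CA", "L34.CA"), c(0.5, 0.80, 0.9), 0.03)
  cmp <- compare_order_params(a, b)
  expect_equal(cmp$table$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(cmp$table$dS[2], 0.15, tolerance = 1e-12)

  # default 0.05 uncertainty when records carry none
  a2 <- mk("I31.CA", 0.95)
  b2 <- mk("I31.CA", 0.80)
  expect_true(compare_order_params(a2, b2)$table$flagged)
  b3 <- mk("I31.CA", 0.88)
  expect_false(compare_order_params(a2, b3)$table$flagged)

  expect_error(compare_order_params(a, mk("X1.CA", 0.5)),
               class = "fibrilnmr_no_shared_sites")
})

test_that("order parameters survive a noisy generate-fit round trip across the S range", {
  kap <- 1 / sqrt(3)
  grid_max <- 1.2 * kap * 22700
  for (S in c(0.2, 0.6, 1.0)) {
    for (s in 1:5) {
      cv <- gen_dipshift_curve(S, noise_sd = 0.02, seed = 40 * S + s)
      fit <- fit_coupling(cv, grid_max)
      rec <- order_parameter(fit, 22700, kap)
      expect_lt(abs(rec$S - S), 0.05)
    }
  }
})

test_that("dephasing curves round-trip through the CSV dialect", {
  cv <- simulate_dephasing(7000, 5000, 16, site = "I31.CA")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dipshift_curve(cv, path)
  back <- read_dipshift_curve(path)
  expect_equal(back$intensity, cv$intensity, tolerance = 1e-8)
  expect_equal(attr(back, "mas_rate_hz"), 5000)
  expect_equal(attr(back, "site"), "I31.CA")
})
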