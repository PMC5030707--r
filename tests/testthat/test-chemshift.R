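test_that("secondary shifts are observed-minus-reference after the referencing offset", {
  rc <- random_coil_table()
  tab <- shift_table(res_index = c(10, 10, 11, 11),
                     res_type = c("Y", "Y", "E", "E"),
                     nucleus = c("CA", "CB", "CA", "CB"),
                     shift_ppm = c(58.1, 38.8, 54.6, 31.9))
  sec <- secondary_shift(tab, rc)
  # Tyr10 sits exactly at random coil; Glu11 is a beta-like record
  expect_equal(sec$delta_ppm[sec$res_index == 10 & sec$nucleus == "CA"], 0)
  expect_equal(sec$delta_ppm[sec$res_index == 11 & sec$nucleus == "CA"], -2.0)
  expect_equal(sec$delta_ppm[sec$res_index == 11 & sec$nucleus == "CB"], 2.0)

  # explicit offset shifts every delta by the same amount
  tab_off <- shift_table(tab$res_index, tab$res_type, tab$nucleus,
                         tab$shift_ppm, ref_offset_ppm = 1.5)
  sec_off <- secondary_shift(tab_off, rc)
  expect_equal(sec_off$delta_ppm, sec$delta_ppm + 1.5)

  expect_error(secondary_shift(tab[0, ], rc), class = "fibrilnmr_bad_input")
})

test_that("secondary_shift matches an element-wise subtraction oracle on a random table", {
  rc <- random_coil_table()
  set.seed(42)
  types <- sample(setdiff(strsplit("ACDEFHIKLMNPQRSTVWY", "")[[1]], "G"), 10,
                  replace = TRUE)
  nuc <- sample(c("CA", "CB"), 10, replace = TRUE)
  obs <- runif(10, 20, 65)
  tab <- shift_table(seq_len(10), types, nuc, obs)
  sec <- secondary_shift(tab, rc)
  for (i in seq_len(10)) {
    ref <- rc$shift_ppm[rc$res_type == types[i] & rc$nucleus == nuc[i]]
    expect_equal(sec$delta_ppm[i], obs[i] - ref)
  }
})

test_that("records without a random-coil reference are skipped with a message", {
  rc <- random_coil_table()
  tab <- shift_table(res_index = c(3, 4), res_type = c("Z", "F"),
                     nucleus = c("CA", "CA"), shift_ppm = c(58, 56))
  expect_message(sec <- secondary_shift(tab, rc), "Z3")
  expect_equal(sec$res_index, 4L)
})

test_that("delta_delta excludes Gly and is invariant under a referencing constant", {
  rc <- random_coil_table()
  tab <- shift_table(res_index = c(9, 19, 19, 34, 34),
                     res_type = c("G", "F", "F", "L", "L"),
                     nucleus = c("CA", "CA", "CB", "CA", "CB"),
                     shift_ppm = c(45.1, 56.0, 41.0, 53.1, 44.4))
  dd <- delta_delta(secondary_shift(tab, rc, quiet = TRUE))
  expect_false("9" %in% names(dd)) # no CB -> Gly never enters
  expect_equal(dd[["19"]], (56.0 - 58.0) - (41.0 - 39.0))

  # add a constant to every carbon shift: all Delta-Delta values unchanged
  tab_c <- shift_table(tab$res_index, tab$res_type, tab$nucleus,
                       tab$shift_ppm + 3.7)
  dd_c <- delta_delta(secondary_shift(tab_c, rc, quiet = TRUE))
  expect_equal(dd_c, dd, tolerance = 1e-12)
})

test_that("delta_delta uses polymorph rank 1 by default and rank 2 on request", {
  rc <- random_coil_table()
  tab <- shift_table(res_index = c(19, 19, 19),
                     res_type = "F", nucleus = c("CA", "CB", "CB"),
                     shift_ppm = c(56.0, 41.0, 42.5), polymorph = c(1, 1, 2))
  sec <- secondary_shift(tab, rc, quiet = TRUE)
  expect_equal(delta_delta(sec)[["19"]], -2 - 2)
  expect_equal(delta_delta(sec, polymorph = 2L), setNames(numeric(0), character(0)))
})

test_that("classification follows the Ca-down/Cb-up beta sign convention", {
  mk <- function(dca, dcb, type = "F") {
    sec <- data.frame(res_index = 1L, res_type = type,
                      nucleus = c("CA", "CB"), delta_ppm = c(dca, dcb),
                      polymorph = 1L, stringsAsFactors = FALSE)
    class(sec) <- c("secondary_shift_table", "data.frame")
    sec
  }
  expect_equal(unname(classify_ss(mk(-2, 2))), "beta")
  expect_equal(unname(classify_ss(mk(2, -2))), "helix")
  expect_equal(unname(classify_ss(mk(0, 0))), "coil")
  expect_equal(unname(classify_ss(mk(-2, -2))), "coil") # inconsistent signs
  expect_equal(unname(classify_ss(mk(-0.5, 0.5))), "coil") # below threshold

  # antisymmetry: negating both deltas swaps beta and helix
  for (pair in list(c(-1.2, 0.9), c(3, -1), c(-0.8, 0.71))) {
    a <- unname(classify_ss(mk(pair[1], pair[2])))
    b <- unname(classify_ss(mk(-pair[1], -pair[2])))
    swap <- c(beta = "helix", helix = "beta", coil = "coil")
    expect_equal(b, unname(swap[a]))
  }
})

test_that("Gly is classified on the Ca sign alone, with the threshold", {
  gly <- function(dca) {
    sec <- data.frame(res_index = 29L, res_type = "G", nucleus = "CA",
                      delta_ppm = dca, polymorph = 1L, stringsAsFactors = FALSE)
    class(sec) <- c("secondary_shift_table", "data.frame")
    classify_ss(sec)
  }
  expect_equal(unname(gly(-1.5)), "beta")
  expect_equal(unname(gly(1.5)), "helix")
  expect_equal(unname(gly(-0.3)), "coil")
})

test_that("correlate_dd matches the direct-formula oracle and validates inputs", {
  set.seed(11)
  a <- setNames(rnorm(8), as.character(1:8))
  b <- setNames(rnorm(8), as.character(1:8))
  res <- correlate_dd(a, b)
  expect_equal(res$r, oracle_pearson(a, b))
  expect_equal(res$n, 8L)

  expect_equal(correlate_dd(a, a)$r, 1.0)
  expect_equal(correlate_dd(a, -a)$r, -1.0)

  # symmetry and positive-affine invariance
  expect_equal(correlate_dd(b, a)$r, res$r)
  expect_equal(correlate_dd(2.5 * a + 3, b)$r, res$r)

  # intersection semantics: only shared residue indices enter
  a2 <- setNames(rnorm(6), as.character(3:8))
  expect_equal(correlate_dd(a2, b)$n, 6L)
  expect_equal(correlate_dd(a2, b)$r, oracle_pearson(a2, b[as.character(3:8)]))

  expect_error(correlate_dd(a[1:2], b), class = "fibrilnmr_too_few_shared")
  flat <- setNames(rep(1, 8), names(a))
  expect_error(correlate_dd(flat, b), class = "fibrilnmr_zero_variance")
})

test_that("beta regions 10-22 and 30-38 are recovered from noisy synthetic tables", {
  rc <- random_coil_table()
  tmpl <- abeta_fibril_template("wt", noise_sd_ppm = 0.3)
  idx_beta <- c(10:22, 30:38)
  seq <- abeta_sequence("wt")
  non_gly_beta <- as.character(idx_beta[seq[idx_beta] != "G"])
  ok <- 0L
  n_runs <- 100L
  for (s in seq_len(n_runs)) {
    tab <- gen_shift_table(tmpl, rc, seed = 5000L + s)
    cls <- classify_ss(secondary_shift(tab, rc, quiet = TRUE))
    beta_ok <- all(cls[non_gly_beta] == "beta")
    nterm_ok <- all(cls[as.character(1:9)] == "coil")
    if (beta_ok && nterm_ok) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})
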