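# DIPSHIFT dipolar-dephasing under magic-angle spinning.
#
# For one 1H-13C pair at crystallite orientation (beta, gamma) the
# instantaneous dipolar frequency under MAS is
#   omega(t) = pi * delta_eff * [ sqrt(2) sin(2 beta) cos(wr t + gamma)
#                                 - sin^2(beta) cos(2 wr t + 2 gamma) ]
# with wr = 2 pi * mas_rate. The accumulated phase integral has the closed
# form used below; crucially it is LINEAR in delta_eff, so a unit-phase
# matrix (phase per Hz of coupling) can be precomputed once per (t1 grid,
# powder) and reused across coupling values during fitting.

#' Powder orientation schemes for MAS averaging
#'
#' `"zcw"` (default) builds a ZCW-style spiral set: cos(beta) is stratified
#' uniformly (equal-area sampling, which carries the sin(beta) solid-angle
#' weight implicitly) while gamma advances by the Fibonacci ratio. The
#' spiral is mirrored in gamma (two interleaved half-sets), which makes the
#' set closed under gamma-negation and hence makes the rotor time-reversal
#' symmetry I(t1) = I(tau_r - t1) exact for the averaged signal. `"grid"`
#' builds an explicit (beta x gamma) product grid with sin(beta) weights;
#' slower but systematic, it serves as the dense reference scheme.
#'
#' @param type `"zcw"` or `"grid"`.
#' @param n Number of orientations for `"zcw"` (rounded up to even; default
#'   378, i.e. two mirrored 189-point spirals).
#' @param n_beta,n_gamma Grid dimensions for `"grid"`.
#' @return List of class `powder_scheme` with components `beta`, `gamma`,
#'   `weight` (weights sum to 1).
#' @export
powder_scheme <- function(type = c("zcw", "grid"), n = 378L,
                          n_beta = 64L, n_gamma = 32L) {
  type <- match.arg(type)
  if (type == "zcw") {
    stopifnot(n >= 8L)
    m <- ceiling(n / 2)
    fib <- c(1, 1)
    while (fib[length(fib)] < m) fib <- c(fib, sum(utils::tail(fib, 2)))
    g <- fib[max(which(fib < m))] # Fibonacci partner for the gamma stride
    j <- seq_len(m) - 1L
    z <- -1 + 2 * (j + 0.5) / m
    gam <- 2 * pi * ((j * g / m) %% 1)
    out <- list(beta = acos(c(z, z)),
                gamma = c(gam, 2 * pi - gam),
                weight = rep(1 / (2 * m), 2 * m))
  } else {
    stopifnot(n_beta >= 2L, n_gamma >= 2L)
    beta <- (seq_len(n_beta) - 0.5) * pi / n_beta
    gamma <- (seq_len(n_gamma) - 1) * 2 * pi / n_gamma
    grid <- expand.grid(beta = beta, gamma = gamma)
    w <- sin(grid$beta)
    out <- list(beta = grid$beta, gamma = grid$gamma, weight = w / sum(w))
  }
  class(out) <- "powder_scheme"
  out
}

validate_powder <- function(powder) {
  if (!inherits(powder, "powder_scheme") ||
      !all(c("beta", "gamma", "weight") %in% names(powder)) ||
      length(powder$beta) != length(powder$weight) ||
      any(!is.finite(powder$weight)) || abs(sum(powder$weight) - 1) > 1e-9) {
    stop_fibrilnmr("invalid powder scheme", "fibrilnmr_bad_powder")
  }
  invisible(powder)
}

# Closed-form accumulated phase per Hz of coupling: matrix [t1 x orientation].
unit_phase_matrix <- function(t1, mas_rate, powder) {
  wr <- 2 * pi * mas_rate
  s2b <- sin(2 * powder$beta)
  sb2 <- sin(powder$beta)^2
  g <- powder$gamma
  # integral of pi*[sqrt2 s2b cos(wr t + g) - sb2 cos(2 wr t + 2 g)] dt
  term1 <- outer(t1, g, function(t, gg) sin(wr * t + gg)) - matrix(sin(g), length(t1), length(g), byrow = TRUE)
  term2 <- outer(t1, g, function(t, gg) sin(2 * wr * t + 2 * gg)) - matrix(sin(2 * g), length(t1), length(g), byrow = TRUE)
  (pi / wr) * (sqrt(2) * sweep(term1, 2L, s2b, `*`) - 0.5 * sweep(term2, 2L, sb2, `*`))
}

#' DIPSHIFT dephasing curve container
#'
#' Normalized intensity sampled over exactly one rotor period
#' tau_r = 1/mas_rate, starting at t1 = 0.
#'
#' @param t1_s Sample times in seconds; strictly increasing, `t1_s[1] == 0`,
#'   last point equal to the rotor period.
#' @param intensity Normalized intensities (unitless, finite).
#' @param mas_rate_hz MAS spinning rate in Hz.
#' @param site Site label, e.g. `"I31.CA"`.
#' @return Data.frame of class `dipshift_curve` with attributes
#'   `mas_rate_hz` and `site`.
#' @export
dipshift_curve <- function(t1_s, intensity, mas_rate_hz, site = "unlabeled") {
  stopifnot(mas_rate_hz > 0, length(t1_s) == length(intensity))
  if (length(t1_s) < 2L || t1_s[1] != 0 || any(diff(t1_s) <= 0)) {
    stop_fibrilnmr("t1 must start at 0 and be strictly increasing",
                   "fibrilnmr_bad_input")
  }
  tau_r <- 1 / mas_rate_hz
  if (abs(t1_s[length(t1_s)] - tau_r) > 1e-9 * tau_r) {
    stop_fibrilnmr("t1 must span exactly one rotor period", "fibrilnmr_bad_input")
  }
  if (!all(is.finite(intensity))) {
    stop_fibrilnmr("intensities must be finite", "fibrilnmr_bad_input")
  }
  df <- data.frame(t1_s = as.numeric(t1_s), intensity = as.numeric(intensity))
  attr(df, "mas_rate_hz") <- mas_rate_hz
  attr(df, "site") <- site
  class(df) <- c("dipshift_curve", "data.frame")
  df
}

#' Simulate a DIPSHIFT dephasing curve
#'
#' Powder-averaged \eqn{I(t_1) = \langle \cos\Phi(t_1) \rangle} for a single
#' heteronuclear pair with motionally averaged effective coupling
#' `delta_eff_hz` (any FSLG decoupling scale is already inside the effective
#' coupling; the scale re-enters only at the order-parameter step). The phase
#' integral is evaluated in closed form; \eqn{I(0) = I(\tau_r) = 1} (rotor
#' echo) holds exactly up to powder-sum rounding.
#'
#' @param delta_eff_hz Effective dipolar coupling in Hz (>= 0).
#' @param mas_rate_hz MAS rate in Hz (> 0).
#' @param n_points Number of t1 samples across one rotor period (>= 8).
#' @param powder A [powder_scheme()].
#' @param site Site label carried on the output.
#' @return A [dipshift_curve()].
#' @export
simulate_dephasing <- function(delta_eff_hz, mas_rate_hz, n_points = 16L,
                               powder = powder_scheme(), site = "simulated") {
  stopifnot(delta_eff_hz >= 0, mas_rate_hz > 0, n_points >= 8L)
  validate_powder(powder)
  t1 <- seq(0, 1 / mas_rate_hz, length.out = n_points)
  P <- unit_phase_matrix(t1, mas_rate_hz, powder)
  intensity <- as.vector(cos(delta_eff_hz * P) %*% powder$weight)
  intensity <- intensity / intensity[1] # I(0) = 1 by construction
  dipshift_curve(t1, intensity, mas_rate_hz, site = site)
}

#' Fit the effective dipolar coupling to a dephasing curve
#'
#' Least-squares fit of [simulate_dephasing()] to a measured curve: a coarse
#' scan of 200 steps from 0 to `delta_grid_max_hz` followed by local
#' golden-section/parabolic refinement around the best grid point. The
#' objective can be locally flat near zero coupling, so ties are broken
#' toward the smaller coupling. Deterministic for fixed inputs.
#'
#' @param curve A [dipshift_curve()].
#' @param delta_grid_max_hz Upper end of the coupling search grid in Hz.
#' @param powder Powder scheme used by the forward model.
#' @return List of class `coupling_fit`: `delta_eff_hz`, `rss`, `converged`,
#'   `site`.
#' @export
fit_coupling <- function(curve, delta_grid_max_hz = 25000,
                         powder = powder_scheme()) {
  if (!inherits(curve, "dipshift_curve")) {
    stop_fibrilnmr("curve must be a dipshift_curve", "fibrilnmr_bad_input")
  }
  stopifnot(delta_grid_max_hz > 0)
  y <- curve$intensity
  if (anyNA(y) || any(diff(curve$t1_s) <= 0)) {
    stop_fibrilnmr("curve has missing points or non-monotone t1",
                   "fibrilnmr_bad_input")
  }
  validate_powder(powder)
  mas <- attr(curve, "mas_rate_hz")
  P <- unit_phase_matrix(curve$t1_s, mas, powder)
  w <- powder$weight
  sse <- function(d) {
    model <- as.vector(cos(d * P) %*% w)
    sum((model / model[1] - y)^2)
  }
  grid <- seq(0, delta_grid_max_hz, length.out = 201L)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals) # first minimum: ties break toward smaller coupling
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  ref <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-3)
  if (ref$objective <= vals[i]) {
    best <- ref$minimum
    rss <- ref$objective
  } else {
    best <- grid[i]
    rss <- vals[i]
  }
  structure(list(delta_eff_hz = best, rss = rss, converged = TRUE,
                 site = attr(curve, "site")),
            class = "coupling_fit")
}

#' Convert a fitted coupling to a molecular order parameter
#'
#' \eqn{S = \delta_{eff} / (\kappa\,\delta_{rigid})}: the fitted motionally
#' averaged coupling divided by the rigid-limit one-bond C-H coupling after
#' correcting for the homonuclear-decoupling scale factor kappa. S = 1 means
#' a rigid site, S = 0 isotropic motion. Values marginally above 1 (<= 1.05,
#' fit noise) are clipped to 1 and flagged; larger values signal a wrong
#' rigid limit or decoupling scale and are rejected.
#'
#' @param fit A `coupling_fit`, or a bare effective coupling in Hz.
#' @param delta_rigid_hz Rigid-limit C-H dipolar coupling (default 22700 Hz,
#'   a 1.10 A bond).
#' @param kappa Homonuclear decoupling scale factor in (0, 1]; default the
#'   theoretical Lee-Goldburg value 1/sqrt(3).
#' @param site Site label (taken from `fit` when absent).
#' @param uncertainty Optional S uncertainty.
#' @return One-row data.frame of class `order_parameter_record`: `site`, `S`,
#'   `delta_eff_hz`, `delta_rigid_hz`, `kappa`, `uncertainty`, `clipped`.
#' @export
order_parameter <- function(fit, delta_rigid_hz = 22700, kappa = 1 / sqrt(3),
                            site = NULL, uncertainty = NA_real_) {
  stopifnot(delta_rigid_hz > 0, kappa > 0, kappa <= 1)
  if (inherits(fit, "coupling_fit")) {
    if (!isTRUE(fit$converged)) {
      stop_fibrilnmr("coupling fit did not converge", "fibrilnmr_not_converged")
    }
    d <- fit$delta_eff_hz
    if (is.null(site)) site <- fit$site
  } else {
    d <- as.numeric(fit)
    if (is.null(site)) site <- "unlabeled"
  }
  stopifnot(d >= 0)
  S <- d / (kappa * delta_rigid_hz)
  clipped <- FALSE
  if (S > 1.05) {
    stop_fibrilnmr(sprintf(
      "order parameter %.3f > 1.05 is unphysical: check rigid limit and kappa", S),
      "fibrilnmr_unphysical")
  }
  if (S > 1) {
    S <- 1
    clipped <- TRUE
  }
  out <- data.frame(site = site, S = S, delta_eff_hz = d,
                    delta_rigid_hz = delta_rigid_hz, kappa = kappa,
                    uncertainty = uncertainty, clipped = clipped,
                    stringsAsFactors = FALSE)
  class(out) <- c("order_parameter_record", "data.frame")
  out
}

#' Compare two sets of order parameters site by site
#'
#' For every shared site label, reports \eqn{\Delta S = S_a - S_b} and flags
#' the site when \eqn{|\Delta S|} exceeds the combined uncertainties (records
#' without an uncertainty contribute `default_u`). Also returns the Pearson
#' correlation of the two S profiles over the shared sites.
#'
#' @param a,b Order-parameter tables (rbind of [order_parameter()] records).
#' @param default_u Uncertainty to assume where a record carries none
#'   (default 0.05).
#' @return List with `table` (data.frame: site, S_a, S_b, dS, flagged) and
#'   `r` (Pearson correlation; `NA` with fewer than 3 shared sites or zero
#'   variance).
#' @export
compare_order_params <- function(a, b, default_u = 0.05) {
  shared <- intersect(a$site, b$site)
  if (length(shared) < 1L) {
    stop_fibrilnmr("no shared site labels", "fibrilnmr_no_shared_sites")
  }
  ia <- match(shared, a$site)
  ib <- match(shared, b$site)
  ua <- ifelse(is.na(a$uncertainty[ia]), default_u, a$uncertainty[ia])
  ub <- ifelse(is.na(b$uncertainty[ib]), default_u, b$uncertainty[ib])
  dS <- a$S[ia] - b$S[ib]
  tab <- data.frame(site = shared, S_a = a$S[ia], S_b = b$S[ib], dS = dS,
                    flagged = abs(dS) > (ua + ub), stringsAsFactors = FALSE)
  r <- if (length(shared) >= 3L && stats::sd(tab$S_a) > 0 && stats::sd(tab$S_b) > 0) {
    stats::cor(tab$S_a, tab$S_b)
  } else if (length(shared) >= 2L && all(dS == 0)) {
    1 # identical profiles are perfectly correlated even when degenerate
  } else {
    NA_real_
  }
  list(table = tab, r = r)
}

#' Read / write a dephasing curve (CSV dialect)
#'
#' Columns `t1_s, intensity` with a header row; MAS rate and site label in
#' `# mas_rate_hz:` and `# site:` comment lines.
#'
#' @param path File path.
#' @return Reader: a [dipshift_curve()]; writer: `path` invisibly.
#' @export
read_dipshift_curve <- function(path) {
  meta <- read_comment_meta(path)
  if (is.null(meta$mas_rate_hz)) {
    stop_fibrilnmr(sprintf("%s: missing '# mas_rate_hz:' header", path),
                   "fibrilnmr_bad_input")
  }
  df <- read_table_skip_comments(path, sep = ",")
  dipshift_curve(df$t1_s, df$intensity, as.numeric(meta$mas_rate_hz),
                 site = if (!is.null(meta$site)) meta$site else "unlabeled")
}

#' @rdname read_dipshift_curve
#' @param curve A [dipshift_curve()].
#' @export
write_dipshift_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dipshift_curve"))
  df <- data.frame(t1_s = sprintf("%.9e", curve$t1_s),
                   intensity = sprintf("%.9f", curve$intensity))
  write_table_with_meta(df, path,
                        meta = list(mas_rate_hz = attr(curve, "mas_rate_hz"),
                                    site = attr(curve, "site")),
                        sep = ",")
}
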