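#' Thioflavin T fluorescence trace
#'
#' A fibrillation time course: ThT fluorescence intensity against incubation
#' time. Requires at least 10 strictly increasing time points.
#'
#' @param time_h Time points in hours.
#' @param intensity Fluorescence intensities (a.u., finite).
#' @param sample Sample label.
#' @return Data.frame of class `tht_trace` with attribute `sample`.
#' @export
tht_trace <- function(time_h, intensity, sample = "unlabeled") {
  stopifnot(length(time_h) == length(intensity))
  if (length(time_h) < 10L || any(diff(time_h) <= 0)) {
    stop_fibrilnmr("need >= 10 strictly increasing time points",
                   "fibrilnmr_bad_input")
  }
  if (!all(is.finite(intensity))) {
    stop_fibrilnmr("intensities must be finite", "fibrilnmr_bad_input")
  }
  df <- data.frame(time_h = as.numeric(time_h), intensity = as.numeric(intensity))
  attr(df, "sample") <- sample
  class(df) <- c("tht_trace", "data.frame")
  df
}

# 4-parameter logistic used throughout the kinetics module.
sigmoid_model <- function(t, F0, A, t50, tau) {
  F0 + A / (1 + exp(-(t - t50) / tau))
}

#' Fit a 4-parameter sigmoid to a ThT trace
#'
#' Least-squares fit of \eqn{F(t) = F_0 + A / (1 + e^{-(t - t_{50})/\tau})}:
#' baseline, amplitude, midpoint and transition time. Start values come from
#' the data (baseline = minimum, amplitude = range, midpoint = first
#' half-range crossing, tau = time span / 10); standard errors come from the
#' local curvature of the least-squares objective. A trace with no visible
#' transition (range below 3x the point-to-point noise estimate) is rejected
#' rather than fitted.
#'
#' @param trace A [tht_trace()].
#' @return List of class `sigmoid_fit`: `F0`, `A`, `t50_h`, `tau_h`,
#'   `lag_h` (= t50 - 2 tau), `se` (named vector incl. `lag_h`), `converged`,
#'   `sample`.
#' @export
fit_tht <- function(trace) {
  stopifnot(inherits(trace, "tht_trace"))
  t <- trace$time_h
  y <- trace$intensity
  noise <- stats::sd(diff(y)) / sqrt(2)
  # transition detection on the denoised trace: the raw range of a flat
  # noisy trace already spans ~5 sigma, so the range is taken after a
  # running-median smooth
  k <- min(11L, if (length(y) %% 2L == 0L) length(y) - 1L else length(y))
  rng <- diff(range(stats::runmed(y, k)))
  if (rng < 3 * noise) {
    stop_fibrilnmr("no transition: intensity range below 3x noise estimate",
                   "fibrilnmr_no_transition")
  }
  half <- min(y) + diff(range(y)) / 2
  t50_0 <- t[which(y >= half)[1]]
  start <- list(F0 = min(y), A = diff(range(y)), t50 = t50_0,
                tau = diff(range(t)) / 10)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(par) {
                         y - sigmoid_model(t, par$F0, par$A, par$t50, par$tau)
                       },
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  # the logistic is invariant under (F0, A, tau) -> (F0 + A, -A, -tau);
  # canonicalize so the reported amplitude and transition time are positive
  canon <- !is.null(fit) && fit$par$A < 0 && fit$par$tau < 0
  if (canon) {
    fit$par$F0 <- fit$par$F0 + fit$par$A
    fit$par$A <- -fit$par$A
    fit$par$tau <- -fit$par$tau
  }
  if (is.null(fit) || !(fit$info %in% 1:4) ||
      fit$par$A <= 0 || fit$par$tau <= 0) {
    out <- list(F0 = NA_real_, A = NA_real_, t50_h = NA_real_, tau_h = NA_real_,
                lag_h = NA_real_, se = c(F0 = NA, A = NA, t50_h = NA,
                                         tau_h = NA, lag_h = NA),
                converged = FALSE, sample = attr(trace, "sample"))
    class(out) <- "sigmoid_fit"
    return(out)
  }
  cf <- unlist(fit$par)
  # covariance from the Gauss-Newton curvature at the optimum
  vc <- tryCatch({
    resvar <- sum(fit$fvec^2) / (length(y) - 4L)
    v <- chol2inv(chol(fit$hessian)) * resvar
    if (canon) {
      tr <- diag(4)
      tr[1, 2] <- 1
      tr[2, 2] <- -1
      tr[4, 4] <- -1
      v <- tr %*% v %*% t(tr)
    }
    v
  }, error = function(e) matrix(NA_real_, 4, 4))
  se <- sqrt(pmax(diag(vc), 0))
  # lag = t50 - 2 tau; first-order error propagation including covariance
  se_lag <- if (all(is.finite(vc[3:4, 3:4]))) {
    sqrt(vc[3, 3] + 4 * vc[4, 4] - 4 * vc[3, 4])
  } else {
    NA_real_
  }
  out <- list(F0 = unname(cf["F0"]), A = unname(cf["A"]),
              t50_h = unname(cf["t50"]), tau_h = unname(cf["tau"]),
              lag_h = unname(cf["t50"] - 2 * cf["tau"]),
              se = c(F0 = unname(se[1]), A = unname(se[2]),
                     t50_h = unname(se[3]), tau_h = unname(se[4]),
                     lag_h = se_lag),
              converged = TRUE, sample = attr(trace, "sample"))
  class(out) <- "sigmoid_fit"
  out
}

#' Lag time of a fitted fibrillation sigmoid
#'
#' The tangent-intercept lag of the logistic: the intercept of the tangent at
#' the midpoint with the baseline, \eqn{t_{lag} = t_{50} - 2\tau}.
#'
#' @param fit A converged `sigmoid_fit`.
#' @return List with `lag_h` and its propagated standard error `se_h`.
#' @export
lag_time <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged)) {
    stop_fibrilnmr("sigmoid fit did not converge", "fibrilnmr_not_converged")
  }
  list(lag_h = fit$t50_h - 2 * fit$tau_h, se_h = unname(fit$se["lag_h"]))
}

#' Read / write ThT traces (CSV dialect)
#'
#' Columns `time_h, intensity` (single well) or `time_h, intensity_1, ...`
#' (multi-well plate) plus a `# sample:` comment line. The multi-well reader
#' returns a list of traces, one per well.
#'
#' @param path File path.
#' @return Reader: a [tht_trace()] or list of them; writer: `path` invisibly.
#' @export
read_tht_trace <- function(path) {
  meta <- read_comment_meta(path)
  sample <- if (!is.null(meta$sample)) meta$sample else "unlabeled"
  df <- read_table_skip_comments(path, sep = ",")
  wells <- setdiff(names(df), "time_h")
  if (length(wells) == 1L) {
    return(tht_trace(df$time_h, df[[wells]], sample = sample))
  }
  out <- lapply(wells, function(w) {
    tht_trace(df$time_h, df[[w]], sample = paste(sample, w, sep = "."))
  })
  names(out) <- wells
  out
}

#' @rdname read_tht_trace
#' @param traces A [tht_trace()] or a list of traces on a common time grid.
#' @param sample Sample label written to the `# sample:` header.
#' @export
write_tht_trace <- function(traces, path, sample = NULL) {
  if (inherits(traces, "tht_trace")) traces <- list(intensity = traces)
  if (is.null(sample)) sample <- attr(traces[[1]], "sample")
  df <- data.frame(time_h = sprintf("%.4f", traces[[1]]$time_h))
  if (length(traces) == 1L) {
    df$intensity <- sprintf("%.6f", traces[[1]]$intensity)
  } else {
    for (i in seq_along(traces)) {
      df[[sprintf("intensity_%d", i)]] <- sprintf("%.6f", traces[[i]]$intensity)
    }
  }
  write_table_with_meta(df, path, meta = list(sample = sample), sep = ",")
}
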