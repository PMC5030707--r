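# Seeded generators for every input type the analysis modules read. Each
# noiseless generator is exactly the corresponding forward model; noise is
# additive Gaussian except ThT traces, where fluorescence noise scales with
# the signal (multiplicative). One integer seed per call, no hidden RNG
# state.

#' Secondary-structure template for synthetic shift tables
#'
#' Declares, per residue, a secondary-structure label and the magnitude of
#' the Calpha/Cbeta secondary-shift offsets that label imprints on the
#' random-coil value.
#'
#' @param sequence Named character vector of one-letter residue codes (names
#'   = residue indices), e.g. from [abeta_sequence()].
#' @param labels Character vector, same length, each `"beta"`, `"helix"` or
#'   `"coil"`.
#' @param ca_offset_ppm,cb_offset_ppm Offset magnitudes (ppm, >= 0) applied
#'   for beta/helix residues. Beta: CA down, CB up; helix mirrored; coil
#'   zero.
#' @param noise_sd_ppm Gaussian noise sd added to every emitted shift (>= 0).
#' @return List of class `structure_template`.
#' @export
structure_template <- function(sequence, labels, ca_offset_ppm = 2.0,
                               cb_offset_ppm = 2.0, noise_sd_ppm = 0.3) {
  stopifnot(length(sequence) == length(labels),
            ca_offset_ppm >= 0, cb_offset_ppm >= 0, noise_sd_ppm >= 0)
  if (!all(labels %in% c("beta", "helix", "coil"))) {
    stop_fibrilnmr("labels must be beta, helix or coil", "fibrilnmr_bad_input")
  }
  if (is.null(names(sequence))) names(sequence) <- as.character(seq_along(sequence))
  structure(list(sequence = sequence, labels = labels,
                 ca_offset_ppm = ca_offset_ppm, cb_offset_ppm = cb_offset_ppm,
                 noise_sd_ppm = noise_sd_ppm),
            class = "structure_template")
}

#' Amyloid-beta fibril template: beta strands at 10-22 and 30-38
#'
#' The fibril fold places two beta strands around residues 10-22 and 30-38
#' with the remaining residues (notably the N-terminus) disordered; this
#' helper labels the chosen peptide accordingly.
#'
#' @param variant Passed to [abeta_sequence()].
#' @inheritParams structure_template
#' @return A [structure_template()].
#' @export
abeta_fibril_template <- function(variant = c("wt", "pglu3"),
                                  ca_offset_ppm = 2.0, cb_offset_ppm = 2.0,
                                  noise_sd_ppm = 0.3) {
  seq <- abeta_sequence(variant)
  idx <- as.integer(names(seq))
  labels <- ifelse((idx >= 10 & idx <= 22) | (idx >= 30 & idx <= 38),
                   "beta", "coil")
  structure_template(seq, labels, ca_offset_ppm, cb_offset_ppm, noise_sd_ppm)
}

#' Generate a synthetic chemical-shift table
#'
#' Inverse of the secondary-shift analysis: for each residue the emitted
#' Calpha is the random-coil value minus (beta) or plus (helix) the CA
#' offset, Cbeta mirrored, coil unshifted; Gaussian noise on top. Glycine
#' emits no CB row.
#'
#' @param template A [structure_template()].
#' @param rc A [random_coil_table()].
#' @param seed Integer seed.
#' @param skip_missing Residue types absent from `rc` (e.g. pyroglutamate
#'   `"Z"`) emit no rows instead of erroring. Default `FALSE`: reject,
#'   naming the residue.
#' @return A [shift_table()].
#' @export
gen_shift_table <- function(template, rc = random_coil_table(), seed = 1L,
                            skip_missing = FALSE) {
  stopifnot(inherits(template, "structure_template"))
  types <- unique(template$sequence)
  known <- types %in% rc$res_type
  if (any(!known) && !skip_missing) {
    bad <- which(template$sequence %in% types[!known])[1]
    stop_fibrilnmr(sprintf(
      "residue type '%s' (residue %s) missing from random-coil table",
      template$sequence[bad], names(template$sequence)[bad]),
      "fibrilnmr_missing_reference")
  }
  rows <- list()
  for (i in seq_along(template$sequence)) {
    type <- template$sequence[[i]]
    if (!(type %in% rc$res_type)) next
    idx <- as.integer(names(template$sequence)[i])
    lab <- template$labels[i]
    sgn <- switch(lab, beta = -1, helix = 1, coil = 0)
    ca <- rc_lookup(rc, type, "CA") + sgn * template$ca_offset_ppm
    rows[[length(rows) + 1L]] <- data.frame(res_index = idx, res_type = type,
                                            nucleus = "CA", shift_ppm = ca,
                                            stringsAsFactors = FALSE)
    cb_rc <- rc_lookup(rc, type, "CB")
    if (!is.na(cb_rc)) {
      cb <- cb_rc - sgn * template$cb_offset_ppm
      rows[[length(rows) + 1L]] <- data.frame(res_index = idx, res_type = type,
                                              nucleus = "CB", shift_ppm = cb,
                                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (template$noise_sd_ppm > 0) {
    df$shift_ppm <- df$shift_ppm +
      with_seed(seed, stats::rnorm(nrow(df), 0, template$noise_sd_ppm))
  }
  shift_table(df$res_index, df$res_type, df$nucleus, df$shift_ppm,
              referencing = "synthetic (matches bundled random-coil table)")
}

#' Generate a synthetic DIPSHIFT dephasing curve
#'
#' Forward-simulates the dephasing of a site with order parameter `S`
#' (effective coupling `S * scaling * rigid_coupling_hz`) and adds Gaussian
#' noise. With `noise_sd = 0` the output equals [simulate_dephasing()]
#' exactly.
#'
#' @param S Order parameter in [0, 1].
#' @param rigid_coupling_hz Rigid-limit C-H coupling (default 22700 Hz).
#' @param scaling Homonuclear decoupling scale factor (default 1/sqrt(3)).
#' @param mas_rate_hz MAS rate (default 5000 Hz).
#' @param n_points t1 samples over one rotor period (>= 8).
#' @param noise_sd Gaussian noise sd on the normalized intensities.
#' @param seed Integer seed.
#' @param powder Powder scheme for the forward model.
#' @param site Site label.
#' @return A [dipshift_curve()].
#' @export
gen_dipshift_curve <- function(S, rigid_coupling_hz = 22700,
                               scaling = 1 / sqrt(3), mas_rate_hz = 5000,
                               n_points = 16L, noise_sd = 0, seed = 1L,
                               powder = powder_scheme(), site = "synthetic") {
  if (S < 0 || S > 1) {
    stop_fibrilnmr("order parameter S must lie in [0, 1]", "fibrilnmr_bad_input")
  }
  stopifnot(mas_rate_hz > 0, n_points >= 8L, noise_sd >= 0)
  curve <- simulate_dephasing(S * scaling * rigid_coupling_hz, mas_rate_hz,
                              n_points, powder, site = site)
  if (noise_sd > 0) {
    curve$intensity <- curve$intensity +
      with_seed(seed, stats::rnorm(nrow(curve), 0, noise_sd))
  }
  curve
}

#' Kinetics preset for synthetic ThT traces
#'
#' @param F0 Baseline fluorescence (a.u.).
#' @param A Amplitude (a.u., > 0).
#' @param t50_h Sigmoid midpoint (h).
#' @param tau_h Transition time (h, > 0).
#' @param time_h Strictly increasing time grid (h).
#' @param noise_frac Multiplicative noise fraction (>= 0); default 0.02, a
#'   typical plate-reader level.
#' @param seed Integer seed.
#' @param sample Sample label.
#' @return List of class `kinetics_preset`.
#' @export
kinetics_preset <- function(F0 = 1, A = 10, t50_h = 13, tau_h = 3,
                            time_h = seq(0, 65, by = 0.5), noise_frac = 0.02,
                            seed = 1L, sample = "synthetic") {
  stopifnot(A > 0, tau_h > 0, noise_frac >= 0)
  if (any(diff(time_h) <= 0)) {
    stop_fibrilnmr("time grid must be strictly increasing", "fibrilnmr_bad_input")
  }
  structure(list(F0 = F0, A = A, t50_h = t50_h, tau_h = tau_h, time_h = time_h,
                 noise_frac = noise_frac, seed = as.integer(seed),
                 sample = sample),
            class = "kinetics_preset")
}

#' Generate a synthetic ThT fluorescence trace
#'
#' \eqn{F(t) = F_0 + A/(1 + e^{-(t - t_{50})/\tau})} on the preset's grid,
#' multiplied by `(1 + eps_t)` with Gaussian `eps_t` of sd `noise_frac`
#' (fluorescence noise scales with signal).
#'
#' @param preset A [kinetics_preset()].
#' @return A [tht_trace()].
#' @export
gen_tht_trace <- function(preset) {
  stopifnot(inherits(preset, "kinetics_preset"))
  f <- sigmoid_model(preset$time_h, preset$F0, preset$A, preset$t50_h,
                     preset$tau_h)
  if (preset$noise_frac > 0) {
    f <- f * (1 + with_seed(preset$seed,
                            stats::rnorm(length(f), 0, preset$noise_frac)))
  }
  tht_trace(preset$time_h, f, sample = preset$sample)
}

#' Generate a synthetic 2D cross-peak list
#'
#' Realizes a declared interresidual contact set on top of the trivially
#' present intra-residue peaks: one cross peak at the two atoms' assigned
#' shifts plus its symmetric (transposed) partner per contact, plus both
#' orientations of every intra-residue atom pair, all with Gaussian
#' coordinate jitter.
#'
#' @param assignments A [shift_table()] providing the shift of every atom
#'   referenced.
#' @param contacts Data.frame with columns `res_i`, `atom_i`, `res_j`,
#'   `atom_j` (may be empty).
#' @param noise_sd Coordinate jitter sd in ppm.
#' @param seed Integer seed.
#' @param mixing_ms Mixing time metadata (default 500 ms, long enough for
#'   ~6 Angstrom contacts).
#' @return A [peak_list()].
#' @export
gen_peaklist <- function(assignments, contacts = empty_contact_spec(),
                         noise_sd = 0, seed = 1L, mixing_ms = 500) {
  stopifnot(inherits(assignments, "shift_table"), noise_sd >= 0)
  asg <- assignments[assignments$polymorph == 1L, , drop = FALSE]
  lookup <- function(res, atom) {
    i <- which(asg$res_index == res & asg$nucleus == atom)
    if (!length(i)) {
      stop_fibrilnmr(sprintf("contact references unassigned atom %d.%s", res, atom),
                     "fibrilnmr_missing_assignment")
    }
    asg$shift_ppm[i[1]]
  }
  w1 <- numeric(0)
  w2 <- numeric(0)
  inten <- numeric(0)
  if (nrow(contacts) > 0) {
    for (k in seq_len(nrow(contacts))) {
      da <- lookup(contacts$res_i[k], contacts$atom_i[k])
      db <- lookup(contacts$res_j[k], contacts$atom_j[k])
      w1 <- c(w1, da, db)
      w2 <- c(w2, db, da)
      inten <- c(inten, 1, 1)
    }
  }
  for (res in unique(asg$res_index)) {
    atoms <- which(asg$res_index == res)
    if (length(atoms) < 2L) next
    pairs <- utils::combn(atoms, 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      w1 <- c(w1, asg$shift_ppm[a], asg$shift_ppm[b])
      w2 <- c(w2, asg$shift_ppm[b], asg$shift_ppm[a])
      inten <- c(inten, 5, 5)
    }
  }
  if (noise_sd > 0 && length(w1)) {
    jitter <- with_seed(seed, stats::rnorm(2 * length(w1), 0, noise_sd))
    w1 <- w1 + jitter[seq_along(w1)]
    w2 <- w2 + jitter[length(w1) + seq_along(w2)]
  }
  peak_list(w1, w2, inten, mixing_ms = mixing_ms)
}

#' @rdname gen_peaklist
#' @export
empty_contact_spec <- function() {
  data.frame(res_i = integer(), atom_i = character(), res_j = integer(),
             atom_j = character(), stringsAsFactors = FALSE)
}

#' Diffraction preset for synthetic radial profiles
#'
#' @param centers_deg Peak centers in 2-theta degrees; must lie inside the
#'   grid.
#' @param fwhm_deg Per-peak full widths at half maximum (> 0).
#' @param amplitude Per-peak amplitudes.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise sd (0 = none).
#' @param wavelength_A Wavelength in Angstrom (> 0).
#' @param grid_deg 2-theta grid in degrees.
#' @return List of class `diffraction_preset`.
#' @export
diffraction_preset <- function(centers_deg = c(8.585, 18.881),
                               fwhm_deg = c(1.0, 0.6),
                               amplitude = c(40, 100), background = 10,
                               noise_sd = 0, wavelength_A = 1.5418,
                               grid_deg = seq(2, 35, by = 0.05)) {
  fwhm_deg <- rep_len(fwhm_deg, length(centers_deg))
  amplitude <- rep_len(amplitude, length(centers_deg))
  stopifnot(all(fwhm_deg > 0), wavelength_A > 0, noise_sd >= 0)
  if (length(centers_deg) &&
      (any(centers_deg < min(grid_deg)) || any(centers_deg > max(grid_deg)))) {
    stop_fibrilnmr("all peak centers must lie inside the 2-theta grid",
                   "fibrilnmr_bad_input")
  }
  structure(list(centers_deg = centers_deg, fwhm_deg = fwhm_deg,
                 amplitude = amplitude, background = background,
                 noise_sd = noise_sd, wavelength_A = wavelength_A,
                 grid_deg = grid_deg),
            class = "diffraction_preset")
}

#' Generate a synthetic radial diffraction profile
#'
#' Sum of Gaussian reflections on a constant background, with optional
#' additive noise.
#'
#' @param preset A [diffraction_preset()].
#' @param seed Integer seed.
#' @return A [radial_profile()].
#' @export
gen_xrd_profile <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "diffraction_preset"))
  x <- preset$grid_deg
  y <- rep(preset$background, length(x))
  for (k in seq_along(preset$centers_deg)) {
    sigma <- preset$fwhm_deg[k] / (2 * sqrt(2 * log(2)))
    y <- y + preset$amplitude[k] * exp(-(x - preset$centers_deg[k])^2 / (2 * sigma^2))
  }
  if (preset$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(x), 0, preset$noise_sd))
  }
  radial_profile(x, y, wavelength_A = preset$wavelength_A)
}
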