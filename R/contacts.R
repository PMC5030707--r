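#' 2D cross-peak list
#'
#' Peaks from a 13C-13C correlation spectrum (e.g. DARR): two chemical-shift
#' coordinates and an intensity. Long mixing times make cross peaks report
#' carbon-carbon proximities up to roughly 6 Angstrom.
#'
#' @param w1_ppm,w2_ppm Peak coordinates (ppm, finite).
#' @param intensity Peak intensities (> 0).
#' @param mixing_ms Mixing time in milliseconds (metadata).
#' @return Data.frame of class `peak_list` with attribute `mixing_ms`.
#' @export
peak_list <- function(w1_ppm, w2_ppm, intensity = 1, mixing_ms = NA_real_) {
  n <- length(w1_ppm)
  stopifnot(length(w2_ppm) == n)
  intensity <- rep_len(intensity, n)
  if (n > 0 && (!all(is.finite(w1_ppm)) || !all(is.finite(w2_ppm)))) {
    stop_fibrilnmr("peak coordinates must be finite", "fibrilnmr_bad_input")
  }
  if (any(intensity <= 0)) {
    stop_fibrilnmr("peak intensities must be > 0", "fibrilnmr_bad_input")
  }
  df <- data.frame(w1_ppm = as.numeric(w1_ppm), w2_ppm = as.numeric(w2_ppm),
                   intensity = as.numeric(intensity))
  attr(df, "mixing_ms") <- mixing_ms
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Detect interresidual contacts from a cross-peak list
#'
#' A cross peak supports the atom pair (a, b) when its two coordinates match
#' the two assigned shifts within `tol` in either orientation. Contacts are
#' reported once per residue/atom pair with the symmetric (transposed) peaks
#' merged, only for residue pairs at sequence separation >= `min_seq_sep`
#' (intra-residue and sequential DARR peaks are trivially present and carry
#' no tertiary information). Diagonal peaks (|w1 - w2| < tol) are ignored.
#' Peaks matching several atom pairs within tolerance support all of them and
#' the resulting contacts are marked ambiguous.
#'
#' @param peaks A [peak_list()].
#' @param assignments A [shift_table()] of assigned shifts (polymorph rank 1
#'   used).
#' @param tol Matching tolerance per dimension in ppm (> 0); default 0.3.
#' @param min_seq_sep Minimum |i - j| between residues; default 2.
#' @return Data.frame of class `contact_list`: `res_i`, `res_j` (res_i <
#'   res_j), `type_i`, `type_j`, `atom_i`, `atom_j`, `n_peaks`,
#'   `mean_match_ppm`, `ambiguous`. Zero rows when nothing matches.
#' @export
detect_contacts <- function(peaks, assignments, tol = 0.3, min_seq_sep = 2L) {
  stopifnot(inherits(peaks, "peak_list"), inherits(assignments, "shift_table"),
            tol > 0)
  if (nrow(assignments) == 0L) {
    stop_fibrilnmr("empty assignment table", "fibrilnmr_bad_input")
  }
  asg <- assignments[assignments$polymorph == 1L, , drop = FALSE]
  empty <- data.frame(res_i = integer(), res_j = integer(),
                      type_i = character(), type_j = character(),
                      atom_i = character(), atom_j = character(),
                      n_peaks = integer(), mean_match_ppm = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("contact_list", "data.frame")
  if (nrow(peaks) == 0L) {
    return(empty)
  }
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    w1 <- peaks$w1_ppm[p]
    w2 <- peaks$w2_ppm[p]
    if (abs(w1 - w2) < tol) next # diagonal: uninformative autocorrelation
    m1 <- which(abs(asg$shift_ppm - w1) <= tol)
    m2 <- which(abs(asg$shift_ppm - w2) <= tol)
    if (!length(m1) || !length(m2)) next
    cand <- expand.grid(a = m1, b = m2)
    cand <- cand[abs(asg$res_index[cand$a] - asg$res_index[cand$b]) >= min_seq_sep, ,
                 drop = FALSE]
    if (!nrow(cand)) next
    amb <- nrow(cand) > 1L
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]
      b <- cand$b[k]
      # canonical orientation: lower residue index first
      if (asg$res_index[a] > asg$res_index[b]) {
        tmp <- a; a <- b; b <- tmp
        d <- (abs(asg$shift_ppm[b] - w1) + abs(asg$shift_ppm[a] - w2)) / 2
      } else {
        d <- (abs(asg$shift_ppm[a] - w1) + abs(asg$shift_ppm[b] - w2)) / 2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        res_i = asg$res_index[a], res_j = asg$res_index[b],
        type_i = asg$res_type[a], type_j = asg$res_type[b],
        atom_i = asg$nucleus[a], atom_j = asg$nucleus[b],
        match_ppm = d, ambiguous = amb, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(empty)
  }
  hits <- do.call(rbind, rows)
  key <- paste(hits$res_i, hits$res_j, hits$atom_i, hits$atom_j)
  agg <- lapply(split(hits, key), function(h) {
    data.frame(res_i = h$res_i[1], res_j = h$res_j[1],
               type_i = h$type_i[1], type_j = h$type_j[1],
               atom_i = h$atom_i[1], atom_j = h$atom_j[1],
               n_peaks = nrow(h), mean_match_ppm = mean(h$match_ppm),
               ambiguous = any(h$ambiguous), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$res_i, out$res_j, out$atom_i, out$atom_j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_list", "data.frame")
  out
}

#' Classify the fibrillation stage from diagnostic contacts
#'
#' Mature amyloid-beta fibrils show the interstrand Phe19-Leu34 side-chain
#' contact but lack the Glu22-Ile31 contact; the latter is diagnostic of
#' earlier assembly stages (oligomers, protofibrils). The call is:
#' `"intermediate"` whenever (22, 31) is present; `"mature"` when (19, 34)
#' is present and (22, 31) absent; `"indeterminate"` when neither is seen.
#'
#' @param found A `contact_list` from [detect_contacts()].
#' @return List with `stage` in `c("mature", "intermediate",
#'   "indeterminate")` and `rationale` (character vector naming the
#'   diagnostic contacts that drove the call).
#' @export
classify_stage <- function(found) {
  pair_present <- function(i, j) {
    any(found$res_i == i & found$res_j == j)
  }
  f19l34 <- pair_present(19L, 34L)
  e22i31 <- pair_present(22L, 31L)
  if (e22i31) {
    stage <- "intermediate"
    why <- c("Glu22-Ile31 contact present: diagnostic of oligomers/protofibrils",
             if (f19l34) "Phe19-Leu34 contact also present")
  } else if (f19l34) {
    stage <- "mature"
    why <- c("Phe19-Leu34 interstrand contact present",
             "Glu22-Ile31 contact absent (as in mature fibrils)")
  } else {
    stage <- "indeterminate"
    why <- "neither diagnostic contact (Phe19-Leu34, Glu22-Ile31) observed"
  }
  list(stage = stage, rationale = why)
}

#' Read / write 2D peak lists (TSV dialect)
#'
#' Columns `w1_ppm  w2_ppm  intensity` (Sparky-export compatible) with the
#' mixing time in a `# mixing_ms:` comment line.
#'
#' @param path File path.
#' @return Reader: a [peak_list()]; writer: `path` invisibly.
#' @export
read_peak_list <- function(path) {
  meta <- read_comment_meta(path)
  df <- read_table_skip_comments(path, sep = "\t")
  peak_list(df$w1_ppm, df$w2_ppm,
            intensity = if (!is.null(df$intensity)) df$intensity else 1,
            mixing_ms = if (!is.null(meta$mixing_ms)) as.numeric(meta$mixing_ms) else NA_real_)
}

#' @rdname read_peak_list
#' @param peaks A [peak_list()].
#' @export
write_peak_list <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  df <- data.frame(w1_ppm = sprintf("%.4f", peaks$w1_ppm),
                   w2_ppm = sprintf("%.4f", peaks$w2_ppm),
                   intensity = sprintf("%.4f", peaks$intensity))
  write_table_with_meta(df, path, meta = list(mixing_ms = attr(peaks, "mixing_ms")),
                        sep = "\t")
}
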