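#' Secondary chemical shifts relative to random coil
#'
#' Computes, per record, the secondary shift
#' \eqn{\Delta\delta = \delta_{obs} - \delta_{rc}} after applying the table's
#' referencing offset. Records whose (residue type, nucleus) has no entry in
#' the random-coil table -- glycine CB never exists, and pyroglutamate has no
#' random-coil reference at all -- are skipped with a message rather than an
#' error.
#'
#' @param table A [shift_table()].
#' @param rc A [random_coil_table()].
#' @param quiet Suppress the skipped-record message.
#' @return A data.frame of class `secondary_shift_table` with columns
#'   `res_index`, `res_type`, `nucleus`, `delta_ppm`, `polymorph`.
#' @export
secondary_shift <- function(table, rc = random_coil_table(), quiet = FALSE) {
  stopifnot(inherits(table, "shift_table"))
  if (nrow(table) == 0L) {
    stop_fibrilnmr("empty shift table", "fibrilnmr_bad_input")
  }
  corrected <- table$shift_ppm + attr(table, "ref_offset_ppm")
  ref <- rc_lookup(rc, table$res_type, table$nucleus)
  skip <- is.na(ref)
  if (any(skip) && !quiet) {
    missing <- unique(paste0(table$res_type[skip], table$res_index[skip], ":",
                             table$nucleus[skip]))
    message("secondary_shift: skipping records with no random-coil reference: ",
            paste(missing, collapse = ", "))
  }
  out <- data.frame(res_index = table$res_index[!skip],
                    res_type = table$res_type[!skip],
                    nucleus = table$nucleus[!skip],
                    delta_ppm = corrected[!skip] - ref[!skip],
                    polymorph = table$polymorph[!skip],
                    stringsAsFactors = FALSE)
  class(out) <- c("secondary_shift_table", "data.frame")
  out
}

#' Referencing-independent secondary-structure metric (Delta-Ca minus Delta-Cb)
#'
#' For every residue having both a CA and a CB secondary shift, returns
#' \eqn{\Delta\delta C\alpha - \Delta\delta C\beta} (ppm). Glycine never
#' appears (no CB), which is why cross-laboratory comparisons based on this
#' metric exclude Gly. A constant referencing offset on all carbon shifts
#' cancels exactly.
#'
#' @param sec A `secondary_shift_table`.
#' @param polymorph Which polymorph rank to use (default 1, the most intense
#'   form).
#' @return Named numeric vector, names = residue indices.
#' @export
delta_delta <- function(sec, polymorph = 1L) {
  stopifnot(inherits(sec, "secondary_shift_table"))
  sec <- sec[sec$polymorph == polymorph, , drop = FALSE]
  ca <- sec[sec$nucleus == "CA", c("res_index", "delta_ppm")]
  cb <- sec[sec$nucleus == "CB", c("res_index", "delta_ppm")]
  shared <- intersect(ca$res_index, cb$res_index)
  shared <- sort(shared)
  out <- ca$delta_ppm[match(shared, ca$res_index)] -
    cb$delta_ppm[match(shared, cb$res_index)]
  names(out) <- as.character(shared)
  out
}

#' Classify per-residue secondary structure from secondary shifts
#'
#' Sign convention: negative \eqn{\Delta C\alpha} together with positive
#' \eqn{\Delta C\beta} reports beta-strand; the mirrored pattern reports
#' helix; values near zero report coil. Both deviations must exceed the
#' significance threshold. Glycine (no CB) is classified on the CA sign
#' alone when \eqn{|\Delta C\alpha|} exceeds the threshold, else coil.
#'
#' @param sec A `secondary_shift_table`.
#' @param threshold Significance cut in ppm (> 0); default 0.7 ppm, the
#'   conventional secondary-shift significance level.
#' @param polymorph Polymorph rank to classify (default 1).
#' @return Named character vector over residue indices with values in
#'   `c("beta", "helix", "coil")`.
#' @export
classify_ss <- function(sec, threshold = 0.7, polymorph = 1L) {
  stopifnot(inherits(sec, "secondary_shift_table"), threshold > 0)
  sec <- sec[sec$polymorph == polymorph, , drop = FALSE]
  idx <- sort(unique(sec$res_index[sec$nucleus %in% c("CA", "CB")]))
  ca <- sec[sec$nucleus == "CA", ]
  cb <- sec[sec$nucleus == "CB", ]
  dca <- ca$delta_ppm[match(idx, ca$res_index)]
  dcb <- cb$delta_ppm[match(idx, cb$res_index)]
  lab <- rep("coil", length(idx))
  both <- !is.na(dca) & !is.na(dcb)
  lab[both & dca <= -threshold & dcb >= threshold] <- "beta"
  lab[both & dca >= threshold & dcb <= -threshold] <- "helix"
  ca_only <- !is.na(dca) & is.na(dcb)
  lab[ca_only & dca <= -threshold] <- "beta"
  lab[ca_only & dca >= threshold] <- "helix"
  names(lab) <- as.character(idx)
  lab
}

#' Pearson correlation between two Delta-Delta maps
#'
#' Correlates two referencing-independent secondary-shift maps over the
#' residues they share, as used to compare one fibril preparation against
#' published datasets.
#'
#' @param a,b Named numeric vectors as returned by [delta_delta()].
#' @return List with `r` (Pearson coefficient) and `n` (matched residues).
#' @export
correlate_dd <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) {
    stop_fibrilnmr(sprintf("need >= 3 shared residues, got %d", length(shared)),
                   "fibrilnmr_too_few_shared")
  }
  x <- a[shared]
  y <- b[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_fibrilnmr("zero variance in one of the inputs; correlation undefined",
                   "fibrilnmr_zero_variance")
  }
  list(r = stats::cor(x, y), n = length(shared))
}
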