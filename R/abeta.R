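#' Amyloid-beta peptide sequences
#'
#' Returns the study peptides as one-letter residue vectors named by their
#' position on the canonical A-beta(1-40) numbering. The N-truncated
#' pyroglutamate variant pGlu3-A-beta(3-40) spans residues 3-40 with residue 3
#' typed as pyroglutamate (code `"Z"` in this package).
#'
#' @param variant `"wt"` for A-beta(1-40) or `"pglu3"` for pGlu3-A-beta(3-40).
#' @return Named character vector of one-letter residue codes; names are
#'   residue indices on the 1-40 numbering.
#' @examples
#' abeta_sequence("wt")[19]     # Phe19
#' abeta_sequence("pglu3")[1:3] # starts at pyroglutamate 3
#' @export
abeta_sequence <- function(variant = c("wt", "pglu3")) {
  variant <- match.arg(variant)
  full <- strsplit("DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV", "")[[1]]
  names(full) <- as.character(seq_along(full))
  if (variant == "wt") {
    return(full)
  }
  v <- full[3:40]
  v[1] <- "Z" # glutamate 3 cyclised to pyroglutamate
  v
}

#' Random-coil chemical-shift reference table
#'
#' Loads a (residue type, nucleus) -> random-coil shift lookup. The bundled
#' default carries the standard literature random-coil Calpha/Cbeta values
#' (DSS-referenced); glycine has no Cbeta and pyroglutamate (code `"Z"`) has
#' no reference entry at all, so downstream secondary-shift analysis skips it.
#'
#' @param file Path to a TSV with columns `res_type`, `nucleus`, `shift_ppm`
#'   and an optional `# provenance:` comment line. `NULL` loads the bundled
#'   table.
#' @return A data.frame of class `rc_table` with attribute `provenance`.
#' @export
random_coil_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "random_coil_ca_cb.tsv", package = "fibrilnmr",
                        mustWork = TRUE)
  }
  df <- read_table_skip_comments(file)
  need <- c("res_type", "nucleus", "shift_ppm")
  if (!all(need %in% names(df))) {
    stop_fibrilnmr("random-coil table must have columns res_type, nucleus, shift_ppm",
                   "fibrilnmr_bad_input")
  }
  df$shift_ppm <- as.numeric(df$shift_ppm)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  has_ca <- aa20 %in% df$res_type[df$nucleus == "CA"]
  if (!all(has_ca)) {
    stop_fibrilnmr(sprintf("random-coil table misses CA for: %s",
                           paste(aa20[!has_ca], collapse = ", ")),
                   "fibrilnmr_bad_input")
  }
  non_gly <- setdiff(aa20, "G")
  has_cb <- non_gly %in% df$res_type[df$nucleus == "CB"]
  if (!all(has_cb)) {
    stop_fibrilnmr(sprintf("random-coil table misses CB for: %s",
                           paste(non_gly[!has_cb], collapse = ", ")),
                   "fibrilnmr_bad_input")
  }
  meta <- read_comment_meta(file)
  attr(df, "provenance") <- if (!is.null(meta$provenance)) meta$provenance else "user-supplied"
  class(df) <- c("rc_table", "data.frame")
  df
}

# Internal lookup: NA when (type, nucleus) has no reference entry.
rc_lookup <- function(rc, res_type, nucleus) {
  key <- paste(rc$res_type, rc$nucleus)
  idx <- match(paste(res_type, nucleus), key)
  rc$shift_ppm[idx]
}
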