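#' Per-residue chemical-shift table
#'
#' The substrate of all secondary-structure analysis: one row per
#' (residue index, nucleus, polymorph rank) with the observed chemical shift.
#' Residue indices follow the A-beta(1-40) numbering. Where structural
#' polymorphism doubles a resonance, the additional value is stored with
#' `polymorph = 2` (rank 1 is the most intense form).
#'
#' @param res_index Integer residue indices (1-based).
#' @param res_type One-letter residue codes (`"Z"` = pyroglutamate).
#' @param nucleus Nucleus labels (`"CA"`, `"CB"`, `"CO"`, `"N"`, or side-chain
#'   carbon labels such as `"CD1"`).
#' @param shift_ppm Observed chemical shifts (ppm); must be finite.
#' @param polymorph Polymorph rank (integer >= 1), default 1.
#' @param referencing Free-text name of the referencing standard.
#' @param ref_offset_ppm Referencing offset added to all shifts before
#'   comparison with a random-coil table (default 0); makes TMS/DSS
#'   conversion explicit instead of silent.
#' @return A data.frame of class `shift_table` with attributes `referencing`
#'   and `ref_offset_ppm`.
#' @export
shift_table <- function(res_index, res_type, nucleus, shift_ppm,
                        polymorph = 1L, referencing = "unspecified",
                        ref_offset_ppm = 0) {
  df <- data.frame(res_index = as.integer(res_index),
                   res_type = as.character(res_type),
                   nucleus = as.character(nucleus),
                   shift_ppm = as.numeric(shift_ppm),
                   polymorph = as.integer(polymorph),
                   stringsAsFactors = FALSE)
  validate_shift_table(df)
  attr(df, "referencing") <- referencing
  attr(df, "ref_offset_ppm") <- as.numeric(ref_offset_ppm)
  class(df) <- c("shift_table", "data.frame")
  df
}

validate_shift_table <- function(df) {
  if (!all(is.finite(df$shift_ppm))) {
    stop_fibrilnmr("all chemical shifts must be finite", "fibrilnmr_bad_input")
  }
  if (any(df$polymorph < 1L)) {
    stop_fibrilnmr("polymorph rank must be >= 1", "fibrilnmr_bad_input")
  }
  if (any(df$res_type == "G" & df$nucleus == "CB")) {
    stop_fibrilnmr("glycine records cannot carry nucleus CB", "fibrilnmr_bad_input")
  }
  key <- paste(df$res_index, df$nucleus, df$polymorph)
  if (anyDuplicated(key)) {
    stop_fibrilnmr("duplicate (res_index, nucleus, polymorph) records",
                   "fibrilnmr_bad_input")
  }
  invisible(df)
}

#' Read / write a chemical-shift table (TSV dialect)
#'
#' Tab-separated UTF-8 with header
#' `res_index  res_type  nucleus  shift_ppm  polymorph` and optional
#' `# referencing:` / `# ref_offset_ppm:` comment lines.
#'
#' @param path File path.
#' @return For the reader, a `shift_table`; the writer returns `path`
#'   invisibly.
#' @export
read_shift_table <- function(path) {
  df <- read_table_skip_comments(path, sep = "\t")
  need <- c("res_index", "res_type", "nucleus", "shift_ppm")
  if (!all(need %in% names(df))) {
    stop_fibrilnmr(sprintf("shift table %s must have columns %s", path,
                           paste(need, collapse = ", ")), "fibrilnmr_bad_input")
  }
  if (is.null(df$polymorph)) df$polymorph <- 1L
  meta <- read_comment_meta(path)
  shift_table(df$res_index, df$res_type, df$nucleus, df$shift_ppm, df$polymorph,
              referencing = if (!is.null(meta$referencing)) meta$referencing else "unspecified",
              ref_offset_ppm = if (!is.null(meta$ref_offset_ppm)) as.numeric(meta$ref_offset_ppm) else 0)
}

#' @rdname read_shift_table
#' @param table A `shift_table`.
#' @export
write_shift_table <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  df <- as.data.frame(table)
  df$shift_ppm <- sprintf("%.3f", df$shift_ppm)
  write_table_with_meta(df, path,
                        meta = list(referencing = attr(table, "referencing"),
                                    ref_offset_ppm = attr(table, "ref_offset_ppm")),
                        sep = "\t")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> %d records, %d residues, referencing: %s (offset %+g ppm)\n",
              nrow(x), length(unique(x$res_index)),
              attr(x, "referencing"), attr(x, "ref_offset_ppm")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
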