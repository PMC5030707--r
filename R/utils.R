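# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring any pre-existing
# global state afterwards. Keeps generators free of hidden RNG coupling.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# `# key: value` comment headers used by all CSV/TSV dialects.
read_comment_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  com <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in com) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  meta
}

write_table_with_meta <- function(df, path, meta = list(), sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], trim = TRUE)), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_skip_comments <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Fixed-format number for byte-reproducible reports: 3 significant figures.
fmt3 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 3), format = "fg", flag = "#", digits = 3))
}

stop_fibrilnmr <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fibrilnmr_error", "error", "condition")))
}
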