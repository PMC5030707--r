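# End-to-end comparison pipeline: ties the per-figure analyses into one
# two-sample report (sample A vs sample B, canonically the pyroglutamate
# variant vs wildtype fibrils).

# Minimal flat-TOML config dialect: [section] headers, `key = value` lines,
# values are quoted strings, numbers, or true/false. Comments start with #.
parse_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (raw in lines) {
    ln <- sub("#.*$", "", raw)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) {
      stop_fibrilnmr(sprintf("cannot parse config line: %s", raw),
                     "fibrilnmr_bad_config")
    }
    key <- m[2]
    val <- trimws(m[3])
    parsed <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl("^[+-]?[0-9.eE+-]+$", val)) {
      as.numeric(val)
    } else {
      val
    }
    if (is.null(section)) {
      out[[key]] <- parsed
    } else {
      out[[section]][[key]] <- parsed
    }
  }
  out
}

#' Read a pipeline run configuration
#'
#' Flat-TOML config with one section per analysis (`[shifts]`, `[dipshift]`,
#' `[contacts]`, `[xrd]`, `[kinetics]`, `[run]`). Path values are resolved
#' relative to the config file; every referenced input must exist.
#'
#' @param path Config file path.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- parse_flat_toml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("sample_a", "sample_b", "dir_a", "dir_b", "peaks_a", "peaks_b",
                 "assignments_a", "assignments_b", "profile_a", "profile_b",
                 "trace_a", "trace_b", "rc_table")
  for (sec in names(cfg)) {
    if (!is.list(cfg[[sec]])) next
    for (key in intersect(names(cfg[[sec]]), path_keys)) {
      p <- cfg[[sec]][[key]]
      if (!file.exists(p)) p <- file.path(base, p)
      if (!file.exists(p)) {
        stop_fibrilnmr(sprintf("config %s.%s: input '%s' does not exist",
                               sec, key, cfg[[sec]][[key]]),
                       "fibrilnmr_bad_config")
      }
      cfg[[sec]][[key]] <- p
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

cfg_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

section_absent <- list(status = "input absent", data = NULL)

run_section <- function(expr) {
  tryCatch(list(status = "ok", data = expr),
           error = function(e) list(status = paste("rejected:", conditionMessage(e)),
                                    data = NULL))
}

#' Run the full two-sample comparison pipeline
#'
#' Executes, in fixed order, every analysis whose inputs are configured:
#' secondary shifts and classification per sample, cross-sample Delta-Delta
#' correlation, DIPSHIFT order-parameter comparison, DARR contact staging,
#' cross-beta diffraction classification, and ThT lag-time extraction.
#' Sections with missing inputs are marked `"input absent"`; a section whose
#' analysis rejects its input is reported as rejected and the pipeline
#' continues. Writes `report.tsv` (machine-readable) and `summary.txt` to
#' the output directory; both are byte-reproducible for a fixed config.
#'
#' @param config A `run_config` or path to one.
#' @param out_dir Output directory (default from `[run] out_dir`, else
#'   `"fibrilnmr-report"`). Created if needed.
#' @return List of class `comparison_report` (sections + parameters),
#'   invisibly; the written files are the primary artifact.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- cfg_get(config, "run", "out_dir", "fibrilnmr-report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  name_a <- cfg_get(config, "run", "sample_a_name", "sample_a")
  name_b <- cfg_get(config, "run", "sample_b_name", "sample_b")

  params <- list(
    ss_threshold_ppm = cfg_get(config, "shifts", "threshold", 0.7),
    contact_tol_ppm = cfg_get(config, "contacts", "tol", 0.3),
    min_seq_sep = cfg_get(config, "contacts", "min_seq_sep", 2),
    kappa = cfg_get(config, "dipshift", "kappa", 1 / sqrt(3)),
    delta_rigid_hz = cfg_get(config, "dipshift", "delta_rigid_hz", 22700),
    delta_grid_max_hz = cfg_get(config, "dipshift", "delta_grid_max_hz", 25000),
    xrd_min_prominence = cfg_get(config, "xrd", "min_prominence", 0.1),
    wavelength_A = cfg_get(config, "xrd", "wavelength_A", 1.5418),
    seed = cfg_get(config, "run", "seed", 1))

  rc <- if (!is.null(cfg_get(config, "shifts", "rc_table"))) {
    random_coil_table(cfg_get(config, "shifts", "rc_table"))
  } else {
    random_coil_table()
  }

  sections <- list()

  # -- secondary shifts + classification ---------------------------------
  sec_tabs <- list()
  shift_paths <- list(a = cfg_get(config, "shifts", "sample_a"),
                      b = cfg_get(config, "shifts", "sample_b"))
  if (is.null(shift_paths$a) && is.null(shift_paths$b)) {
    sections$shifts <- section_absent
  } else {
    sections$shifts <- run_section({
      res <- list()
      for (s in c("a", "b")) {
        if (is.null(shift_paths[[s]])) next
        tab <- read_shift_table(shift_paths[[s]])
        sec <- secondary_shift(tab, rc, quiet = TRUE)
        res[[s]] <- list(secondary = sec,
                         classes = classify_ss(sec, params$ss_threshold_ppm),
                         dd = delta_delta(sec))
      }
      res
    })
    if (sections$shifts$status == "ok") sec_tabs <- sections$shifts$data
  }

  # -- Delta-Delta correlation across the two samples --------------------
  if (length(sec_tabs) == 2L) {
    sections$correlation <- run_section(
      correlate_dd(sec_tabs$a$dd, sec_tabs$b$dd))
  } else {
    sections$correlation <- section_absent
  }

  # -- DIPSHIFT order parameters ----------------------------------------
  dip_dirs <- list(a = cfg_get(config, "dipshift", "dir_a"),
                   b = cfg_get(config, "dipshift", "dir_b"))
  if (is.null(dip_dirs$a) || is.null(dip_dirs$b)) {
    sections$dipshift <- section_absent
  } else {
    sections$dipshift <- run_section({
      fit_dir <- function(dir) {
        files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
        if (!length(files)) {
          stop_fibrilnmr(sprintf("no curve CSVs in %s", dir), "fibrilnmr_bad_input")
        }
        recs <- lapply(files, function(f) {
          fit <- fit_coupling(read_dipshift_curve(f), params$delta_grid_max_hz)
          order_parameter(fit, params$delta_rigid_hz, params$kappa)
        })
        do.call(rbind, recs)
      }
      ops_a <- fit_dir(dip_dirs$a)
      ops_b <- fit_dir(dip_dirs$b)
      c(compare_order_params(ops_a, ops_b), list(ops_a = ops_a, ops_b = ops_b))
    })
  }

  # -- DARR contacts and stage call -------------------------------------
  contact_in <- list(
    a = list(peaks = cfg_get(config, "contacts", "peaks_a"),
             asg = cfg_get(config, "contacts", "assignments_a")),
    b = list(peaks = cfg_get(config, "contacts", "peaks_b"),
             asg = cfg_get(config, "contacts", "assignments_b")))
  have_contacts <- vapply(contact_in, function(x) {
    !is.null(x$peaks) && !is.null(x$asg)
  }, logical(1))
  if (!any(have_contacts)) {
    sections$contacts <- section_absent
  } else {
    sections$contacts <- run_section({
      res <- list()
      for (s in c("a", "b")[have_contacts]) {
        found <- detect_contacts(read_peak_list(contact_in[[s]]$peaks),
                                 read_shift_table(contact_in[[s]]$asg),
                                 tol = params$contact_tol_ppm,
                                 min_seq_sep = params$min_seq_sep)
        res[[s]] <- list(contacts = found, stage = classify_stage(found))
      }
      res
    })
  }

  # -- X-ray cross-beta --------------------------------------------------
  xrd_paths <- list(a = cfg_get(config, "xrd", "profile_a"),
                    b = cfg_get(config, "xrd", "profile_b"))
  if (is.null(xrd_paths$a) && is.null(xrd_paths$b)) {
    sections$xrd <- section_absent
  } else {
    sections$xrd <- run_section({
      res <- list()
      for (s in c("a", "b")) {
        if (is.null(xrd_paths[[s]])) next
        refl <- detect_reflections(read_radial_profile(xrd_paths[[s]]),
                                   params$xrd_min_prominence)
        res[[s]] <- list(reflections = refl, call = classify_cross_beta(refl))
      }
      res
    })
  }

  # -- ThT kinetics ------------------------------------------------------
  kin_paths <- list(a = cfg_get(config, "kinetics", "trace_a"),
                    b = cfg_get(config, "kinetics", "trace_b"))
  if (is.null(kin_paths$a) && is.null(kin_paths$b)) {
    sections$kinetics <- section_absent
  } else {
    sections$kinetics <- run_section({
      res <- list()
      for (s in c("a", "b")) {
        if (is.null(kin_paths[[s]])) next
        traces <- read_tht_trace(kin_paths[[s]])
        if (inherits(traces, "tht_trace")) traces <- list(traces)
        lags <- vapply(traces, function(tr) lag_time(fit_tht(tr))$lag_h,
                       numeric(1))
        res[[s]] <- list(lag_h = mean(lags),
                         sd_h = if (length(lags) > 1L) stats::sd(lags) else NA_real_,
                         n_wells = length(lags))
      }
      res
    })
  }

  report <- list(sample_names = c(a = name_a, b = name_b),
                 parameters = params, sections = sections)
  class(report) <- "comparison_report"
  write_report_files(report, out_dir)
  invisible(report)
}

# Byte-reproducible report writers. All numbers go through fmt3 (3
# significant figures, explicit units in the labels).
write_report_files <- function(report, out_dir) {
  secs <- report$sections
  tsv <- c("# fibrilnmr comparison report", "## parameters\tvalue")
  p <- report$parameters
  for (k in names(p)) tsv <- c(tsv, sprintf("%s\t%s", k, fmt3(p[[k]])))
  tsv <- c(tsv, sprintf("sample_a\t%s", report$sample_names["a"]),
           sprintf("sample_b\t%s", report$sample_names["b"]))

  add_status <- function(tsv, name) {
    c(tsv, sprintf("## %s\t%s", name, secs[[name]]$status))
  }

  tsv <- add_status(tsv, "shifts")
  if (secs$shifts$status == "ok") {
    for (s in names(secs$shifts$data)) {
      cls <- secs$shifts$data[[s]]$classes
      tsv <- c(tsv, sprintf("classification_%s\t%s", s,
                            paste(sprintf("%s:%s", names(cls), cls), collapse = ",")))
      dd <- secs$shifts$data[[s]]$dd
      tsv <- c(tsv, sprintf("delta_delta_ppm_%s\t%s", s,
                            paste(sprintf("%s:%s", names(dd), fmt3(dd)), collapse = ",")))
    }
  }

  tsv <- add_status(tsv, "correlation")
  if (secs$correlation$status == "ok") {
    tsv <- c(tsv, sprintf("pearson_r\t%s", fmt3(secs$correlation$data$r)),
             sprintf("n_residues\t%d", secs$correlation$data$n))
  }

  tsv <- add_status(tsv, "dipshift")
  if (secs$dipshift$status == "ok") {
    cmpt <- secs$dipshift$data$table
    tsv <- c(tsv, "site\tS_a\tS_b\tdS\tflagged")
    for (i in seq_len(nrow(cmpt))) {
      tsv <- c(tsv, sprintf("%s\t%s\t%s\t%s\t%s", cmpt$site[i],
                            fmt3(cmpt$S_a[i]), fmt3(cmpt$S_b[i]),
                            fmt3(cmpt$dS[i]), cmpt$flagged[i]))
    }
    tsv <- c(tsv, sprintf("order_param_pearson_r\t%s", fmt3(secs$dipshift$data$r)))
  }

  tsv <- add_status(tsv, "contacts")
  if (secs$contacts$status == "ok") {
    for (s in names(secs$contacts$data)) {
      st <- secs$contacts$data[[s]]$stage
      found <- secs$contacts$data[[s]]$contacts
      pairs <- unique(sprintf("%s%d-%s%d", found$type_i, found$res_i,
                              found$type_j, found$res_j))
      tsv <- c(tsv, sprintf("stage_%s\t%s", s, st$stage),
               sprintf("contacts_%s\t%s", s, paste(pairs, collapse = ",")))
    }
  }

  tsv <- add_status(tsv, "xrd")
  if (secs$xrd$status == "ok") {
    for (s in names(secs$xrd$data)) {
      refl <- secs$xrd$data[[s]]$reflections
      tsv <- c(tsv, sprintf("cross_beta_%s\t%s", s,
                            secs$xrd$data[[s]]$call$cross_beta),
               sprintf("d_spacings_A_%s\t%s", s,
                       paste(fmt3(refl$d_A), collapse = ",")))
    }
  }

  tsv <- add_status(tsv, "kinetics")
  if (secs$kinetics$status == "ok") {
    for (s in names(secs$kinetics$data)) {
      k <- secs$kinetics$data[[s]]
      tsv <- c(tsv, sprintf("lag_h_%s\t%s", s, fmt3(k$lag_h)),
               sprintf("lag_sd_h_%s\t%s", s, fmt3(k$sd_h)),
               sprintf("n_wells_%s\t%d", s, k$n_wells))
    }
  }

  writeLines(tsv, file.path(out_dir, "report.tsv"))

  human <- c("fibrilnmr comparison report",
             sprintf("sample A: %s", report$sample_names["a"]),
             sprintf("sample B: %s", report$sample_names["b"]), "")
  for (name in names(secs)) {
    human <- c(human, sprintf("[%s] %s", name, secs[[name]]$status))
  }
  if (secs$correlation$status == "ok") {
    human <- c(human, sprintf(
      "secondary-structure correlation: r = %s over %d residues",
      fmt3(secs$correlation$data$r), secs$correlation$data$n))
  }
  if (secs$contacts$status == "ok") {
    for (s in names(secs$contacts$data)) {
      human <- c(human, sprintf("fibril stage (%s): %s", s,
                                secs$contacts$data[[s]]$stage$stage))
    }
  }
  if (secs$kinetics$status == "ok") {
    for (s in names(secs$kinetics$data)) {
      k <- secs$kinetics$data[[s]]
      human <- c(human, sprintf("lag time (%s): %s +/- %s h", s,
                                fmt3(k$lag_h), fmt3(k$sd_h)))
    }
  }
  writeLines(human, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes everything [run_pipeline()] needs to reproduce the full two-sample
#' comparison from synthetic data: full-sequence shift tables for the
#' pyroglutamate variant and wildtype (same fibril template, independent
#' noise), DIPSHIFT dephasing curves for eight backbone sites per sample
#' (with the Ile31 order parameter raised in the variant), three-well ThT
#' trace files with lag times 7 h and 43 h, mature-stage cross-peak lists
#' (Phe19-Leu34 present, Glu22-Ile31 absent), a cross-beta diffraction
#' profile per sample, a ready-to-run `config.toml`, and a `manifest.tsv`
#' listing every file with its generating parameters.
#'
#' @param output_dir Directory to write into (created if needed).
#' @param seed Integer seed; all per-file seeds derive from it.
#' @return Data.frame manifest (file, role, parameters), invisibly.
#' @export
make_fixtures <- function(output_dir, seed = 1L) {
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir) || file.access(output_dir, 2L) != 0L) {
    stop_fibrilnmr(sprintf("output directory '%s' is not writable", output_dir),
                   "fibrilnmr_bad_output_dir")
  }
  seed <- as.integer(seed)
  man <- list()
  note <- function(file, role, params) {
    man[[length(man) + 1L]] <<- data.frame(file = file, role = role,
                                           parameters = params,
                                           stringsAsFactors = FALSE)
  }

  # shift tables: same fibril template, independent noise per sample
  tab_a <- gen_shift_table(abeta_fibril_template("pglu3"), seed = seed,
                           skip_missing = TRUE)
  tab_b <- gen_shift_table(abeta_fibril_template("wt"), seed = seed + 1L)
  write_shift_table(tab_a, file.path(output_dir, "shifts_pglu3.tsv"))
  write_shift_table(tab_b, file.path(output_dir, "shifts_wt.tsv"))
  note("shifts_pglu3.tsv", "shift table A",
       sprintf("beta 10-22 & 30-38, offsets 2.0 ppm, noise 0.3 ppm, seed %d", seed))
  note("shifts_wt.tsv", "shift table B",
       sprintf("beta 10-22 & 30-38, offsets 2.0 ppm, noise 0.3 ppm, seed %d", seed + 1L))

  # DIPSHIFT curves: rigid core, mobile N-terminus; Ile31 raised in sample A
  sites <- c("F4.CA", "S8.CA", "V12.CA", "F19.CA", "E22.CA", "I31.CA",
             "L34.CA", "V36.CA")
  S_b <- c(0.40, 0.55, 0.90, 0.95, 0.90, 0.80, 0.95, 0.90)
  S_a <- c(0.55, 0.65, 0.90, 0.95, 0.90, 0.95, 0.95, 0.90)
  for (s in c("a", "b")) {
    dir_s <- file.path(output_dir, sprintf("dipshift_%s", s))
    dir.create(dir_s, showWarnings = FALSE)
    Sv <- if (s == "a") S_a else S_b
    for (k in seq_along(sites)) {
      curve <- gen_dipshift_curve(Sv[k], noise_sd = 0.02,
                                  seed = seed + 100L * (s == "b") + k,
                                  site = sites[k])
      write_dipshift_curve(curve,
                           file.path(dir_s, sprintf("%s.csv", sites[k])))
    }
    note(sprintf("dipshift_%s/", s), sprintf("dephasing curves %s", toupper(s)),
         "MAS 5 kHz, rigid 22.7 kHz, kappa 1/sqrt(3), 16 points, noise 0.02")
  }

  # ThT kinetics: 3 wells each; true lags 7 h (A) and 43 h (B)
  for (s in c("a", "b")) {
    t50 <- if (s == "a") 13 else 49
    wells <- lapply(1:3, function(w) {
      gen_tht_trace(kinetics_preset(t50_h = t50, tau_h = 3,
                                    seed = seed + 200L + 10L * (s == "b") + w,
                                    sample = sprintf("sample_%s", s)))
    })
    write_tht_trace(wells, file.path(output_dir, sprintf("tht_%s.csv", s)),
                    sample = sprintf("sample_%s", s))
    note(sprintf("tht_%s.csv", s), sprintf("ThT traces %s", toupper(s)),
         sprintf("F0=1, A=10, t50=%g h, tau=3 h (lag %g h), noise 2%%", t50, t50 - 6))
  }

  # DARR peak lists: mature preset for both samples
  mature <- data.frame(res_i = 19L, atom_i = "CB", res_j = 34L, atom_j = "CB",
                       stringsAsFactors = FALSE)
  pk_a <- gen_peaklist(tab_a, mature, noise_sd = 0.05, seed = seed + 300L)
  pk_b <- gen_peaklist(tab_b, mature, noise_sd = 0.05, seed = seed + 301L)
  write_peak_list(pk_a, file.path(output_dir, "darr_pglu3.tsv"))
  write_peak_list(pk_b, file.path(output_dir, "darr_wt.tsv"))
  note("darr_pglu3.tsv", "peak list A", "mature preset: F19-L34 in, E22-I31 out")
  note("darr_wt.tsv", "peak list B", "mature preset: F19-L34 in, E22-I31 out")

  # X-ray: cross-beta reflections at 4.7 and 10.3 Angstrom
  for (s in c("a", "b")) {
    prof <- gen_xrd_profile(diffraction_preset(noise_sd = 0.5),
                            seed = seed + 400L + (s == "b"))
    write_radial_profile(prof, file.path(output_dir, sprintf("xrd_%s.csv", s)))
    note(sprintf("xrd_%s.csv", s), sprintf("diffraction profile %s", toupper(s)),
         "reflections at 8.585 and 18.881 deg (d = 10.3, 4.7 A), Cu K-alpha")
  }

  cfg <- c(
    "[run]",
    'sample_a_name = "pGlu3-Abeta(3-40) fibrils"',
    'sample_b_name = "WT Abeta(1-40) fibrils"',
    sprintf("seed = %d", seed),
    "",
    "[shifts]",
    'sample_a = "shifts_pglu3.tsv"',
    'sample_b = "shifts_wt.tsv"',
    "threshold = 0.7",
    "",
    "[dipshift]",
    'dir_a = "dipshift_a"',
    'dir_b = "dipshift_b"',
    "delta_rigid_hz = 22700",
    sprintf("kappa = %.9f", 1 / sqrt(3)),
    "delta_grid_max_hz = 25000",
    "",
    "[contacts]",
    'peaks_a = "darr_pglu3.tsv"',
    'assignments_a = "shifts_pglu3.tsv"',
    'peaks_b = "darr_wt.tsv"',
    'assignments_b = "shifts_wt.tsv"',
    "tol = 0.3",
    "min_seq_sep = 2",
    "",
    "[xrd]",
    'profile_a = "xrd_a.csv"',
    'profile_b = "xrd_b.csv"',
    "min_prominence = 0.1",
    "",
    "[kinetics]",
    'trace_a = "tht_a.csv"',
    'trace_b = "tht_b.csv"')
  writeLines(cfg, file.path(output_dir, "config.toml"))
  note("config.toml", "pipeline config", "flat TOML, paths relative to bundle")

  manifest <- do.call(rbind, man)
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
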