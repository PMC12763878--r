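MEAS_COLS <- c("specimen_id", "well_id", "design", "t_h", "treatment",
               "phase_start_h", "phase_end_h", "analyte", "conc_pg_ml",
               "censor")

#' Read a long-format measurement table into well series
#'
#' The interchange format is a tidy CSV/TSV (delimiter inferred from the
#' extension) with one row per sampled concentration and columns
#' `specimen_id, well_id, design, t_h, treatment, phase_start_h,
#' phase_end_h, analyte, conc_pg_ml, censor`. Phases are reconstructed from
#' the unique `(treatment, phase_start_h, phase_end_h)` triples per well,
#' so a file written by [write_measurements()] round-trips exactly.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV (comma) or TSV (tab) file.
#' @param panel optional [analyte_panel()]; when supplied, analytes not in
#'   the panel are an error naming them.
#' @return list of [well_series()].
#' @export
read_measurements <- function(path, panel = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(MEAS_COLS, names(df))
  if (length(missing_cols)) {
    stop_invalid("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$conc_pg_ml))))
  if (length(bad)) {
    stop_invalid("non-numeric concentration at data row(s): ",
                 paste(utils::head(bad, 5), collapse = ", "))
  }
  df$conc_pg_ml <- as.numeric(df$conc_pg_ml)
  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$analyte), panel$analyte)
    if (length(unknown)) {
      stop_invalid("analyte(s) not in panel: ", paste(unknown, collapse = ", "))
    }
  }
  wells <- split(df, df$well_id)
  lapply(unname(wells), function(w) {
    sched <- unique(w[, c("phase_start_h", "phase_end_h", "treatment")])
    sched <- sched[order(sched$phase_start_h), , drop = FALSE]
    names(sched) <- c("t_start_h", "t_end_h", "treatment")
    rownames(sched) <- NULL
    w <- w[order(w$analyte, w$t_h), , drop = FALSE]
    well_series(specimen_id = w$specimen_id[1], well_id = w$well_id[1],
                design = w$design[1], schedule = sched,
                samples = data.frame(t_h = w$t_h, analyte = w$analyte,
                                     conc_pg_ml = w$conc_pg_ml,
                                     censor = w$censor,
                                     treatment = w$treatment,
                                     stringsAsFactors = FALSE))
  })
}

#' @rdname read_measurements
#' @param wells a list of [well_series()] (or a long data frame).
#' @export
write_measurements <- function(wells, path) {
  m <- as_measurements(wells)
  m <- m[, MEAS_COLS]
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A plain list capturing every tunable of the pipeline; round-trips
#' through JSON. Unspecified fields take the documented defaults.
#'
#' @param seed root seed for all randomness.
#' @param design `"crosswell"` or `"sequential"`.
#' @param measurements path to a measurement CSV/TSV, or `NULL` to
#'   simulate a cohort.
#' @param panel path to a panel JSON, or `NULL` for [default_panel()].
#' @param out_dir output directory.
#' @param cohort named list of [cohort_spec()] overrides (simulation only).
#' @param kinetics named list of [kinetics_spec()] overrides.
#' @param threshold,saturation,trim_k cross-well stage parameters.
#' @param frac_below_threshold panel exclusion threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = c("crosswell", "sequential"),
                       measurements = NULL, panel = NULL, out_dir = ".",
                       cohort = list(), kinetics = list(),
                       threshold = 5.0, saturation = 10, trim_k = 2,
                       frac_below_threshold = 0.95) {
  design <- match.arg(design)
  structure(list(seed = as.integer(seed), design = design,
                 measurements = measurements, panel = panel,
                 out_dir = out_dir, cohort = cohort, kinetics = kinetics,
                 threshold = threshold, saturation = saturation,
                 trim_k = trim_k,
                 frac_below_threshold = frac_below_threshold),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate (when no measurement file is given) -> censoring and
#' panel QC -> the design-specific response stage -> enrichment/report.
#' All artifacts are written under `config$out_dir` together with a
#' manifest recording the package version, seed, parameters and a config
#' fingerprint; two runs with the same config produce identical numeric
#' outputs.
#'
#' @param config a [run_config()] (or path to its JSON).
#' @param metadata optional specimen metadata data frame (`specimen_id`,
#'   `biomarker_status`); required for enrichment on real measurements.
#' @return invisibly, a list with the stage outputs and artifact paths.
#' @export
run_pipeline <- function(config, metadata = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- if (is.null(config$panel)) default_panel() else read_panel(config$panel)

  if (is.null(config$measurements)) {
    cs <- do.call(cohort_spec, utils::modifyList(list(seed = config$seed),
                                                 config$cohort))
    ks <- do.call(kinetics_spec, config$kinetics)
    cohort <- gen_cohort(cs, panel, design = config$design)
    wells <- unlist(lapply(seq_len(nrow(cohort)), function(i) {
      gen_well_series(cohort[i, ], ks, panel, design = config$design,
                      responsive_analytes = cs$responsive_analytes,
                      effect_theta = cs$effect_theta,
                      seed = child_seed(config$seed, 2, i))
    }), recursive = FALSE)
    metadata <- metadata %||% cohort
  } else {
    wells <- read_measurements(config$measurements, panel)
  }

  wells <- apply_censoring(wells, panel)
  panel_qc <- exclude_low_analytes(wells, panel, config$frac_below_threshold)
  qc <- list(pct_above_lloq = pct_above_lloq(wells, panel_qc),
             n_wells = length(wells),
             n_excluded_analytes = sum(panel_qc$excluded))
  meas_path <- file.path(config$out_dir, "measurements.csv")
  write_measurements(wells, meas_path)
  jsonlite::write_json(qc, file.path(config$out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)

  result <- list(panel = panel_qc, qc = qc, wells = wells)
  if (config$design == "crosswell") {
    zmat <- suppressMessages(build_response_matrix(
      wells, panel_qc, trim_k = config$trim_k,
      saturation = config$saturation))
    up <- suppressMessages(call_upregulated(zmat, config$threshold))
    cl <- ward_cluster(zmat)
    utils::write.table(
      data.frame(specimen_id = rownames(zmat), unclass(zmat)[,],
                 check.names = FALSE),
      file.path(config$out_dir, "response_matrix.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(specimen_id = names(up$counts), n_upregulated = up$counts),
      file.path(config$out_dir, "upregulated_counts.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(specimen_order = cl$specimen_order,
                              analyte_order = cl$analyte_order),
                         file.path(config$out_dir, "cluster_orders.json"),
                         auto_unbox = FALSE)
    result <- c(result, list(response_matrix = zmat, upregulated = up,
                             clusters = cl))
    if (!is.null(metadata) && "biomarker_status" %in% names(metadata)) {
      enr <- biomarker_enrichment(zmat, metadata, config$threshold)
      jsonlite::write_json(
        list(count_test = enr$count_test, per_analyte = enr$per_analyte,
             fisher = enr$fisher),
        file.path(config$out_dir, "enrichment.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      result$enrichment <- enr
    }
  } else {
    fc <- do.call(rbind, lapply(wells, well_slope_fc, panel = panel_qc))
    agg <- aggregate_replicates(fc)
    utils::write.table(fc, file.path(config$out_dir, "slope_fc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(agg, file.path(config$out_dir, "specimen_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    result <- c(result, list(slope_fc = fc, aggregated = agg))
  }

  manifest <- list(
    package = "ltfassay",
    version = as.character(utils::packageVersion("ltfassay")),
    seed = config$seed, design = config$design,
    parameters = unclass(config)[c("threshold", "saturation", "trim_k",
                                   "frac_below_threshold")],
    # hash over the analysis-defining fields only (not output paths), so
    # the same analysis rerun elsewhere carries the same fingerprint
    config_hash = fnv1a(jsonlite::toJSON(
      unclass(config)[setdiff(names(config), "out_dir")],
      auto_unbox = TRUE, digits = NA, null = "null")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}
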