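#' Construct a well series
#'
#' One culture well's treatment schedule and time-stamped cumulative
#' analyte concentrations with censoring flags. Times are hours,
#' concentrations pg/mL; the `censor` flag is one of `"none"`,
#' `"below_lloq"`, `"capped_uloq"`.
#'
#' @param specimen_id,well_id identifiers.
#' @param design `"crosswell"` or `"sequential"`.
#' @param schedule data frame `t_start_h`, `t_end_h`, `treatment` of
#'   contiguous, non-overlapping phases.
#' @param samples data frame `t_h`, `analyte`, `conc_pg_ml`, `censor`
#'   (and optionally `treatment`); times must be strictly increasing per
#'   analyte and concentrations non-negative.
#' @return object of class `well_series`.
#' @export
well_series <- function(specimen_id, well_id, design, schedule, samples) {
  design <- match.arg(design, c("crosswell", "sequential"))
  validate_schedule(schedule)
  samples <- as.data.frame(samples)
  stopifnot(all(c("t_h", "analyte", "conc_pg_ml") %in% names(samples)))
  if (is.null(samples$censor)) samples$censor <- "none"
  if (any(samples$conc_pg_ml < 0, na.rm = TRUE)) {
    stop_invalid("concentrations must be non-negative")
  }
  for (a in unique(samples$analyte)) {
    tt <- samples$t_h[samples$analyte == a]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop_invalid("sample times must be strictly increasing per analyte (", a, ")")
    }
  }
  structure(list(specimen_id = specimen_id, well_id = well_id,
                 design = design, schedule = schedule, samples = samples),
            class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  cat(sprintf("<well_series> %s / %s (%s), %d phases, %d samples\n",
              x$specimen_id, x$well_id, x$design, nrow(x$schedule),
              nrow(x$samples)))
  invisible(x)
}

# Coerce a well_series / list of well_series / long data.frame into the
# canonical long measurement table.
as_measurements <- function(x) {
  if (inherits(x, "well_series")) x <- list(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("specimen_id", "well_id", "t_h", "analyte",
                    "conc_pg_ml") %in% names(x)))
    if (is.null(x$censor)) x$censor <- "none"
    return(x)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "well_series")))
  if (length(x) == 0) {
    return(data.frame(specimen_id = character(0), well_id = character(0),
                      design = character(0), t_h = numeric(0),
                      treatment = character(0), phase_start_h = numeric(0),
                      phase_end_h = numeric(0), analyte = character(0),
                      conc_pg_ml = numeric(0), censor = character(0)))
  }
  do.call(rbind, lapply(x, function(ws) {
    s <- ws$samples
    ph <- phase_at(s$t_h, ws$schedule)
    data.frame(specimen_id = ws$specimen_id, well_id = ws$well_id,
               design = ws$design, t_h = s$t_h,
               treatment = s$treatment %||% ph$treatment,
               phase_start_h = ph$t_start_h, phase_end_h = ph$t_end_h,
               analyte = s$analyte, conc_pg_ml = s$conc_pg_ml,
               censor = s$censor, stringsAsFactors = FALSE)
  }))
}

#' Apply quantitation-limit censoring
#'
#' Values above an analyte's ULOQ are set to the ULOQ and flagged
#' `"capped_uloq"`; values below the LLOQ keep their numeric value but are
#' flagged `"below_lloq"` (they can be dropped later where a stage says
#' so). The operation is idempotent and never alters a value except the
#' ULOQ cap; flags are sticky.
#'
#' @param x a [well_series()], a list of them, or a long measurement data
#'   frame with `analyte`, `conc_pg_ml`, `censor` columns.
#' @param panel an [analyte_panel()] covering every analyte in `x`.
#' @return `x` with censoring applied, same shape as the input.
#' @export
apply_censoring <- function(x, panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  censor_df <- function(df) {
    unknown <- setdiff(unique(df$analyte), panel$analyte)
    if (length(unknown)) {
      stop_invalid("analyte(s) not in panel: ", paste(unknown, collapse = ", "))
    }
    i <- match(df$analyte, panel$analyte)
    if (is.null(df$censor)) df$censor <- "none"
    over <- df$conc_pg_ml > panel$uloq[i]
    df$conc_pg_ml[over] <- panel$uloq[i][over]
    df$censor[over | df$censor == "capped_uloq"] <- "capped_uloq"
    under <- df$conc_pg_ml < panel$lloq[i] & df$censor != "capped_uloq"
    df$censor[under | df$censor == "below_lloq"] <- "below_lloq"
    df
  }
  if (inherits(x, "well_series")) {
    x$samples <- censor_df(x$samples)
    return(x)
  }
  if (is.data.frame(x)) return(censor_df(x))
  lapply(x, apply_censoring, panel = panel)
}

#' Exclude analytes consistently below the LLOQ
#'
#' Marks as excluded every analyte whose fraction of below-LLOQ
#' measurements across the whole input reaches `frac_below_threshold`.
#' Used to drop panel members that the assay cannot quantify in
#' conditioned media.
#'
#' @param x measurements (see [apply_censoring()] for accepted shapes).
#' @param panel an [analyte_panel()].
#' @param frac_below_threshold fraction in (0, 1]; default 0.95
#'   ("consistently below").
#' @return the updated panel with `excluded` / `exclusion_reason` set.
#' @export
exclude_low_analytes <- function(x, panel, frac_below_threshold = 0.95) {
  if (!is.numeric(frac_below_threshold) || frac_below_threshold <= 0 ||
      frac_below_threshold > 1) {
    stop_invalid("frac_below_threshold must be in (0, 1]")
  }
  m <- as_measurements(apply_censoring(x, panel))
  for (k in seq_len(nrow(panel))) {
    sel <- m$analyte == panel$analyte[k]
    if (!any(sel)) next
    frac <- mean(m$censor[sel] == "below_lloq")
    if (frac >= frac_below_threshold) {
      panel$excluded[k] <- TRUE
      panel$exclusion_reason[k] <-
        sprintf("below LLOQ in %.0f%% of samples", 100 * frac)
    }
  }
  panel
}

#' Percentage of panel analytes detected above the LLOQ
#'
#' Coverage metric for assay sensitivity: the share of non-excluded panel
#' analytes with at least one quantifiable (not below-LLOQ) measurement.
#' By default only each well's final time point counts as the detection
#' opportunity (`at = "endpoint"`); `at = "any"` accepts any time point.
#'
#' @param x measurements (any accepted shape).
#' @param panel an [analyte_panel()].
#' @param at `"endpoint"` or `"any"`.
#' @return percentage in `[0, 100]`.
#' @export
pct_above_lloq <- function(x, panel, at = c("endpoint", "any")) {
  at <- match.arg(at)
  m <- as_measurements(apply_censoring(x, panel))
  if (nrow(m) == 0) stop_invalid("no measurements supplied")
  keep <- panel$analyte[!panel$excluded]
  if (length(keep) == 0) stop_invalid("panel has no non-excluded analytes")
  if (at == "endpoint") {
    tmax <- stats::aggregate(t_h ~ well_id + analyte, data = m, FUN = max)
    m <- merge(m, tmax, by = c("well_id", "analyte", "t_h"))
  }
  detected <- vapply(keep, function(a) {
    sel <- m$analyte == a
    any(sel) && any(m$censor[sel] != "below_lloq")
  }, logical(1))
  100 * sum(detected) / length(keep)
}

#' Replicate coefficient of variation at a time point
#'
#' CV in percent (100 x sample SD / mean, n-1 denominator) of an analyte's
#' concentration across replicate wells sharing a specimen, treatment and
#' nominal time point. Below-LLOQ values are excluded (with a message);
#' fewer than two usable values yields `NA` with a warning rather than a
#' silent zero.
#'
#' @param x measurements (any accepted shape).
#' @param analyte analyte name.
#' @param t_h nominal sampling time; matched within `tol_h`.
#' @param tol_h matching tolerance in hours (default 2, for the ~4/~20/~48
#'   grid).
#' @return CV in percent, or `NA_real_` if undefined.
#' @export
replicate_cv <- function(x, analyte, t_h, tol_h = 2) {
  m <- as_measurements(x)
  sel <- m$analyte == analyte & abs(m$t_h - t_h) <= tol_h
  v <- m$conc_pg_ml[sel]
  cen <- m$censor[sel]
  if (any(cen == "below_lloq")) {
    message(sum(cen == "below_lloq"), " below-LLOQ value(s) excluded from CV")
  }
  v <- v[cen != "below_lloq"]
  if (length(v) < 2) {
    warning("fewer than 2 usable replicate values; CV undefined")
    return(NA_real_)
  }
  cv_percent(v)
}

#' Ordinary least-squares rate of change
#'
#' Slope of `values` against `times_h` (per hour). With exactly two points
#' this is the difference quotient; with more it is the OLS fit. Duplicate
#' time points are rejected.
#'
#' @param times_h numeric times (hours), all distinct, length >= 2.
#' @param values numeric values, same length.
#' @return slope per hour.
#' @export
rate_of_change <- function(times_h, values) {
  if (length(times_h) < 2 || length(values) != length(times_h)) {
    stop_invalid("need >= 2 (time, value) pairs of equal length")
  }
  if (anyDuplicated(times_h)) stop_invalid("duplicate time points")
  tc <- times_h - mean(times_h)
  sum(tc * (values - mean(values))) / sum(tc^2)
}
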