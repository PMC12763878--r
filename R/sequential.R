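#' Per-phase slope of cumulative cytokine production
#'
#' OLS slope (pg/mL/h; the difference quotient when exactly two points) of
#' an analyte's cumulative concentration over the samples falling in one
#' treatment phase of the well's schedule, matched within `tol_h`. The
#' sample at a phase boundary belongs to both phases: it terminates the
#' control window and initiates the treatment window. ULOQ-capped points
#' are excluded (a capped value can only flatten the slope); if fewer than
#' two usable points remain the slope is undefined (`NA` with a warning).
#'
#' @param series a [well_series()].
#' @param analyte analyte name.
#' @param phase_label treatment label of the phase (e.g. `"IgG"`, `"ICI"`).
#' @param tol_h time tolerance for window membership (default 2 h).
#' @param exclude_capped drop ULOQ-capped points (default `TRUE`).
#' @return slope in pg/mL/h, or `NA_real_` when undefined.
#' @export
phase_slope <- function(series, analyte, phase_label, tol_h = 2,
                        exclude_capped = TRUE) {
  stopifnot(inherits(series, "well_series"))
  ph <- series$schedule[series$schedule$treatment == phase_label, , drop = FALSE]
  if (nrow(ph) == 0) stop_invalid("phase '", phase_label, "' not in the schedule")
  s <- series$samples[series$samples$analyte == analyte, , drop = FALSE]
  sel <- s$t_h >= ph$t_start_h[1] - tol_h & s$t_h <= ph$t_end_h[nrow(ph)] + tol_h
  s <- s[sel, , drop = FALSE]
  if (exclude_capped && any(s$censor == "capped_uloq")) {
    message(sum(s$censor == "capped_uloq"),
            " ULOQ-capped point(s) excluded from the ", phase_label, " slope")
    s <- s[s$censor != "capped_uloq", , drop = FALSE]
  }
  if (nrow(s) < 2) {
    warning("fewer than 2 usable points in phase '", phase_label,
            "'; slope undefined")
    return(NA_real_)
  }
  rate_of_change(s$t_h, s$conc_pg_ml)
}

#' Slope fold change with a guarded division
#'
#' `fc = treatment_slope / control_slope`, computed only when the control
#' slope exceeds `epsilon`; otherwise the result is flagged indeterminate
#' (no silent division by a noise-level denominator). The recommended
#' epsilon is the analyte's LLOQ divided by the control-phase duration —
#' the slowest production rate the assay could have distinguished from
#' nothing.
#'
#' @param control_slope,treatment_slope slopes in pg/mL/h.
#' @param epsilon indeterminacy floor for the control slope (default 0,
#'   i.e. only non-positive/missing control slopes are indeterminate).
#' @return list with `fc` (numeric or `NA`) and `valid` (logical).
#' @export
slope_fc <- function(control_slope, treatment_slope, epsilon = 0) {
  if (is.na(control_slope) || is.na(treatment_slope) ||
      control_slope <= epsilon) {
    return(list(fc = NA_real_, valid = FALSE))
  }
  list(fc = treatment_slope / control_slope, valid = TRUE)
}

#' Classify a slope fold change into response bands
#'
#' Three-band rule: increase when fc > 1.5; no change when fc is in the
#' closed interval \[0.5, 1.5\]; decrease when fc < 0.5. Indeterminate
#' (missing) fold changes pass through as `"indeterminate"`. Vectorized,
#' total, and monotone in fc.
#'
#' @param fc numeric vector of fold changes (`NA` = indeterminate).
#' @return character vector of `"increase"`, `"no_change"`, `"decrease"`,
#'   `"indeterminate"`.
#' @export
classify_fc <- function(fc) {
  out <- rep("indeterminate", length(fc))
  out[!is.na(fc) & fc > 1.5] <- "increase"
  out[!is.na(fc) & fc >= 0.5 & fc <= 1.5] <- "no_change"
  out[!is.na(fc) & fc < 0.5] <- "decrease"
  out
}

#' Slope fold change for every analyte of a sequential well
#'
#' Convenience wrapper running [phase_slope()] for the control and
#' treatment phases, [slope_fc()] with the LLOQ-based epsilon, and
#' [classify_fc()].
#'
#' @param series a [well_series()] with a two-phase schedule.
#' @param panel an [analyte_panel()]; excluded analytes are skipped.
#' @param control_label,treatment_label schedule labels (defaults `"IgG"`,
#'   `"ICI"`).
#' @param tol_h time tolerance (default 2 h).
#' @return data frame, one row per analyte: `specimen_id`, `well_id`,
#'   `analyte`, `control_slope`, `treatment_slope`, `fc`, `class`.
#' @export
well_slope_fc <- function(series, panel, control_label = "IgG",
                          treatment_label = "ICI", tol_h = 2) {
  stopifnot(inherits(series, "well_series"), inherits(panel, "analyte_panel"))
  ctl <- series$schedule[series$schedule$treatment == control_label, , drop = FALSE]
  if (nrow(ctl) == 0) stop_invalid("control phase '", control_label, "' not in schedule")
  dur <- sum(ctl$t_end_h - ctl$t_start_h)
  analytes <- panel$analyte[!panel$excluded]
  analytes <- intersect(analytes, unique(series$samples$analyte))
  do.call(rbind, lapply(analytes, function(a) {
    cs <- suppressWarnings(phase_slope(series, a, control_label, tol_h))
    ts <- suppressWarnings(phase_slope(series, a, treatment_label, tol_h))
    eps <- panel$lloq[panel$analyte == a] / dur
    r <- slope_fc(cs, ts, epsilon = eps)
    data.frame(specimen_id = series$specimen_id, well_id = series$well_id,
               analyte = a, control_slope = cs, treatment_slope = ts,
               fc = r$fc, class = classify_fc(r$fc),
               stringsAsFactors = FALSE)
  }))
}

#' Aggregate replicate wells of a specimen
#'
#' For each specimen x analyte: the maximum fold change over valid
#' replicates and the any-replicate response flag (`any_increase`) — a
#' positive response in any replicate suggests treatment sensitivity in a
#' heterogeneous tissue. Specimens whose replicates are all indeterminate
#' are flagged unevaluable.
#'
#' @param fc_table data frame as returned by [well_slope_fc()] (rows from
#'   several wells allowed).
#' @return data frame, one row per specimen x analyte: `max_fc`,
#'   `any_increase`, `n_valid`, `unevaluable`.
#' @export
aggregate_replicates <- function(fc_table) {
  stopifnot(all(c("specimen_id", "analyte", "fc", "class") %in% names(fc_table)))
  sp <- split(fc_table, list(fc_table$specimen_id, fc_table$analyte), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    valid <- !is.na(g$fc)
    data.frame(specimen_id = g$specimen_id[1], analyte = g$analyte[1],
               max_fc = if (any(valid)) max(g$fc[valid]) else NA_real_,
               any_increase = any(g$class == "increase"),
               n_valid = sum(valid),
               unevaluable = !any(valid),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Concordance between cross-well and sequential classifications
#'
#' Per analyte, the percentage (nearest integer) of specimens whose
#' response class agrees between the two experimental designs, over
#' specimens classified under both. Discordant pairs are listed.
#'
#' @param crosswell_classes,sequential_classes data frames with
#'   `specimen_id`, `analyte`, `class`.
#' @return data frame per analyte: `n_pairs`, `n_concordant`,
#'   `percent_concordant`; the discordant pairs are attached as the
#'   `"discordant"` attribute.
#' @export
concordance <- function(crosswell_classes, sequential_classes) {
  need <- c("specimen_id", "analyte", "class")
  stopifnot(all(need %in% names(crosswell_classes)),
            all(need %in% names(sequential_classes)))
  m <- merge(crosswell_classes[need], sequential_classes[need],
             by = c("specimen_id", "analyte"),
             suffixes = c("_crosswell", "_sequential"))
  m <- m[m$class_crosswell != "indeterminate" &
           m$class_sequential != "indeterminate", , drop = FALSE]
  if (nrow(m) == 0) stop_invalid("no specimen/analyte pairs with both classes")
  m$match <- m$class_crosswell == m$class_sequential
  out <- do.call(rbind, lapply(split(m, m$analyte), function(g) {
    data.frame(analyte = g$analyte[1], n_pairs = nrow(g),
               n_concordant = sum(g$match),
               percent_concordant = round(100 * sum(g$match) / nrow(g)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "discordant") <- m[!m$match, , drop = FALSE]
  out
}

#' RECIST percent change and partial-response flag
#'
#' `percent_change = 100 * (followup - baseline) / baseline`; a partial
#' response is a reduction of more than 30% in the longest diameter
#' (RECIST v1.1).
#'
#' @param baseline_mm baseline longest diameter (mm, > 0).
#' @param followup_mm follow-up longest diameter (mm, >= 0).
#' @return list with `percent_change` and `partial_response`.
#' @examples
#' recist_percent_change(54.6, 34.2)  # -37%, partial response
#' @export
recist_percent_change <- function(baseline_mm, followup_mm) {
  check_scalar_pos(baseline_mm, "baseline_mm")
  if (!is.numeric(followup_mm) || followup_mm < 0) {
    stop_invalid("followup_mm must be non-negative")
  }
  pc <- 100 * (followup_mm - baseline_mm) / baseline_mm
  list(percent_change = pc, partial_response = pc < -30)
}
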