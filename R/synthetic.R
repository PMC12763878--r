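#' Cohort specification for the synthetic-data generator
#'
#' Describes a simulated specimen cohort with a biomarker-linked hidden
#' responder state: each specimen is biomarker positive with probability
#' `biomarker_positive_fraction` and is a responder with probability
#' `responder_prob_given_positive` or `responder_prob_given_negative`
#' conditional on that status. Responders multiply the production rate of
#' the `responsive_analytes` by `effect_theta` during treatment.
#'
#' @param n_specimens number of specimens (>= 1).
#' @param biomarker_positive_fraction probability of biomarker-positive
#'   status (PD-L1/MMR/MSI composite).
#' @param responder_prob_given_positive,responder_prob_given_negative
#'   conditional responder probabilities.
#' @param responsive_analytes character vector, subset of the panel.
#' @param effect_theta treatment-phase slope multiplier (>= 0, unitless).
#' @param n_replicates replicate wells per arm.
#' @param seed integer root seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 30,
                        biomarker_positive_fraction = 0.5,
                        responder_prob_given_positive = 0.8,
                        responder_prob_given_negative = 0.05,
                        responsive_analytes = default_responsive_analytes(),
                        effect_theta = 4, n_replicates = 3, seed = 1L) {
  check_scalar_pos(n_specimens, "n_specimens")
  check_prob(biomarker_positive_fraction, "biomarker_positive_fraction")
  check_prob(responder_prob_given_positive, "responder_prob_given_positive")
  check_prob(responder_prob_given_negative, "responder_prob_given_negative")
  if (effect_theta < 0) stop_invalid("effect_theta must be >= 0")
  structure(list(n_specimens = as.integer(n_specimens),
                 biomarker_positive_fraction = biomarker_positive_fraction,
                 responder_prob_given_positive = responder_prob_given_positive,
                 responder_prob_given_negative = responder_prob_given_negative,
                 responsive_analytes = responsive_analytes,
                 effect_theta = effect_theta,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Kinetics specification for simulated cytokine trajectories
#'
#' Cumulative analyte concentration in conditioned media accumulates
#' piecewise-linearly: within each treatment phase the concentration grows
#' at `baseline_rate` (pg/mL/h), multiplied by `effect_theta` for a
#' responder's responsive analytes during the treatment phase. Noise is
#' multiplicative lognormal at two levels: one well factor per well
#' (coefficient of variation `well_cv(n_ltf)`, shared by all of that well's
#' measurements) and one independent measurement factor per sampled
#' concentration (`measurement_cv`). Well-to-well CV shrinks with the
#' number of fragments per well as `cv_at_200 * sqrt(200 / n_ltf)` — the
#' square-root law of averaging over independently sampled fragments.
#'
#' @param baseline_rate named numeric vector, pg/mL/h per analyte; analytes
#'   missing from the vector get `default_rate`.
#' @param default_rate fallback production rate (pg/mL/h).
#' @param dead_analytes analytes given `dead_rate` so they stay below LLOQ.
#' @param dead_rate production rate of dead analytes.
#' @param n_ltf fragments per well (default 200, the platform's target).
#' @param cv_at_200 well-to-well CV in percent at 200 fragments (default
#'   20, the observed cross-well replicate variability at that count).
#' @param measurement_cv per-measurement CV in percent (default 10).
#' @param timepoints_h sampling times, strictly increasing (default
#'   4, 20, 48 h).
#' @param schedule data frame `t_start_h`, `t_end_h`, `treatment`;
#'   contiguous, non-overlapping phases. Default: IgG 0-20 h then ICI
#'   20-48 h (the sequential design).
#' @return list of class `kinetics_spec`.
#' @export
kinetics_spec <- function(baseline_rate = NULL, default_rate = 10,
                          dead_analytes = default_dead_analytes(),
                          dead_rate = 0.01,
                          n_ltf = 200, cv_at_200 = 20, measurement_cv = 10,
                          timepoints_h = c(4, 20, 48),
                          schedule = data.frame(
                            t_start_h = c(0, 20), t_end_h = c(20, 48),
                            treatment = c("IgG", "ICI"),
                            stringsAsFactors = FALSE)) {
  if (is.unsorted(timepoints_h, strictly = TRUE)) {
    stop_invalid("timepoints_h must be strictly increasing")
  }
  validate_schedule(schedule)
  if (any(unlist(baseline_rate) <= 0)) stop_invalid("baseline rates must be positive")
  structure(list(baseline_rate = baseline_rate, default_rate = default_rate,
                 dead_analytes = dead_analytes, dead_rate = dead_rate,
                 n_ltf = n_ltf, cv_at_200 = cv_at_200,
                 measurement_cv = measurement_cv,
                 timepoints_h = timepoints_h, schedule = schedule),
            class = "kinetics_spec")
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("t_start_h", "t_end_h", "treatment") %in% names(schedule)))
  if (any(schedule$t_end_h <= schedule$t_start_h)) {
    stop_invalid("schedule phases must have t_end_h > t_start_h")
  }
  if (nrow(schedule) > 1) {
    gaps <- schedule$t_start_h[-1] - schedule$t_end_h[-nrow(schedule)]
    if (any(abs(gaps) > 1e-9)) {
      stop_invalid("schedule phases must be contiguous and non-overlapping")
    }
  }
  invisible(schedule)
}

#' Well-to-well CV as a function of fragment count
#'
#' `cv_at_200 * sqrt(200 / n_ltf)`: pooling more fragments averages over
#' more independent tissue samples, shrinking the well-level CV like the
#' standard error of a mean.
#'
#' @param n_ltf fragments per well.
#' @param cv_at_200 CV in percent at 200 fragments.
#' @export
well_cv_for_count <- function(n_ltf, cv_at_200 = 20) {
  check_scalar_pos(n_ltf, "n_ltf")
  cv_at_200 * sqrt(200 / n_ltf)
}

#' Generate a specimen cohort with hidden responder ground truth
#'
#' @param cohort a [cohort_spec()].
#' @param panel an [analyte_panel()] (must be non-empty).
#' @param design `"crosswell"` or `"sequential"`.
#' @param tumor_types recycled over specimens.
#' @return data frame of specimen records: `specimen_id`, `tumor_type`,
#'   `biomarker_status` (`"positive"`/`"negative"`), `responder` (the
#'   hidden ground-truth flag), `n_replicates`, `design`.
#' @export
gen_cohort <- function(cohort, panel = default_panel(),
                       design = c("crosswell", "sequential"),
                       tumor_types = c("melanoma", "lung", "colorectal",
                                       "ovarian", "head and neck", "kidney")) {
  design <- match.arg(design)
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!inherits(panel, "analyte_panel") || nrow(panel) == 0) {
    stop_invalid("panel must be a non-empty analyte_panel")
  }
  if (!all(cohort$responsive_analytes %in% panel$analyte)) {
    stop_invalid("responsive_analytes must be a subset of the panel")
  }
  set.seed(child_seed(cohort$seed, 1))
  n <- cohort$n_specimens
  positive <- stats::runif(n) < cohort$biomarker_positive_fraction
  p_resp <- ifelse(positive, cohort$responder_prob_given_positive,
                   cohort$responder_prob_given_negative)
  responder <- stats::runif(n) < p_resp
  data.frame(
    specimen_id = sprintf("S%03d", seq_len(n)),
    tumor_type = rep_len(tumor_types, n),
    biomarker_status = ifelse(positive, "positive", "negative"),
    responder = responder,
    n_replicates = cohort$n_replicates,
    design = design,
    stringsAsFactors = FALSE
  )
}

#' Simulate longitudinal cytokine measurements for one specimen
#'
#' Produces the well series of either experimental design. In the
#' cross-well design, control (IgG) and treated (ICI) fragments occupy
#' separate replicate wells, each cultured under a single-phase schedule
#' spanning the full duration. In the sequential design each well runs the
#' two-phase schedule of the kinetics spec (control first, then drug) and
#' acts as its own control. Responder ground truth multiplies the
#' production rate of responsive analytes by `effect_theta` whenever the
#' active treatment is `"ICI"` (or any non-IgG label). Cumulative curves
#' are piecewise linear and non-decreasing before noise; censoring against
#' the panel is applied last.
#'
#' @param specimen one row of [gen_cohort()] output (or a list with
#'   `specimen_id` and `responder`).
#' @param kinetics a [kinetics_spec()].
#' @param panel an [analyte_panel()].
#' @param design `"crosswell"` or `"sequential"`.
#' @param responsive_analytes analytes whose rate responds to treatment.
#' @param effect_theta treatment-phase rate multiplier for responders.
#' @param n_replicates wells per arm (crosswell) or replicate wells
#'   (sequential).
#' @param seed integer seed; wells get derived child streams.
#' @return list of `well_series` objects (see [well_series()]).
#' @export
gen_well_series <- function(specimen, kinetics = kinetics_spec(),
                            panel = default_panel(),
                            design = c("crosswell", "sequential"),
                            responsive_analytes = default_responsive_analytes(),
                            effect_theta = 4,
                            n_replicates = specimen$n_replicates %||% 3,
                            seed = 1L) {
  design <- match.arg(design)
  stopifnot(inherits(kinetics, "kinetics_spec"))
  validate_schedule(kinetics$schedule)
  total_span <- range(kinetics$schedule$t_start_h, kinetics$schedule$t_end_h)
  responder <- isTRUE(specimen$responder)
  sid <- specimen$specimen_id %||% "S001"

  well_defs <- if (design == "sequential") {
    lapply(seq_len(n_replicates), function(r)
      list(well_id = sprintf("%s_seq_w%d", sid, r), schedule = kinetics$schedule))
  } else {
    c(lapply(seq_len(n_replicates), function(r)
        list(well_id = sprintf("%s_IgG_w%d", sid, r),
             schedule = data.frame(t_start_h = total_span[1],
                                   t_end_h = total_span[2],
                                   treatment = "IgG", stringsAsFactors = FALSE))),
      lapply(seq_len(n_replicates), function(r)
        list(well_id = sprintf("%s_ICI_w%d", sid, r),
             schedule = data.frame(t_start_h = total_span[1],
                                   t_end_h = total_span[2],
                                   treatment = "ICI", stringsAsFactors = FALSE))))
  }

  rates <- stats::setNames(rep(kinetics$default_rate, nrow(panel)), panel$analyte)
  if (!is.null(kinetics$baseline_rate)) {
    rates[names(kinetics$baseline_rate)] <- unlist(kinetics$baseline_rate)
  }
  rates[kinetics$dead_analytes[kinetics$dead_analytes %in% names(rates)]] <-
    kinetics$dead_rate
  wcv <- well_cv_for_count(kinetics$n_ltf, kinetics$cv_at_200)

  theta_vec <- ifelse(responder & panel$analyte %in% responsive_analytes,
                      effect_theta, 1)
  lapply(seq_along(well_defs), function(w) {
    wd <- well_defs[[w]]
    set.seed(child_seed(seed, 17, w))
    well_factor <- lnorm_factor(1, wcv)
    tp <- kinetics$timepoints_h
    tp <- tp[tp >= total_span[1] & tp <= total_span[2]]
    sched <- wd$schedule
    # noise-free cumulative curves, vectorized: analytes x phases %*%
    # phases x timepoints overlap durations
    ov <- vapply(tp, function(t)
      pmax(0, pmin(t, sched$t_end_h) - sched$t_start_h), numeric(nrow(sched)))
    ov <- matrix(ov, nrow = nrow(sched))
    mult <- outer(theta_vec, !is_control_label(sched$treatment),
                  function(th, treated) ifelse(treated, th, 1))
    conc <- (rates[panel$analyte] * mult) %*% ov  # analytes x timepoints
    noise <- matrix(lnorm_factor(length(conc), kinetics$measurement_cv),
                    nrow = nrow(conc))
    conc <- conc * well_factor * noise
    ph <- phase_at(tp, sched)
    samp <- data.frame(
      t_h = rep(tp, each = nrow(panel)),
      analyte = rep(panel$analyte, length(tp)),
      conc_pg_ml = as.vector(conc),
      censor = "none",
      treatment = rep(ph$treatment, each = nrow(panel)),
      stringsAsFactors = FALSE)
    samp <- samp[order(samp$analyte, samp$t_h), , drop = FALSE]
    rownames(samp) <- NULL
    ws <- well_series(specimen_id = sid, well_id = wd$well_id,
                      design = design, schedule = sched, samples = samp)
    apply_censoring(ws, panel)
  })
}

# Noise-free cumulative concentration at time t under a phase schedule.
# theta multiplies the rate in phases whose treatment is not IgG-like.
cumulative_conc <- function(t, schedule, rate, theta) {
  acc <- 0
  for (p in seq_len(nrow(schedule))) {
    overlap <- max(0, min(t, schedule$t_end_h[p]) - schedule$t_start_h[p])
    mult <- if (is_control_label(schedule$treatment[p])) 1 else theta
    acc <- acc + rate * mult * overlap
  }
  acc
}

is_control_label <- function(x) grepl("^igg", tolower(x))

# Phase membership of sampling times; a time on a boundary is attributed to
# the phase it terminates (the media sampled at 20 h accumulated under the
# control phase).
phase_at <- function(t, schedule) {
  idx <- vapply(t, function(ti) {
    hit <- which(ti > schedule$t_start_h - 1e-9 & ti <= schedule$t_end_h + 1e-9)
    if (length(hit) == 0) hit <- which.min(abs(schedule$t_start_h - ti))
    hit[1]
  }, integer(1))
  schedule[idx, , drop = FALSE]
}
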