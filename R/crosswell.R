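#' Cumulative concentration difference between treatment arms
#'
#'   delta = mean(ICI endpoint concentrations) - mean(IgG endpoint
#'   concentrations)
#'
#' The cross-well response signal for one specimen and analyte: replicate
#' wells of each arm are averaged at the endpoint time and the arm means
#' are differenced (pg/mL). Swapping the arms flips the sign.
#'
#' @param x measurements for one specimen (any shape accepted by
#'   [apply_censoring()]); the `treatment` column identifies arms.
#' @param analyte analyte name.
#' @param t_end_h endpoint time (hours), matched within `tol_h`; default
#'   the latest time present.
#' @param treatment_ici,treatment_control arm labels (defaults `"ICI"`,
#'   `"IgG"`).
#' @param tol_h time matching tolerance (default 2 h).
#' @return difference in pg/mL.
#' @export
cumulative_difference <- function(x, analyte, t_end_h = NULL,
                                  treatment_ici = "ICI",
                                  treatment_control = "IgG", tol_h = 2) {
  m <- as_measurements(x)
  m <- m[m$analyte == analyte, , drop = FALSE]
  if (is.null(t_end_h)) t_end_h <- max(m$t_h)
  m <- m[abs(m$t_h - t_end_h) <= tol_h, , drop = FALSE]
  ici <- m$conc_pg_ml[m$treatment == treatment_ici]
  ctl <- m$conc_pg_ml[m$treatment == treatment_control]
  if (length(ici) == 0 || length(ctl) == 0) {
    stop_invalid("missing ", if (length(ici) == 0) treatment_ici else treatment_control,
                 " arm for analyte ", analyte, " at ", t_end_h, " h")
  }
  mean(ici) - mean(ctl)
}

#' MAD-trimmed modified Z-scores
#'
#' Robust standardization of a vector of per-specimen response values:
#'
#' 1. compute the median `m` and `MAD = median(|x - m|)`;
#' 2. form the trimmed set of values within `trim_k` MADs of the median;
#' 3. recompute the median `m*` and `MAD*` on the trimmed set;
#' 4. transform every value (outliers included) to
#'    `z = scale_c * (x - m*) / MAD*` with `scale_c = 0.6745`, the
#'    classical modified Z-score constant (0.6745 = the normal quartile,
#'    making `z` comparable to a standard score);
#' 5. saturate to `[-saturation, +saturation]`.
#'
#' The trimmed location/scale make a handful of strong responders unable
#' to inflate the spread estimate and mask themselves. If `MAD*` is zero
#' the fallback scale is `1.4826 * mean(|x - m*|)` over the trimmed set;
#' if that is also zero all scores are 0. Both fallbacks emit a message.
#' `NA`s pass through as `NA`.
#'
#' @param x numeric vector (>= 3 finite values).
#' @param trim_k trimming width in MAD units (default 2).
#' @param scale_c scale constant (default 0.6745).
#' @param saturation saturation bound (default 10).
#' @return numeric vector of saturated modified Z-scores.
#' @examples
#' mad_trimmed_modz(c(1, 2, 3, 4, 100))  # the outlier saturates at 10
#' @export
mad_trimmed_modz <- function(x, trim_k = 2, scale_c = 0.6745, saturation = 10) {
  ok <- is.finite(x)
  if (sum(ok) < 3) stop_invalid("need at least 3 finite values")
  v <- x[ok]
  m <- stats::median(v)
  mad0 <- stats::median(abs(v - m))
  trimmed <- if (mad0 > 0) v[abs(v - m) <= trim_k * mad0] else v
  m_star <- stats::median(trimmed)
  mad_star <- stats::median(abs(trimmed - m_star))
  if (mad_star == 0) {
    # fallback scale: mean absolute deviation rescaled to MAD units
    mad_star <- 1.4826 * mean(abs(trimmed - m_star))
    message("MAD* = 0; falling back to 1.4826 * mean absolute deviation")
  }
  z <- rep(NA_real_, length(x))
  if (mad_star == 0) {
    message("degenerate spread; all modified Z-scores set to 0")
    z[ok] <- 0
  } else {
    z[ok] <- pmin(pmax(scale_c * (v - m_star) / mad_star, -saturation), saturation)
  }
  z
}

#' Build the specimen x analyte response matrix
#'
#' Runs the full cross-well normalization: endpoint cumulative differences
#' per specimen and analyte ([cumulative_difference()]), then MAD-trimmed
#' modified Z-scores ([mad_trimmed_modz()]) computed along `axis` —
#' per analyte across specimens by default, so a score says "this specimen's
#' induction of this cytokine is extreme relative to the cohort".
#'
#' @param x cohort measurements (any accepted shape).
#' @param panel an [analyte_panel()]; excluded analytes are dropped.
#' @param t_end_h endpoint time (default: latest time in the data).
#' @param axis `"analyte"` (scores across specimens, default) or
#'   `"specimen"` (scores across analytes within each specimen).
#' @param ... passed to [mad_trimmed_modz()].
#' @inheritParams cumulative_difference
#' @return a `response_matrix`: numeric matrix (specimens x analytes) of
#'   saturated modified Z-scores with a `"deltas"` attribute holding the
#'   raw differences.
#' @export
build_response_matrix <- function(x, panel, t_end_h = NULL,
                                  axis = c("analyte", "specimen"),
                                  treatment_ici = "ICI",
                                  treatment_control = "IgG", ...) {
  axis <- match.arg(axis)
  m <- as_measurements(x)
  analytes <- panel$analyte[!panel$excluded]
  specimens <- unique(m$specimen_id)
  m <- m[m$analyte %in% analytes &
           m$treatment %in% c(treatment_ici, treatment_control), , drop = FALSE]
  # endpoint rows per specimen x analyte (vectorized equivalent of calling
  # cumulative_difference() on each pair; identical by construction)
  key <- paste(m$specimen_id, m$analyte, sep = "\r")
  t_end <- if (is.null(t_end_h)) stats::ave(m$t_h, key, FUN = max) else t_end_h
  tol_h <- 2
  m <- m[abs(m$t_h - t_end) <= tol_h, , drop = FALSE]
  arm_mean <- function(trt) {
    sel <- m$treatment == trt
    ag <- stats::aggregate(list(conc = m$conc_pg_ml[sel]),
                           list(specimen_id = m$specimen_id[sel],
                                analyte = m$analyte[sel]), mean)
    out <- matrix(NA_real_, length(specimens), length(analytes),
                  dimnames = list(specimens, analytes))
    out[cbind(ag$specimen_id, ag$analyte)] <- ag$conc
    out
  }
  deltas <- arm_mean(treatment_ici) - arm_mean(treatment_control)
  z <- if (axis == "analyte") {
    apply(deltas, 2, mad_trimmed_modz, ...)
  } else {
    t(apply(deltas, 1, mad_trimmed_modz, ...))
  }
  dimnames(z) <- dimnames(deltas)
  structure(z, deltas = deltas, axis = axis, class = c("response_matrix", "matrix"))
}

#' Call upregulated specimen/analyte pairs
#'
#' A conservative upregulation call: modified Z-score >= `threshold`
#' (inclusive; default 5). Missing scores are never called (their count
#' contribution is 0) and are reported via a message.
#'
#' @param zmat a `response_matrix` (or plain numeric matrix).
#' @param threshold call threshold (default 5.0).
#' @return list with `calls` (logical matrix) and `counts` (named integer
#'   vector of upregulated analytes per specimen).
#' @export
call_upregulated <- function(zmat, threshold = 5.0) {
  z <- unclass(zmat)
  attr(z, "deltas") <- NULL; attr(z, "axis") <- NULL
  nmiss <- sum(is.na(z))
  if (nmiss) message(nmiss, " missing score(s) treated as not called")
  calls <- !is.na(z) & z >= threshold
  list(calls = calls, counts = rowSums(calls))
}

#' Ward hierarchical clustering of the response matrix
#'
#' Agglomerative clustering along both axes with the Ward minimum-variance
#' criterion on Euclidean distances (`hclust` method `"ward.D2"`). Missing
#' scores are imputed as 0 — the "no change" point of the Z scale — with a
#' message; a row or column more than `max_missing` missing is an error.
#' Row/column order is made deterministic by sorting labels first, so the
#' tree does not depend on input order beyond genuine ties.
#'
#' @param zmat a `response_matrix`.
#' @param max_missing maximum tolerated missing fraction per row/column
#'   (default 0.2).
#' @return list with `specimen_order`, `analyte_order` (leaf label
#'   vectors), and `specimen_hclust`, `analyte_hclust`.
#' @export
ward_cluster <- function(zmat, max_missing = 0.2) {
  z <- unclass(zmat)
  attr(z, "deltas") <- NULL; attr(z, "axis") <- NULL
  z <- z[order(rownames(z)), order(colnames(z)), drop = FALSE]
  rmiss <- rowMeans(is.na(z)); cmiss <- colMeans(is.na(z))
  if (any(rmiss > max_missing) || any(cmiss > max_missing)) {
    stop_invalid("rows/columns exceed the ", max_missing,
                 " missing-fraction limit for imputation")
  }
  if (anyNA(z)) {
    message(sum(is.na(z)), " missing score(s) imputed as 0 for clustering")
    z[is.na(z)] <- 0
  }
  hs <- stats::hclust(stats::dist(z), method = "ward.D2")
  ha <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  list(specimen_order = rownames(z)[hs$order],
       analyte_order = colnames(z)[ha$order],
       specimen_hclust = hs, analyte_hclust = ha)
}

#' Biomarker enrichment of the cytokine response
#'
#' Three views of whether biomarker-positive specimens respond more:
#' (a) upregulated-analyte counts compared between biomarker groups by a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test; (b) each analyte's
#' Z-scores compared likewise; (c) each analyte's binary upregulation call
#' cross-tabulated against biomarker status and tested by a two-sided
#' Fisher exact test with the sample odds ratio.
#'
#' @param zmat a `response_matrix`.
#' @param statuses named character vector (`"positive"`/`"negative"`) or a
#'   data frame with `specimen_id`, `biomarker_status`; must cover the
#'   matrix rows, with >= 2 specimens per group.
#' @param threshold upregulation threshold passed to [call_upregulated()].
#' @return list with `count_test` (p-value + group medians), `per_analyte`
#'   (data frame of Mann-Whitney p per analyte) and `fisher` (data frame of
#'   Fisher p, odds ratio and table cells per analyte).
#' @export
biomarker_enrichment <- function(zmat, statuses, threshold = 5.0) {
  z <- unclass(zmat)
  attr(z, "deltas") <- NULL; attr(z, "axis") <- NULL
  if (is.data.frame(statuses)) {
    statuses <- stats::setNames(statuses$biomarker_status, statuses$specimen_id)
  }
  st <- statuses[rownames(z)]
  if (anyNA(st)) stop_invalid("statuses must cover every specimen in the matrix")
  pos <- st == "positive"; neg <- st == "negative"
  if (sum(pos) < 2 || sum(neg) < 2) {
    stop_invalid("need >= 2 specimens per biomarker group")
  }
  # degenerate all-tied samples make the normal-approximation rank test
  # return NaN; identical groups carry no evidence, so p = 1
  mw_p <- function(a, b) {
    if (length(unique(c(a, b))) < 2) return(1)
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    if (is.nan(p)) 1 else p
  }
  up <- call_upregulated(z, threshold)
  counts <- up$counts
  count_test <- list(
    p_value = mw_p(counts[pos], counts[neg]),
    median_positive = stats::median(counts[pos]),
    median_negative = stats::median(counts[neg]))
  per_analyte <- do.call(rbind, lapply(colnames(z), function(a) {
    p <- tryCatch(mw_p(z[pos, a], z[neg, a]), error = function(e) NA_real_)
    data.frame(analyte = a, mw_p = p)
  }))
  fisher <- do.call(rbind, lapply(colnames(z), function(a) {
    tab <- matrix(c(sum(up$calls[pos, a]), sum(!up$calls[pos, a] & !is.na(z[pos, a])),
                    sum(up$calls[neg, a]), sum(!up$calls[neg, a] & !is.na(z[neg, a]))),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(analyte = a, fisher_p = ft$p.value,
               odds_ratio = unname(ft$estimate),
               up_pos = tab[1, 1], nup_pos = tab[1, 2],
               up_neg = tab[2, 1], nup_neg = tab[2, 2])
  }))
  list(count_test = count_test, per_analyte = per_analyte, fisher = fisher)
}
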