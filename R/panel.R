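#' Construct an analyte panel
#'
#' An analyte panel records, for each analyte of a multiplex immunoassay,
#' the lower and upper limits of quantitation (LLOQ/ULOQ, pg/mL) and an
#' exclusion flag used to drop analytes that are consistently unquantifiable.
#'
#' @param analyte character vector of unique analyte names.
#' @param lloq numeric vector of lower limits of quantitation (pg/mL).
#' @param uloq numeric vector of upper limits of quantitation (pg/mL).
#' @param excluded logical vector; `TRUE` marks an analyte dropped from
#'   analysis.
#' @param exclusion_reason character vector; free text, `NA` when retained.
#' @return a data frame of class `analyte_panel`.
#' @seealso [default_panel()], [exclude_low_analytes()]
#' @export
analyte_panel <- function(analyte, lloq, uloq,
                          excluded = rep(FALSE, length(analyte)),
                          exclusion_reason = rep(NA_character_, length(analyte))) {
  analyte <- as.character(analyte)
  if (anyDuplicated(analyte)) stop_invalid("analyte names must be unique")
  if (length(lloq) != length(analyte) || length(uloq) != length(analyte)) {
    stop_invalid("lloq and uloq must have one value per analyte")
  }
  if (any(!is.finite(lloq)) || any(!is.finite(uloq)) ||
      any(lloq <= 0) || any(uloq <= lloq)) {
    stop_invalid("limits must satisfy 0 < lloq < uloq for every analyte")
  }
  panel <- data.frame(
    analyte = analyte, lloq = as.numeric(lloq), uloq = as.numeric(uloq),
    excluded = as.logical(excluded),
    exclusion_reason = as.character(exclusion_reason),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("analyte_panel", "data.frame")
  panel
}

#' Default 30-plex secretome panel
#'
#' A 30-analyte panel modeled on a commercial multiplex cytokine kit. The
#' analyte names are the kit's public list; the LLOQ/ULOQ values are
#' *synthetic* (realistic orders of magnitude for a bead-based immunoassay)
#' because kit-specific limits are proprietary. Six analytes (CD40L, EGF,
#' FGF basic, IL-12p70, IL-15, FLT-3L) are typically unquantifiable in
#' conditioned media and are the generator's default "dead" analytes; they
#' start *unexcluded* here so that [exclude_low_analytes()] can be shown to
#' find them from data.
#'
#' @return an [analyte_panel()] with 30 rows.
#' @export
default_panel <- function() {
  nm <- c("IFN-gamma", "CXCL10", "IL-1Ra", "TNF-alpha", "IL-2", "IL-4",
          "IL-5", "IL-6", "IL-7", "IL-8", "IL-10", "IL-13", "IL-17A",
          "IL-1beta", "GM-CSF", "G-CSF", "Granzyme B", "CCL2", "CCL3",
          "CCL4", "CCL5", "CXCL1", "VEGF", "TRAIL",
          "CD40L", "EGF", "FGF basic", "IL-12p70", "IL-15", "FLT-3L")
  lloq <- c(2.5, 1.5, 8, 1.2, 1.8, 2.1, 1.1, 0.9, 1.6, 1.4, 1.3, 4.2, 1.9,
            0.8, 2.4, 1.7, 3.1, 2.2, 3.4, 2.8, 1.9, 5.1, 2.6, 3.7,
            4.5, 2.9, 3.3, 1.5, 2.0, 5.6)
  panel <- analyte_panel(nm, lloq = lloq, uloq = lloq * 2000)
  panel
}

# Default responsive analytes: the T-cell activation axis highlighted by the
# platform (IFN-gamma / CXCL10) plus canonical co-secreted effectors.
default_responsive_analytes <- function() {
  c("IFN-gamma", "CXCL10", "TNF-alpha", "IL-2", "GM-CSF", "Granzyme B")
}

# The six analytes the generator leaves below quantitation by default.
default_dead_analytes <- function() {
  c("CD40L", "EGF", "FGF basic", "IL-12p70", "IL-15", "FLT-3L")
}

#' Read / write an analyte panel as JSON
#'
#' @param path file path.
#' @return `read_panel()` returns an [analyte_panel()]; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  x <- jsonlite::fromJSON(path)
  analyte_panel(x$analyte, x$lloq, x$uloq,
                excluded = x$excluded %||% rep(FALSE, length(x$analyte)),
                exclusion_reason = x$exclusion_reason %||%
                  rep(NA_character_, length(x$analyte)))
}

#' @rdname read_panel
#' @param panel an [analyte_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  jsonlite::write_json(unclass(panel), path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
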