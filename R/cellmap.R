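#' Construct a 2D labeled cell map
#'
#' A cell map is the substrate of the fragmentation simulation: a marked
#' point set (cell centroids with a marker label, micron coordinates, origin
#' at the lower-left corner) together with a binary tissue mask. The mask is
#' a raster of `res_um` micron pixels using half-open pixel intervals; when
#' `mask = NULL` the whole rectangle is tissue.
#'
#' @param width_um,height_um map extent in microns.
#' @param points data frame with columns `x_um`, `y_um`, `marker`.
#' @param mask either `NULL` (all tissue) or a list with elements `raster`
#'   (logical matrix, rows indexed by x pixel, columns by y pixel) and
#'   `res_um` (pixel size, microns).
#' @return an object of class `cellmap`.
#' @export
cellmap <- function(width_um, height_um, points, mask = NULL) {
  check_scalar_pos(width_um, "width_um")
  check_scalar_pos(height_um, "height_um")
  points <- as.data.frame(points)
  stopifnot(all(c("x_um", "y_um", "marker") %in% names(points)))
  if (nrow(points)) {
    bad <- points$x_um < 0 | points$x_um > width_um |
      points$y_um < 0 | points$y_um > height_um
    if (any(bad)) stop_invalid(sum(bad), " point(s) outside the map extent")
  }
  if (!is.null(mask)) {
    stopifnot(is.list(mask), is.matrix(mask$raster), is.numeric(mask$res_um))
    if (nrow(points)) {
      inside <- point_in_mask(points$x_um, points$y_um, mask, width_um, height_um)
      if (!all(inside)) stop_invalid(sum(!inside), " point(s) outside the tissue mask")
    }
  }
  structure(list(width_um = width_um, height_um = height_um,
                 points = points, mask = mask),
            class = "cellmap")
}

# Half-open pixel lookup; points on the far border fall in the last pixel.
point_in_mask <- function(x, y, mask, width_um, height_um) {
  if (is.null(mask)) return(rep(TRUE, length(x)))
  res <- mask$res_um
  i <- pmin(floor(x / res) + 1L, nrow(mask$raster))
  j <- pmin(floor(y / res) + 1L, ncol(mask$raster))
  mask$raster[cbind(i, j)]
}

#' Tissue area of a cell map (mm^2)
#' @param map a [cellmap()].
#' @export
tissue_area_mm2 <- function(map) {
  if (is.null(map$mask)) return(map$width_um * map$height_um / 1e6)
  sum(map$mask$raster) * (map$mask$res_um^2) / 1e6
}

#' @export
print.cellmap <- function(x, ...) {
  cat(sprintf("<cellmap> %.0f x %.0f um, %d points, tissue %.3f mm^2\n",
              x$width_um, x$height_um, nrow(x$points), tissue_area_mm2(x)))
  invisible(x)
}

#' Simulate a spatial cell map
#'
#' Generates cell positions either as a homogeneous Poisson process or as a
#' Thomas cluster process (Poisson-distributed parents, Poisson-distributed
#' offspring displaced by an isotropic Gaussian). Both are parameterized by
#' the *total* intensity so that the expected number of cells equals
#' `intensity_per_mm2` times the tissue area; for the Thomas process the
#' parent rate is `intensity_per_mm2 / mean_offspring`. Parents are drawn in
#' a window padded by `4 * sigma_um` so cluster mass is not lost at edges,
#' and offspring falling outside the extent or mask are discarded (thinning,
#' which preserves the intensity inside the tissue).
#'
#' @param width_um,height_um extent in microns.
#' @param process `"poisson"` or `"thomas"`.
#' @param intensity_per_mm2 expected cells per mm^2 of tissue (>= 0).
#' @param mean_offspring Thomas: expected offspring per parent (> 0).
#' @param sigma_um Thomas: Gaussian offspring dispersion (microns, > 0).
#' @param mask optional tissue mask (see [cellmap()]).
#' @param marker marker label attached to every point (default `"CD3+"`).
#' @param seed integer seed; identical seeds give identical maps.
#' @return a [cellmap()].
#' @examples
#' m <- gen_cellmap(1000, 1000, "poisson", intensity_per_mm2 = 500, seed = 1)
#' nrow(m$points)
#' @export
gen_cellmap <- function(width_um, height_um,
                        process = c("poisson", "thomas"),
                        intensity_per_mm2,
                        mean_offspring = 25, sigma_um = 100,
                        mask = NULL, marker = "CD3+", seed = 1L) {
  process <- match.arg(process)
  check_scalar_pos(width_um, "width_um")
  check_scalar_pos(height_um, "height_um")
  if (!is.numeric(intensity_per_mm2) || length(intensity_per_mm2) != 1L ||
      !is.finite(intensity_per_mm2) || intensity_per_mm2 < 0) {
    stop_invalid("intensity_per_mm2 must be a single non-negative number")
  }
  set.seed(seed)
  lambda_um2 <- intensity_per_mm2 / 1e6  # cells per um^2
  if (process == "poisson") {
    n <- stats::rpois(1, lambda_um2 * width_um * height_um)
    x <- stats::runif(n, 0, width_um)
    y <- stats::runif(n, 0, height_um)
  } else {
    check_scalar_pos(mean_offspring, "mean_offspring")
    check_scalar_pos(sigma_um, "sigma_um")
    pad <- 4 * sigma_um
    pw <- width_um + 2 * pad
    ph <- height_um + 2 * pad
    parent_rate_um2 <- lambda_um2 / mean_offspring
    np <- stats::rpois(1, parent_rate_um2 * pw * ph)
    px <- stats::runif(np, -pad, width_um + pad)
    py <- stats::runif(np, -pad, height_um + pad)
    noff <- stats::rpois(np, mean_offspring)
    x <- rep(px, noff) + stats::rnorm(sum(noff), 0, sigma_um)
    y <- rep(py, noff) + stats::rnorm(sum(noff), 0, sigma_um)
    keep <- x >= 0 & x <= width_um & y >= 0 & y <= height_um
    x <- x[keep]; y <- y[keep]
  }
  if (!is.null(mask)) {
    keep <- point_in_mask(x, y, mask, width_um, height_um)
    x <- x[keep]; y <- y[keep]
  }
  cellmap(width_um, height_um,
          data.frame(x_um = x, y_um = y, marker = rep(marker, length(x)),
                     stringsAsFactors = FALSE),
          mask = mask)
}

#' Quadrat counts of a cell map
#'
#' Counts points per cell of a regular `nx` by `ny` grid; the standard
#' diagnostic for over/underdispersion (variance-to-mean ratio ~ 1 for a
#' homogeneous Poisson process, > 1 for a cluster process).
#'
#' @param map a [cellmap()].
#' @param nx,ny grid dimensions.
#' @return integer matrix of counts (`nx` rows, `ny` columns).
#' @export
quadrat_counts <- function(map, nx = 10, ny = 10) {
  i <- pmin(floor(map$points$x_um / (map$width_um / nx)) + 1L, nx)
  j <- pmin(floor(map$points$y_um / (map$height_um / ny)) + 1L, ny)
  cnt <- matrix(0L, nx, ny)
  if (length(i)) {
    tab <- table(factor(i, levels = seq_len(nx)), factor(j, levels = seq_len(ny)))
    cnt <- matrix(as.integer(tab), nx, ny)
  }
  cnt
}

#' Write / read a cell map as plain text
#'
#' Points go to a CSV (`x_um`, `y_um`, `marker`); the mask (if any) goes to
#' a companion `<path>.mask.json` holding the extent, raster resolution and
#' the 0/1 raster rows, so the whole object is text and round-trips exactly.
#'
#' @param map a [cellmap()].
#' @param path CSV path for the points.
#' @return `write_cellmap()` returns `path` invisibly; `read_cellmap()`
#'   returns a [cellmap()].
#' @export
write_cellmap <- function(map, path) {
  utils::write.csv(map$points, path, row.names = FALSE, quote = FALSE)
  hdr <- list(width_um = map$width_um, height_um = map$height_um)
  if (!is.null(map$mask)) {
    hdr$mask_res_um <- map$mask$res_um
    hdr$mask_rows <- apply(map$mask$raster * 1L, 1, paste, collapse = "")
  }
  jsonlite::write_json(hdr, paste0(path, ".mask.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cellmap
#' @export
read_cellmap <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  hdr <- jsonlite::fromJSON(paste0(path, ".mask.json"))
  mask <- NULL
  if (!is.null(hdr$mask_rows)) {
    raster <- do.call(rbind, lapply(strsplit(hdr$mask_rows, ""),
                                    function(r) as.integer(r) == 1L))
    mask <- list(raster = raster, res_um = hdr$mask_res_um)
  }
  cellmap(hdr$width_um, hdr$height_um, pts, mask = mask)
}
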