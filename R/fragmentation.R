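#' Cut a cell map into fragments
#'
#' Reproduces in silico the two tissue sampling strategies the platform
#' compares: `"slice"` cuts parallel strips of width `slice_width_um`
#' spanning the full map (vertical strips by default, i.e. cuts parallel to
#' the y axis), and `"cuboid"` cuts a regular grid of `edge_um` squares —
#' the 2D face of a cuboid live tumor fragment. The grid is anchored at the
#' origin; the last row/column may be narrower when the extent is not a
#' multiple of the edge. Fragments whose tissue fraction (mask area over
#' fragment area) falls below `min_tissue_fraction` are discarded; every
#' retained point is counted in exactly one fragment, so at
#' `min_tissue_fraction = 0` cutting conserves total counts.
#'
#' @param map a [cellmap()].
#' @param mode `"cuboid"` or `"slice"`.
#' @param edge_um cuboid edge length (microns); used when `mode = "cuboid"`.
#' @param slice_width_um strip width (microns); used when `mode = "slice"`.
#' @param min_tissue_fraction fragments with a smaller tissue fraction are
#'   dropped (default 0.5; border handling).
#' @param orientation `"vertical"` (strips along y, default) or
#'   `"horizontal"`; relevant for anisotropic or clustered maps.
#' @return a `fragment_set`: list with `frames` (one row per retained
#'   fragment: bounds, `tissue_fraction`, `tissue_area_mm2`) and `counts`
#'   (fragment x marker matrix of point counts).
#' @examples
#' m <- gen_cellmap(3000, 3000, "poisson", 100, seed = 1)
#' fr <- cut_map(m, "cuboid", edge_um = 300, min_tissue_fraction = 0)
#' nrow(fr$frames)  # 100 fragments on a 10 x 10 grid
#' @export
cut_map <- function(map, mode = c("cuboid", "slice"), edge_um = 300,
                    slice_width_um = 300, min_tissue_fraction = 0.5,
                    orientation = c("vertical", "horizontal")) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  stopifnot(inherits(map, "cellmap"))
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1) {
    stop_invalid("min_tissue_fraction must be in [0, 1]")
  }
  w <- map$width_um; h <- map$height_um
  if (mode == "cuboid") {
    check_scalar_pos(edge_um, "edge_um")
    if (edge_um > max(w, h)) {
      warning("edge_um exceeds the map extent; returning a single fragment")
    }
    xb <- unique(c(seq(0, w, by = edge_um), w))
    yb <- unique(c(seq(0, h, by = edge_um), h))
  } else {
    check_scalar_pos(slice_width_um, "slice_width_um")
    if (orientation == "vertical") {
      xb <- unique(c(seq(0, w, by = slice_width_um), w))
      yb <- c(0, h)
    } else {
      xb <- c(0, w)
      yb <- unique(c(seq(0, h, by = slice_width_um), h))
    }
  }
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  frames <- data.frame(
    frag_id = seq_len(nrow(grid)),
    x0 = xb[grid$ix], x1 = xb[grid$ix + 1L],
    y0 = yb[grid$iy], y1 = yb[grid$iy + 1L]
  )
  frames$tissue_fraction <- vapply(seq_len(nrow(frames)), function(k) {
    frag_tissue_fraction(map, frames$x0[k], frames$x1[k], frames$y0[k], frames$y1[k])
  }, numeric(1))
  frames$tissue_area_mm2 <- frames$tissue_fraction *
    (frames$x1 - frames$x0) * (frames$y1 - frames$y0) / 1e6

  # assign each point to its grid cell (half-open intervals, far border
  # clamped into the last cell)
  markers <- unique(map$points$marker)
  if (length(markers) == 0L) markers <- "CD3+"
  counts <- matrix(0L, nrow(frames), length(markers),
                   dimnames = list(NULL, markers))
  if (nrow(map$points)) {
    ix <- pmin(findInterval(map$points$x_um, xb, left.open = FALSE), nx)
    iy <- pmin(findInterval(map$points$y_um, yb, left.open = FALSE), ny)
    cell <- (iy - 1L) * nx + ix
    for (mk in markers) {
      sel <- map$points$marker == mk
      tab <- tabulate(cell[sel], nbins = nrow(frames))
      counts[, mk] <- tab
    }
  }
  keep <- frames$tissue_fraction >= min_tissue_fraction
  structure(list(frames = frames[keep, , drop = FALSE],
                 counts = counts[keep, , drop = FALSE],
                 mode = mode,
                 edge_um = if (mode == "cuboid") edge_um else slice_width_um),
            class = "fragment_set")
}

# Fraction of a rectangle covered by tissue; exact for mask = NULL, pixel
# sum for raster masks.
frag_tissue_fraction <- function(map, x0, x1, y0, y1) {
  if (is.null(map$mask)) return(1)
  res <- map$mask$res_um
  r <- map$mask$raster
  i <- seq(floor(x0 / res) + 1L, min(ceiling(x1 / res), nrow(r)))
  j <- seq(floor(y0 / res) + 1L, min(ceiling(y1 / res), ncol(r)))
  # pixel overlap weights along each axis
  px <- pmin(i * res, x1) - pmax((i - 1) * res, x0)
  py <- pmin(j * res, y1) - pmax((j - 1) * res, y0)
  sum(outer(px, py) * r[i, j, drop = FALSE]) / ((x1 - x0) * (y1 - y0))
}

#' Randomly pool fragments into wells and count a marker
#'
#' Shuffles fragments (without replacement) and fills `n_pools` disjoint
#' pools, each accumulating fragments until its summed tissue area reaches
#' `pool_area_mm2`. Matching pools by tissue area — not by fragment number —
#' is what makes slice pools and cuboid pools comparable: both see the same
#' amount of tissue, but a slice pool sees it in far fewer independent
#' sampling units, which is exactly the heterogeneity effect the simulation
#' quantifies.
#'
#' @param fragments a `fragment_set` from [cut_map()].
#' @param pool_area_mm2 target tissue area per pool (mm^2).
#' @param n_pools number of pools (>= 2).
#' @param marker marker to count (default `"CD3+"`).
#' @param seed integer seed for the shuffle.
#' @return a `pool_sampling` list: `per_pool_counts`, `cv_percent`
#'   (100 x sample SD / mean), `n_pools`, `pool_area_mm2`, `seed`.
#' @export
pool_and_count <- function(fragments, pool_area_mm2, n_pools, marker = "CD3+",
                           seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"))
  check_scalar_pos(pool_area_mm2, "pool_area_mm2")
  if (n_pools < 2) stop_invalid("n_pools must be >= 2")
  if (!marker %in% colnames(fragments$counts)) {
    stop_invalid("marker '", marker, "' not present in the fragment counts")
  }
  areas <- fragments$frames$tissue_area_mm2
  max_pools <- floor(sum(areas) / pool_area_mm2)
  if (max_pools < n_pools) {
    stop(errorCondition(
      sprintf("insufficient tissue: %.3f mm^2 available supports at most %d pool(s) of %.3f mm^2",
              sum(areas), max_pools, pool_area_mm2),
      class = c("ltf_insufficient_tissue", "error")))
  }
  set.seed(seed)
  ord <- sample.int(length(areas))
  cnts <- fragments$counts[ord, marker]
  ars <- areas[ord]
  per_pool <- integer(n_pools)
  k <- 1L
  for (p in seq_len(n_pools)) {
    acc <- 0; tot <- 0L
    while (acc < pool_area_mm2) {
      if (k > length(ars)) {
        stop(errorCondition(
          sprintf("insufficient tissue while filling pool %d; at most %d pool(s) achievable",
                  p, p - 1L),
          class = c("ltf_insufficient_tissue", "error")))
      }
      acc <- acc + ars[k]
      tot <- tot + cnts[k]
      k <- k + 1L
    }
    per_pool[p] <- tot
  }
  structure(list(per_pool_counts = per_pool,
                 cv_percent = cv_percent(per_pool),
                 n_pools = n_pools, pool_area_mm2 = pool_area_mm2,
                 marker = marker, seed = seed),
            class = "pool_sampling")
}

#' Cross-pool CV as a function of fragment size
#'
#' For each cuboid edge length (and the slice baseline) the map is cut,
#' pooled `n_randomizations` times with derived child seeds, and the
#' distribution of cross-pool CVs is recorded. Each edge is compared with
#' the slice baseline by a two-sided Mann-Whitney (Wilcoxon rank-sum) test
#' across the CV replicates — a distribution-free choice that matches the
#' randomized-pool design.
#'
#' @param map a [cellmap()].
#' @param edge_list_um cuboid edge lengths to evaluate (microns).
#' @param pool_area_mm2 target tissue area per pool.
#' @param n_pools pools per randomization (>= 2).
#' @param n_randomizations CV replicates per scheme (>= 2; a single
#'   randomization cannot form a distribution).
#' @param seed root seed; each scheme x randomization gets a child stream.
#' @param slice_width_um slice baseline width (default 300 microns, the
#'   thickness of a standard tissue slice).
#' @param min_tissue_fraction passed to [cut_map()].
#' @param marker marker to count.
#' @return list with `cv` (long data frame: `scheme`, `replicate`,
#'   `cv_percent`) and `tests` (per edge: median CV, slice median CV,
#'   two-sided Mann-Whitney p-value vs the slice baseline).
#' @export
cv_by_size <- function(map, edge_list_um, pool_area_mm2, n_pools,
                       n_randomizations, seed = 1L, slice_width_um = 300,
                       min_tissue_fraction = 0.5, marker = "CD3+") {
  if (length(edge_list_um) < 1) stop_invalid("need at least one edge length")
  if (n_randomizations < 2) {
    stop_invalid("n_randomizations must be >= 2 to form a CV distribution")
  }
  schemes <- c(list(slice = cut_map(map, "slice", slice_width_um = slice_width_um,
                                    min_tissue_fraction = min_tissue_fraction)),
               stats::setNames(
                 lapply(edge_list_um, function(e)
                   cut_map(map, "cuboid", edge_um = e,
                           min_tissue_fraction = min_tissue_fraction)),
                 paste0("cuboid_", edge_list_um)))
  cv_long <- do.call(rbind, lapply(seq_along(schemes), function(s) {
    cvs <- vapply(seq_len(n_randomizations), function(r) {
      pool_and_count(schemes[[s]], pool_area_mm2, n_pools, marker,
                     seed = child_seed(seed, s, r))$cv_percent
    }, numeric(1))
    data.frame(scheme = names(schemes)[s], replicate = seq_len(n_randomizations),
               cv_percent = cvs, stringsAsFactors = FALSE)
  }))
  slice_cv <- cv_long$cv_percent[cv_long$scheme == "slice"]
  tests <- do.call(rbind, lapply(edge_list_um, function(e) {
    ecv <- cv_long$cv_percent[cv_long$scheme == paste0("cuboid_", e)]
    p <- stats::wilcox.test(ecv, slice_cv, exact = FALSE)$p.value
    data.frame(edge_um = e, median_cv = stats::median(ecv),
               slice_median_cv = stats::median(slice_cv), p_value = p)
  }))
  list(cv = cv_long, tests = tests)
}

#' Cuboid fragment geometry
#'
#' Closed-form face area and volume of a cuboid fragment with the given
#' edge length: a 300 um fragment has a face of 0.09 mm^2 and a volume of
#' 0.027 mm^3, so 200 fragments carry about 5.4 mm^3 of tissue.
#'
#' @param edge_um cuboid edge length in microns (> 0).
#' @return list with `edge_um`, `face_area_mm2`, `volume_mm3`.
#' @export
cuboid_geometry <- function(edge_um) {
  check_scalar_pos(edge_um, "edge_um")
  e_mm <- edge_um / 1000
  list(edge_um = edge_um, face_area_mm2 = e_mm^2, volume_mm3 = e_mm^3)
}

#' Core needle biopsy slicing geometry
#'
#' Models the core as a cylinder of diameter `core_diameter_mm` and length
#' `core_length_mm` cut into slices of thickness `slice_thickness_um` at
#' angle `cut_angle_deg` to the longitudinal axis. At 90 degrees the cross
#' section is the circle pi d^2 / 4 and the blade advances one thickness per
#' slice; at an oblique angle theta the section is an ellipse with semi-axes
#' d/2 and d/(2 sin theta) and the axial advance per slice is
#' thickness / sin(theta), so fewer slices fit. The summed slice volume
#' never exceeds the cylinder volume.
#'
#' @param core_diameter_mm needle core diameter (mm).
#' @param core_length_mm core length (mm).
#' @param slice_thickness_um slice thickness (microns; must be smaller than
#'   the core length).
#' @param cut_angle_deg cutting angle in (0, 90] degrees.
#' @return list with `n_slices`, `slice_area_mm2`, `slice_volume_mm3`,
#'   `total_volume_mm3`, `cylinder_volume_mm3` and the inputs.
#' @export
cnb_geometry <- function(core_diameter_mm, core_length_mm,
                         slice_thickness_um, cut_angle_deg = 90) {
  check_scalar_pos(core_diameter_mm, "core_diameter_mm")
  check_scalar_pos(core_length_mm, "core_length_mm")
  check_scalar_pos(slice_thickness_um, "slice_thickness_um")
  if (!is.numeric(cut_angle_deg) || cut_angle_deg <= 0 || cut_angle_deg > 90) {
    stop_invalid("cut_angle_deg must be in (0, 90]")
  }
  t_mm <- slice_thickness_um / 1000
  if (t_mm >= core_length_mm) stop_invalid("slice thickness must be smaller than core length")
  s <- sin(cut_angle_deg * pi / 180)
  advance_mm <- t_mm / s
  n_slices <- floor(core_length_mm / advance_mm)
  slice_area_mm2 <- pi * core_diameter_mm^2 / (4 * s)  # ellipse: pi (d/2)(d/(2s))
  slice_volume_mm3 <- slice_area_mm2 * t_mm
  cyl_vol <- pi * (core_diameter_mm / 2)^2 * core_length_mm
  total <- min(n_slices * slice_volume_mm3, cyl_vol)
  list(core_diameter_mm = core_diameter_mm, core_length_mm = core_length_mm,
       slice_thickness_um = slice_thickness_um, cut_angle_deg = cut_angle_deg,
       n_slices = n_slices, slice_area_mm2 = slice_area_mm2,
       slice_volume_mm3 = slice_volume_mm3, total_volume_mm3 = total,
       cylinder_volume_mm3 = cyl_vol)
}
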