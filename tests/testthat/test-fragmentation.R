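test_that("cutting tiles the map and conserves counts", {
  m <- gen_cellmap(3000, 3000, "poisson", 150, seed = 1)
  cub <- cut_map(m, "cuboid", edge_um = 300, min_tissue_fraction = 0)
  expect_equal(nrow(cub$frames), 100)  # 10 x 10 grid
  sl <- cut_map(m, "slice", slice_width_um = 300, min_tissue_fraction = 0)
  expect_equal(nrow(sl$frames), 10)
  # conservation: every point in exactly one fragment
  expect_equal(sum(cub$counts), nrow(m$points))
  expect_equal(sum(sl$counts), nrow(m$points))
  # horizontal orientation gives strips along the other axis
  sh <- cut_map(m, "slice", slice_width_um = 300, min_tissue_fraction = 0,
                orientation = "horizontal")
  expect_equal(nrow(sh$frames), 10)
  expect_equal(sum(sh$counts), nrow(m$points))
})

test_that("oversized edge yields a single fragment with a warning", {
  m <- gen_cellmap(1000, 1000, "poisson", 50, seed = 2)
  expect_warning(fr <- cut_map(m, "cuboid", edge_um = 5000,
                               min_tissue_fraction = 0), "single fragment")
  expect_equal(nrow(fr$frames), 1)
  expect_equal(sum(fr$counts), nrow(m$points))
})

test_that("pooling matches tissue area, errors on insufficient tissue, and CV is exact", {
  m <- gen_cellmap(3000, 3000, "poisson", 150, seed = 3)
  fr <- cut_map(m, "cuboid", edge_um = 300, min_tissue_fraction = 0)
  p <- pool_and_count(fr, 0.9, 4, seed = 5)
  expect_equal(p$cv_percent, 100 * sd(p$per_pool_counts) / mean(p$per_pool_counts))
  expect_identical(pool_and_count(fr, 0.9, 4, seed = 5)$per_pool_counts,
                   p$per_pool_counts)
  err <- tryCatch(pool_and_count(fr, 4, 4, seed = 1), error = identity)
  expect_s3_class(err, "ltf_insufficient_tissue")
  expect_match(conditionMessage(err), "at most 2 pool")
  expect_error(pool_and_count(fr, 0.9, 1, seed = 1), class = "ltf_invalid_parameter")
})

test_that("identical fragment counts give CV = 0", {
  # a regular lattice of one point per 300 um cell
  centers <- expand.grid(x_um = seq(150, 2850, by = 300),
                         y_um = seq(150, 2850, by = 300))
  centers$marker <- "CD3+"
  m <- cellmap(3000, 3000, centers)
  fr <- cut_map(m, "cuboid", edge_um = 300, min_tissue_fraction = 0)
  expect_true(all(fr$counts == 1))
  p <- pool_and_count(fr, 0.9, 5, seed = 1)
  expect_equal(p$cv_percent, 0)
})

test_that("pool CV follows the 100/sqrt(N) Poisson law (light version)", {
  cvs <- vapply(1:100, function(s) {
    m <- gen_cellmap(3000, 3000, "poisson", 200, seed = s)
    fr <- cut_map(m, "cuboid", edge_um = 300, min_tissue_fraction = 0)
    pool_and_count(fr, 0.9, 8, seed = s)$cv_percent
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 100 / sqrt(180)) / (100 / sqrt(180)), 0.15)
})

test_that("cv_by_size orders clustered maps and validates inputs", {
  m <- gen_cellmap(15000, 15000, "thomas", 300, mean_offspring = 400,
                   sigma_um = 500, seed = 42)
  r <- cv_by_size(m, c(100, 300), pool_area_mm2 = 4.5, n_pools = 4,
                  n_randomizations = 12, seed = 42)
  med <- tapply(r$cv$cv_percent, r$cv$scheme, median)
  expect_gt(med[["slice"]], med[["cuboid_300"]])
  expect_gte(med[["cuboid_300"]], med[["cuboid_100"]])
  expect_true(all(r$tests$p_value >= 0 & r$tests$p_value <= 1))
  expect_error(cv_by_size(m, c(300), 2.7, 4, n_randomizations = 1, seed = 1),
               class = "ltf_invalid_parameter")
})

test_that("cuboid geometry closed forms are exact", {
  g <- cuboid_geometry(300)
  expect_equal(g$face_area_mm2, 0.09)
  expect_equal(g$volume_mm3, 0.027)
  expect_equal(200 * g$volume_mm3, 5.4)
  g1 <- cuboid_geometry(1000)
  expect_equal(g1$face_area_mm2, 1)
  expect_equal(g1$volume_mm3, 1)
  expect_error(cuboid_geometry(0), class = "ltf_invalid_parameter")
})

test_that("cnb geometry: perpendicular and oblique slicing", {
  g <- cnb_geometry(1, 9.9, 300, 90)
  expect_equal(g$n_slices, 33)
  expect_equal(g$slice_area_mm2, pi / 4)
  # 90 degrees reduces the ellipse to the circle
  expect_equal(cnb_geometry(2, 10, 250, 90)$slice_area_mm2, pi * 2^2 / 4)
  # oblique: fewer slices, larger sections, volume bound holds
  for (ang in c(20, 45, 67, 90)) {
    go <- cnb_geometry(1.2, 8, 300, ang)
    expect_lte(go$total_volume_mm3, go$cylinder_volume_mm3 + 1e-12)
    expect_equal(go$slice_area_mm2,
                 pi * 1.2^2 / (4 * sin(ang * pi / 180)))
  }
  expect_lt(cnb_geometry(1, 9.9, 300, 20)$n_slices, 33)
  expect_error(cnb_geometry(1, 9.9, 300, 0), class = "ltf_invalid_parameter")
  expect_error(cnb_geometry(1, 9.9, 300, 91), class = "ltf_invalid_parameter")
  expect_error(cnb_geometry(1, 0.2, 300, 90), class = "ltf_invalid_parameter")
})

test_that("mask-aware cutting respects min_tissue_fraction", {
  # left half tissue, right half background, 100 um pixels
  raster <- matrix(FALSE, 30, 30)
  raster[1:15, ] <- TRUE
  mask <- list(raster = raster, res_um = 100)
  m <- gen_cellmap(3000, 3000, "poisson", 200, mask = mask, seed = 8)
  expect_true(all(m$points$x_um <= 1500))
  fr <- cut_map(m, "cuboid", edge_um = 300, min_tissue_fraction = 0.5)
  expect_equal(nrow(fr$frames), 50)   # only the tissue half is retained
  expect_equal(sum(fr$counts), nrow(m$points))
  expect_equal(tissue_area_mm2(m), 4.5)
})
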