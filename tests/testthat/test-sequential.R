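test_that("phase_slope fits each window, sharing the boundary sample", {
  ws <- make_series(c(4, 20, 48), c(40, 200, 480))
  expect_equal(phase_slope(ws, "IFN-gamma", "IgG"), 10)   # (200-40)/16
  expect_equal(phase_slope(ws, "IFN-gamma", "ICI"), 10)   # (480-200)/28
  flat <- make_series(c(4, 20, 48), c(40, 200, 200))
  expect_equal(phase_slope(flat, "IFN-gamma", "ICI"), 0)
  expect_error(phase_slope(ws, "IFN-gamma", "aCD3"), class = "ltf_invalid_parameter")
})

test_that("capped points are excluded from slope fits", {
  ws <- make_series(c(4, 20, 48), c(40, 200, 5000),
                    censor = c("none", "none", "capped_uloq"))
  expect_warning(expect_message(s <- phase_slope(ws, "IFN-gamma", "ICI"),
                                "capped"), "undefined")
  expect_true(is.na(s))
  # three in-phase points, one capped: slope uses the other two
  ws3 <- make_series(c(4, 20, 34, 48), c(40, 200, 340, 5000),
                     censor = c("none", "none", "none", "capped_uloq"))
  expect_message(s3 <- phase_slope(ws3, "IFN-gamma", "ICI"), "capped")
  expect_equal(s3, 10)
})

test_that("slope_fc guards the division and classify_fc applies the bands", {
  expect_equal(slope_fc(10, 25)$fc, 2.5)
  r <- slope_fc(0, 25)
  expect_true(is.na(r$fc)); expect_false(r$valid)
  expect_false(slope_fc(0.5, 25, epsilon = 1)$valid)
  # scale invariance
  expect_equal(slope_fc(3 * 10, 3 * 25)$fc, 2.5)
  expect_equal(classify_fc(c(12.4, 1.5, 0.5, 1.51, 0.4, NA, 0.9)),
               c("increase", "no_change", "no_change", "increase",
                 "decrease", "indeterminate", "no_change"))
})

test_that("classify_fc is a total monotone step function", {
  fc <- sort(c(runif(50, 0, 3), 0.5, 1.5))
  cls <- classify_fc(fc)
  lev <- c(decrease = 1, no_change = 2, increase = 3)
  expect_true(all(diff(lev[cls]) >= 0))
})

test_that("offset and scale invariance of the slope statistic", {
  ws <- make_series(c(4, 20, 48), c(40, 200, 480))
  base <- phase_slope(ws, "IFN-gamma", "IgG")
  shifted <- make_series(c(4, 20, 48), c(40, 200, 480) + 55)
  expect_equal(phase_slope(shifted, "IFN-gamma", "IgG"), base)
  scaled <- make_series(c(4, 20, 48), c(40, 200, 480) * 3)
  fc0 <- slope_fc(base, phase_slope(ws, "IFN-gamma", "ICI"))$fc
  fcs <- slope_fc(phase_slope(scaled, "IFN-gamma", "IgG"),
                  phase_slope(scaled, "IFN-gamma", "ICI"))$fc
  expect_equal(fcs, fc0)
})

test_that("aggregate_replicates takes the max FC and the any-increase flag", {
  tab <- data.frame(specimen_id = "S1", well_id = c("w1", "w2", "w3"),
                    analyte = "IFN-gamma", control_slope = 10,
                    treatment_slope = c(11, 32, 9),
                    fc = c(1.1, 3.2, 0.9),
                    class = c("no_change", "increase", "no_change"))
  agg <- aggregate_replicates(tab)
  expect_equal(agg$max_fc, 3.2)
  expect_true(agg$any_increase)
  expect_false(agg$unevaluable)
  single <- aggregate_replicates(tab[1, ])
  expect_equal(single$max_fc, 1.1)
  allna <- tab; allna$fc <- NA_real_; allna$class <- "indeterminate"
  expect_true(aggregate_replicates(allna)$unevaluable)
})

test_that("one responder well among null wells is detected by any_increase", {
  panel <- tiny_panel()
  ks <- kinetics_spec(measurement_cv = 20, cv_at_200 = 0)
  hits <- vapply(1:60, function(s) {
    resp <- gen_well_series(list(specimen_id = "S1", responder = TRUE), ks,
                            panel, "sequential",
                            responsive_analytes = "IFN-gamma",
                            effect_theta = 4, n_replicates = 1,
                            seed = child_seed(s, 1))
    null <- gen_well_series(list(specimen_id = "S1", responder = FALSE), ks,
                            panel, "sequential", effect_theta = 4,
                            n_replicates = 5, seed = child_seed(s, 2))
    fc <- do.call(rbind, lapply(c(resp, null), well_slope_fc, panel = panel))
    agg <- aggregate_replicates(fc)
    agg$any_increase[agg$analyte == "IFN-gamma"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("concordance counts matching classes per analyte", {
  cw <- data.frame(specimen_id = paste0("S", 1:6), analyte = "IFN-gamma",
                   class = c("increase", "increase", "increase",
                             "increase", "increase", "no_change"))
  sq <- cw; sq$class[6] <- "increase"  # 5 of 6 match
  out <- concordance(cw, sq)
  expect_equal(out$percent_concordant, 83)
  expect_equal(nrow(attr(out, "discordant")), 1)
  expect_equal(concordance(cw, cw)$percent_concordant, 100)
  expect_error(concordance(cw[0, ], sq[0, ]), class = "ltf_invalid_parameter")
})

test_that("zero-noise paired designs are fully concordant", {
  panel <- tiny_panel()
  ks <- noise_free_kinetics()
  for (s in 1:5) {
    for (resp in c(TRUE, FALSE)) {
      sp <- list(specimen_id = sprintf("S%d%d", s, resp), responder = resp)
      seq_w <- gen_well_series(sp, ks, panel, "sequential",
                               effect_theta = 3, n_replicates = 1, seed = s)
      cw_w <- gen_well_series(sp, ks, panel, "crosswell",
                              effect_theta = 3, n_replicates = 1, seed = s)
      fc_seq <- well_slope_fc(seq_w[[1]], panel)
      # cross-well fold change: ICI-well slope over IgG-well slope
      m <- do.call(rbind, lapply(cw_w, ltfassay:::as_measurements))
      fc_cw <- do.call(rbind, lapply(panel$analyte, function(a) {
        igg <- m[m$analyte == a & m$treatment == "IgG", ]
        ici <- m[m$analyte == a & m$treatment == "ICI", ]
        data.frame(specimen_id = sp$specimen_id, analyte = a,
                   class = classify_fc(slope_fc(
                     rate_of_change(igg$t_h, igg$conc_pg_ml),
                     rate_of_change(ici$t_h, ici$conc_pg_ml))$fc))
      }))
      out <- concordance(fc_cw,
                         fc_seq[, c("specimen_id", "analyte", "class")])
      expect_true(all(out$percent_concordant == 100))
    }
  }
})

test_that("recist_percent_change reproduces the worked example and boundary", {
  r <- recist_percent_change(54.6, 34.2)
  expect_equal(round(r$percent_change), -37)
  expect_true(r$partial_response)
  r0 <- recist_percent_change(100, 100)
  expect_equal(r0$percent_change, 0)
  expect_false(r0$partial_response)
  r31 <- recist_percent_change(100, 69)
  expect_equal(r31$percent_change, -31)
  expect_true(r31$partial_response)
  # reduction of exactly 30% is not a partial response (strict >30%)
  expect_false(recist_percent_change(100, 70)$partial_response)
  expect_error(recist_percent_change(0, 10), class = "ltf_invalid_parameter")
})
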