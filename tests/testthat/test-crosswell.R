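crosswell_pair <- function(ici, igg, analyte = "IFN-gamma") {
  mk <- function(v, trt, w) {
    well_series("S001", w, "crosswell",
                data.frame(t_start_h = 0, t_end_h = 48, treatment = trt),
                data.frame(t_h = 48, analyte = analyte, conc_pg_ml = v,
                           censor = "none", stringsAsFactors = FALSE))
  }
  c(mapply(mk, ici, "ICI", paste0("I", seq_along(ici)), SIMPLIFY = FALSE),
    mapply(mk, igg, "IgG", paste0("G", seq_along(igg)), SIMPLIFY = FALSE))
}

test_that("cumulative_difference is the difference of arm means and antisymmetric", {
  wells <- crosswell_pair(c(120, 130), c(100, 90))
  expect_equal(cumulative_difference(wells, "IFN-gamma", 48), 30)
  expect_equal(cumulative_difference(wells, "IFN-gamma", 48,
                                     treatment_ici = "IgG",
                                     treatment_control = "ICI"), -30)
  same <- crosswell_pair(c(100, 90), c(100, 90))
  expect_equal(cumulative_difference(same, "IFN-gamma", 48), 0)
  only_ici <- crosswell_pair(c(100), numeric(0))
  expect_error(cumulative_difference(only_ici, "IFN-gamma", 48), "IgG")
})

test_that("mad_trimmed_modz follows the stated steps", {
  # hand evaluation: [1,2,3,4,100] -> trimmed {1,2,3,4}, m*=2.5, MAD*=1,
  # z(100) = 0.6745 * 97.5 = 65.76 -> saturated at 10
  z <- mad_trimmed_modz(c(1, 2, 3, 4, 100))
  expect_equal(z, c(0.6745 * (c(1, 2, 3, 4) - 2.5) / 1, 10))
  # symmetric [-1, 0, 1]
  expect_equal(mad_trimmed_modz(c(-1, 0, 1)), c(-0.6745, 0, 0.6745))
  # degenerate spread -> all zero under the fallback
  expect_message(z0 <- mad_trimmed_modz(rep(5, 6)), "0")
  expect_equal(z0, rep(0, 6))
  expect_error(mad_trimmed_modz(c(1, 2)), class = "ltf_invalid_parameter")
})

test_that("mad_trimmed_modz matches the literal oracle on random vectors", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    x <- switch(1 + i %% 3,
                rnorm(n, 0, 10),
                rcauchy(n),                        # heavy outliers
                c(rnorm(n - 2), rnorm(2, 50, 5)))  # planted responders
    got <- suppressMessages(mad_trimmed_modz(x))
    expect_equal(got, oracle_modz(x), tolerance = 1e-10)
    expect_lte(max(abs(got)), 10)
  }
})

test_that("modz is shift/scale equivariant as stated", {
  set.seed(7)
  x <- rnorm(20, 3, 4)
  z <- mad_trimmed_modz(x)
  expect_equal(mad_trimmed_modz(x + 100), z, tolerance = 1e-9)
  expect_equal(mad_trimmed_modz(x * 3.5), z, tolerance = 1e-9)
})

test_that("upregulation calls are inclusive at the threshold", {
  z <- matrix(c(5.0, 4.99, 10, -10, NA, 7), nrow = 2,
              dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  up <- suppressMessages(call_upregulated(z, 5.0))
  expect_true(up$calls["S1", "A"])     # z = 5.0 exactly -> called
  expect_false(up$calls["S2", "A"])    # 4.99 -> not called
  expect_false(up$calls["S1", "C"])    # missing -> not called
  expect_equal(unname(up$counts), c(2, 1))
  # all-saturated row over 24 analytes counts 24
  zz <- matrix(10, 1, 24, dimnames = list("S1", paste0("a", 1:24)))
  expect_equal(unname(suppressMessages(call_upregulated(zz))$counts), 24)
})

test_that("ward_cluster matches the enumeration oracle and is order invariant", {
  # planted two-cluster data, 4 points
  x <- matrix(c(0, 0, 0.2, 0.1, 5, 5, 5.3, 5.2), 4, 2, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), c("A", "B")))
  cl <- ward_cluster(x)
  o <- oracle_ward(x)
  expect_identical(hclust_merge_sets(cl$specimen_hclust), o$merges)
  expect_equal(cl$specimen_hclust$height, o$heights, tolerance = 1e-10)
  # identical specimens merge first at zero height
  y <- rbind(x, S5 = x["S1", ])
  cly <- ward_cluster(y)
  expect_equal(min(cly$specimen_hclust$height), 0)
  expect_identical(sort(hclust_merge_sets(cly$specimen_hclust)[[1]]),
                   c(1L, 5L))  # S1 and S5 after label sorting
  # permutation invariance of topology (labels sorted internally)
  perm <- x[c(3, 1, 4, 2), ]
  expect_identical(hclust_merge_sets(ward_cluster(perm)$specimen_hclust),
                   hclust_merge_sets(cl$specimen_hclust))
  # a larger random instance against the oracle
  set.seed(12)
  r <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("S", 1:7), c("A", "B")))
  expect_identical(hclust_merge_sets(ward_cluster(r)$specimen_hclust),
                   oracle_ward(r)$merges)
})

test_that("ward_cluster imputation policy", {
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("S", 1:5), paste0("A", 1:10)))
  x[1, 1] <- NA   # 10% of the row: imputed
  expect_message(ward_cluster(x), "imputed")
  x[1, 2:4] <- NA   # 40% of the row: beyond the policy
  expect_error(ward_cluster(x), class = "ltf_invalid_parameter")
})

test_that("biomarker_enrichment: identical groups give p = 1, Fisher matches oracle", {
  z <- matrix(c(6, 6, 1, 1, 6, 6, 1, 1), 8, 1,
              dimnames = list(paste0("S", 1:8), "A"))
  st <- setNames(rep(c("positive", "negative"), each = 4), paste0("S", 1:8))
  # identical response pattern in both groups
  enr <- suppressMessages(biomarker_enrichment(z, st))
  expect_equal(enr$count_test$p_value, 1)
  expect_equal(enr$fisher$fisher_p[1], 1)
  # the worked 2x2 example through the package path
  expect_equal(stats::fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value,
               oracle_fisher(3, 1, 1, 3))
  expect_equal(oracle_fisher(3, 1, 1, 3), 34 / 70)
  expect_error(suppressMessages(
    biomarker_enrichment(z, setNames(c("positive", rep("negative", 7)),
                                     paste0("S", 1:8)))),
    class = "ltf_invalid_parameter")
})

test_that("build_response_matrix equals per-pair cumulative_difference + modz", {
  panel <- tiny_panel()
  set.seed(31)
  wells <- list()
  for (s in 1:6) {
    for (a in panel$analyte) {
      ici <- rnorm(2, 100 * s, 5); igg <- rnorm(2, 80, 5)
      mk <- function(v, trt, w) well_series(
        sprintf("S%02d", s), sprintf("S%02d_%s_%s", s, trt, w), "crosswell",
        data.frame(t_start_h = 0, t_end_h = 48, treatment = trt),
        data.frame(t_h = 48, analyte = a, conc_pg_ml = v, censor = "none"))
      wells <- c(wells, mapply(mk, ici, "ICI", c("w1", "w2"), SIMPLIFY = FALSE),
                 mapply(mk, igg, "IgG", c("w3", "w4"), SIMPLIFY = FALSE))
    }
  }
  # merge the per-analyte wells of one specimen into single well series is
  # not needed: the matrix builder works from the long table
  z <- build_response_matrix(wells, panel)
  d <- attr(z, "deltas")
  m <- do.call(rbind, lapply(wells, ltfassay:::as_measurements))
  for (s in rownames(d)) for (a in colnames(d)) {
    expect_equal(d[s, a],
                 cumulative_difference(m[m$specimen_id == s, ], a, 48))
  }
  for (a in colnames(d)) {
    expect_equal(unname(z[, a]), unname(oracle_modz(d[, a])), tolerance = 1e-10)
  }
  expect_lte(max(abs(z), na.rm = TRUE), 10)  # saturation invariant
})

test_that("responders out-respond non-responders in the synthetic cohort", {
  panel <- default_panel()
  cs <- cohort_spec(n_specimens = 24, biomarker_positive_fraction = 0.5,
                    effect_theta = 3, n_replicates = 2, seed = 5)
  coh <- gen_cohort(cs, panel)
  wells <- unlist(lapply(seq_len(nrow(coh)), function(i)
    gen_well_series(coh[i, ], kinetics_spec(), panel, "crosswell",
                    effect_theta = 3, seed = child_seed(5, 2, i))),
    recursive = FALSE)
  pq <- exclude_low_analytes(wells, panel)
  z <- suppressMessages(build_response_matrix(wells, pq))
  up <- suppressMessages(call_upregulated(z))
  expect_gt(median(up$counts[coh$responder]), median(up$counts[!coh$responder]))
})
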