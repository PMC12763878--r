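# ltfassay

Analysis toolkit for ex vivo live-tumor-fragment (LTF) immunotherapy
response assays. Fresh tumor tissue — a resection or a core needle biopsy
(CNB) — is cut into ~300 µm fragments, cultured in hydrogel, treated with an
immune checkpoint inhibitor (ICI) or IgG control, and read out through the
cytokines secreted into conditioned media. This package implements the
statistics that make those readouts interpretable, for platform developers
and computational biologists:

* **Fragmentation simulation** — how finely must tissue be cut so that
  randomly pooled wells are comparable? A 2D point-process simulator
  (Poisson or Thomas-clustered CD3⁺ maps), slice/cuboid cutting, random
  pooling at matched tissue area, and CV comparisons
  (`gen_cellmap`, `cut_map`, `pool_and_count`, `cv_by_size`), plus exact
  LTF/CNB geometry (`cuboid_geometry`, `cnb_geometry`).
* **Quantitation QC** — LLOQ/ULOQ censoring, exclusion of consistently
  unquantifiable analytes, detection coverage and replicate CVs
  (`apply_censoring`, `exclude_low_analytes`, `pct_above_lloq`,
  `replicate_cv`, `rate_of_change`).
* **Cross-well response** (resections): per-specimen ICI − IgG cumulative
  concentration differences, standardized per analyte across the cohort as
  MAD-trimmed modified Z-scores

  `z = 0.6745 (x − m*) / MAD*`, saturated to ±10,

  where `m*`/`MAD*` are recomputed on the samples within 2 MAD of the
  median; upregulation is the conservative call `z ≥ 5`. Ward clustering
  and biomarker (PD-L1/MMR/MSI) enrichment via Mann–Whitney and Fisher
  exact tests (`build_response_matrix`, `call_upregulated`, `ward_cluster`,
  `biomarker_enrichment`).
* **Sequential response** (CNBs): each well is its own control — IgG
  0–20 h, then ICI to 48 h; the statistic is the fold change of OLS slopes
  of cumulative production, `FC = slope(ICI phase) / slope(control phase)`,
  classified as increase (> 1.5), no change (0.5–1.5) or decrease (< 0.5),
  aggregated over replicates by max FC and an any-increase flag
  (`phase_slope`, `slope_fc`, `classify_fc`, `aggregate_replicates`,
  `concordance`, `recist_percent_change`).
* **Synthetic data with ground truth** — cohorts with biomarker-linked
  hidden responder status and longitudinal cytokine trajectories under a
  two-level lognormal noise model, so every stage has a parameter-recovery
  test surface (`cohort_spec`, `kinetics_spec`, `gen_cohort`,
  `gen_well_series`).
* **IO / pipeline / CLI** — tidy CSV interchange, JSON configs and panels,
  a deterministic end-to-end runner with a manifest (`read_measurements`,
  `run_pipeline`), and a CLI (`ltf_cli`; `inst/cli/ltfassay`).

See the methods vignette (`vignettes/ltfassay-methods.Rmd`) for the models,
assumptions, calibration of the simulation defaults, and known limitations
(including two acceptance properties that the stated simulation world
cannot meet, analyzed there rather than patched).

## Worked example

```r
library(ltfassay)

# geometry sanity: a 300 um cuboid LTF, 200 per well
g <- cuboid_geometry(300)
# face 0.09 mm^2, volume 0.027 mm^3, 200 LTFs = 5.4 mm^3

# a small synthetic resection cohort with hidden ground truth
panel <- default_panel()
cs <- cohort_spec(n_specimens = 12, biomarker_positive_fraction = 0.5,
                  effect_theta = 4, n_replicates = 3, seed = 7)
coh <- gen_cohort(cs, panel)
wells <- unlist(lapply(seq_len(nrow(coh)), function(i)
  gen_well_series(coh[i, ], kinetics_spec(), panel, "crosswell",
                  effect_theta = 4, seed = child_seed(7, 2, i))),
  recursive = FALSE)

panel_qc <- exclude_low_analytes(wells, panel)
panel_qc$analyte[panel_qc$excluded]
#> "CD40L" "EGF" "FGF basic" "IL-12p70" "IL-15" "FLT-3L"   # the 6 dead analytes

z  <- build_response_matrix(wells, panel_qc)   # specimen x analyte, |z| <= 10
up <- call_upregulated(z, 5)
data.frame(specimen = names(up$counts), biomarker = coh$biomarker_status,
           responder = coh$responder, n_upregulated = unname(up$counts))
#>    specimen biomarker responder n_upregulated
#> 1      S001  positive     FALSE             0
#> 2      S002  positive      TRUE             6
#> 5      S005  positive      TRUE             8
#> 10     S010  positive      TRUE             9
#> ...        (the three hidden responders carry the upregulated cytokines)

biomarker_enrichment(z, coh)$count_test
#> p = 0.0467, median upregulated count 7 (positive) vs 0 (negative)

# a responsive CNB specimen under sequential treatment, 2 replicate wells
ws <- gen_well_series(list(specimen_id = "CNB1", responder = TRUE),
                      kinetics_spec(), panel, "sequential",
                      responsive_analytes = c("IFN-gamma", "CXCL10"),
                      effect_theta = 6, n_replicates = 2, seed = 42)
fc  <- do.call(rbind, lapply(ws, well_slope_fc, panel = panel_qc))
agg <- aggregate_replicates(fc)
subset(agg, analyte %in% c("IFN-gamma", "CXCL10", "IL-1Ra"))
#>    specimen_id   analyte    max_fc any_increase n_valid unevaluable
#>           CNB1    CXCL10 5.628            TRUE       2       FALSE
#>           CNB1 IFN-gamma 6.652            TRUE       2       FALSE
#>           CNB1    IL-1Ra 0.709           FALSE       2       FALSE

# clinical comparison helper
recist_percent_change(54.6, 34.2)
#> percent_change -37.4, partial_response TRUE
```

The max FC > 1.5 for IFN-γ/CXCL10 with an unchanged IL-1Ra is the
signature of an ICI-responsive specimen; `any_increase` is the
specimen-level sensitivity call.

## Command line

```sh
inst/cli/ltfassay simulate --config cfg.json --seed 1 --out out/
inst/cli/ltfassay fragment --map points.csv --edge-um 100,300 \
    --pool-area-mm2 4.5 --n-pools 4 --n-randomizations 12 --out out/
inst/cli/ltfassay qc --measurements media.csv --out out/
inst/cli/ltfassay sequential --measurements media.csv --out out/
```

Exit codes: 0 ok, 1 user error, 2 internal error.
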