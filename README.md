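# spotzone

Tumor-margin zonation analysis for spot-based spatial transcriptomics.

Lung adenocarcinomas (and solid tumors generally) remodel their
microenvironment in narrow rims around the invasive margin: fibroblast
and macrophage populations pile up within a few hundred microns of the
border, and malignant cells at the leading edge behave differently from
the core. `spotzone` turns 50-µm-binned spatial transcriptomics into
quantitative margin biology, for analysts who already have deconvolved
cell-type abundances per spot and want the downstream spatial analysis:

* **Spot assignment** — per-spot abundances are scaled to [0, 1]; a spot
  is assigned to its dominant cell type when the dominant/second ratio
  strictly exceeds the 10th percentile of the section's finite-ratio
  distribution.
* **Border detection** — the malignant-cell abundance raster is
  thresholded (Otsu), Gaussian-blurred, Canny-edge-detected, closed and
  filled; contours are refined to sub-pixel iso-contours and simplified;
  the largest candidate polygon is the region of interest and its
  boundary the tumor *borderline*.
* **Zonal bands** — the margin is split into six 500-µm bands by signed
  distance to the borderline: TR1–TR3 (tumor side, `[0,500)`,
  `[500,1000)`, `[1000,1500)` µm) and NR1–NR3 (normal side, `(0,500]`,
  `(500,1000]`, `(1000,1500]` µm) — the signed-distance equivalent of
  perpendicular parallel offsets at 500/1000/1500 µm on both sides.
* **Zonal statistics** — per-band cell-type composition (call
  proportions or mean relative abundances), two-sided
  Wilcoxon–Mann–Whitney tests (exact tie-aware enumeration for
  n + m ≤ 12), Benjamini–Hochberg correction.
* **Differential expression** — per-gene Welch t-tests on
  log1p-normalized expression; a gene is flagged when
  |log2FC| ≥ 1.5 and BH-adjusted p < 0.05, with log2FC measured on the
  linear scale as `log2(expm1(m̄_a)/expm1(m̄_b))`.
* **Gene-set scores** — mean set expression minus an expression-matched
  control set (25 bins, 50 controls per gene).
* **CNV profiles** — genome-ordered 250-gene moving average of
  reference-subtracted log-expression (windows truncated at chromosome
  boundaries), per-spot burden (signed mean = net gain; mean square =
  aberration load) and Mann–Whitney group comparisons.
* **Synthetic sections** — a simulator with planted tumor geometry,
  stromal gradients, negative-binomial counts and CNV blocks gives every
  stage a ground-truth recovery test.

## Worked example

Simulate a 7 × 7 mm section (19 600 spots) with a 1700-µm tumor, a
tumor-side fibroblast gradient (peak 0.3, decay 400 µm), and run the
margin pipeline:

```r
library(spotzone)

scn <- scene(width_um = 7000, height_um = 7000, tumor_radius = 1700,
             gradient_specs = list(list(cell_type = "fibroblast",
                                        side = "tumor", decay_um = 400,
                                        peak = 0.3)),
             seed = 42)
panel   <- make_signature_panel(n_genes = 250, n_types = 5, seed = 1)
section <- simulate_section(scn, panel)

region     <- detect_tumor_region(rasterize_abundance(section, "AT2-like"))
borderline <- extract_borderline(region)
bands      <- build_bands(borderline)
calls      <- assign_spots(normalize_abundance(section$abundance), q = 10)
calls
#> assignment_result: 17640 of 19600 spots assigned (90.0%), ratio threshold 5.51 at q = 10

band_labels <- assign_spots_to_bands(section, bands)
comp <- band_composition(band_labels, section$abundance)
comp[comp$cell_type == "fibroblast", c("band", "n_spots", "proportion")]
#>  band n_spots proportion
#>   NR3    3709     0.0556
#>   NR2    3097     0.0556
#>   NR1    2447     0.0556
#>   TR1    1829     0.2086
#>   TR2    1207     0.1065
#>   TR3     556     0.0716
```

The detected ROI covers 9.09 mm² (planted: π·1.7² = 9.08 mm²). Exactly
90% of spots clear the 10th-percentile ratio threshold (5.51). The
fibroblast share jumps from its 5.6% background to 20.9% in TR1 — the
first 500 µm inside the border — and decays inward (10.7% in TR2, 7.2%
in TR3), recovering the planted gradient; `rank_sum_test()` on per-spot
TR1 vs NR1 fibroblast abundances puts the enrichment far beyond
conventional significance.

`run_pipeline(run_config(...))` chains the same stages and writes
TSV/MTX/GeoJSON artifacts plus a `report.json` with per-stage counts.

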