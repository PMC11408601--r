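# mimsr

Quantitative analysis of multiplexed stable-isotope imaging (MIMS /
NanoSIMS) of newly synthesized RNA and DNA within single nuclei.

NanoSIMS rasters a sample with a focused cesium beam and counts several
secondary-ion species in parallel from the same sputtered nanovolume at every
pixel. Feeding cells a stable-isotope-labeled nucleoside (¹⁵N-uridine for new
RNA; ¹³C- or ²H-thymidine or BrdU for DNA) raises the corresponding isotope
ratio above its natural background, so transcription and DNA density can be
mapped together at ~40–120 nm resolution. `mimsr` is for analysts working
with such multi-mass count images — and for anyone who wants to validate
such an analysis chain end-to-end, since it ships a synthetic scene
simulator with exact ground truth.

## The quantities it computes

For a numerator/denominator ion pair (e.g. ¹²C¹⁵N⁻/¹²C¹⁴N⁻) with natural
background ratio R₀ (0.0037 for ¹⁵N/¹⁴N):

- per-pixel ratio `R = N/D`, masked invalid where `D < min_denominator`
  (default 20 counts);
- enrichment as percent above background, `E = 100·(R/R₀ − 1)`; raw ratios
  are displayed ×10⁴ (background 0.0037 prints as 37);
- pooled ROI ratio `R = ΣN/ΣD` with Poisson counting error
  `SE = R·√(1/ΣN + 1/ΣD)` (the mean of per-pixel ratios is always reported
  alongside);
- HSI renders mapping an enrichment range onto a blue→red hue scale —
  a pure view that never alters the measurements;
- top-N hotspots: every w×w window inside a search region is scored by the
  pooled ratio of its summed counts; the top N (default 20 of 4×4 px,
  non-overlapping) are ranked, and the complementary tracer is read from the
  identical window pixels;
- laminar silencing: `area(% unlabeled) = 100·(DNA area − RNA area)/DNA area`
  from threshold-traced DNA- and RNA-guided nuclear borders;
- pixel statistics: per-cell OLS regressions of RNA on DNA density (or on
  P/S and ⁸¹Br proxies), raw MAD and COV dispersion, top-percentile DNA
  density subsets, pulse-chase and condition-contrast tables.

The simulator (`scene_spec()`, `build_scene()`, `sample_counts()`) generates
nuclei with DNA-poor RNA-bright nucleoli, an RNA-silent laminar rim of dense
DNA, chromatin-density texture, cytoplasm and Poisson shot noise at a
configurable count budget, with per-pixel expected counts and enrichments as
ground truth.

## Worked example

```r
library(mimsr)
spec  <- scene_spec()                     # default 120-min pulse conditions
truth <- build_scene(spec)
stack <- sample_counts(truth, seed = 1)

rds     <- tracer_definitions()
nucleus <- segment_nucleus(stack, "P_threshold")
p <- pooled_roi_ratio(stack, nucleus, rds[["15N_RNA"]])
cat(sprintf("nuclear 15N/14N ratio %.4f (x1e4: %.0f), enrichment %.1f%% +/- %.1f%%\n",
            p$ratio, ratio_to_scaled(p$ratio), p$enrichment, p$enrichment_se))

enr <- enrichment_image(stack, rds[["15N_RNA"]])
nl  <- nucleolus_detect(enrichment_image(stack, rds[["15N_RNA"]], smooth = 3),
                        nucleus)
f <- fold_enrichment(nl[[1]], nucleus, enr)
cat(sprintf("nucleolus 1: fold %.2f +/- %.2f over the nuclear mean\n",
            f$fold, f$se))

hs <- detect_hotspots(stack, rds[["15N_RNA"]], window = 4, top_n = 5,
                      search_mask = nucleus,
                      exclusion_mask = Reduce(`|`, lapply(nl, `[[`, "mask")))
hs <- colocalize_hotspots(hs, rds[["13C_DNA"]], stack, reference_roi = nucleus)
print(hs[, c("rank", "origin_row", "origin_col", "window_enrichment",
             "complementary_enrichment")])
dispersion(enr$values[nucleus$mask & enr$valid])
```

prints

```
nuclear 15N/14N ratio 0.0073 (x1e4: 73), enrichment 96.6% +/- 1.5%
nucleolus 1: fold 3.13 +/- 0.13 over the nuclear mean
  rank origin_row origin_col window_enrichment complementary_enrichment
1    1         90         59          186.8964                123.57400
2    2         45         60          182.0562                118.81038
3    3         64         83          179.6487                 71.93570
4    4         72         50          178.1110                 88.14781
5    5         64         77          177.3888                 96.84090
dispersion (n = 4561): median 69.27, MAD 65.72 (raw), mean 97.04, sd 122.6, COV 1.263
```

The nuclear enrichment of 96.6% recovers the simulated nucleoplasmic
multiplier of 1.0 (100% above background, averaged with the dimmer lamina
and brighter nucleoli); the nucleolar fold sits near the configured ~3×
excess; the top RNA hotspots carry their complementary ¹³C-DNA enrichment
extracted from the same pixels, against a nuclear reference mean.

The configuration-driven pipeline writes every figure-style artifact (TIFF
stacks, HSI PNGs, hotspot/regression TSVs, a JSON manifest with checksums)
in one call:

```r
run_pipeline(list(mode = "simulate+analyze", output_dir = "out", seed = 1,
                  analyses = c("dispersion", "hotspot_coloc",
                               "pixel_correlation", "laminar_area")))
```

A shell entry point with the same verbs lives in
`inst/scripts/run_pipeline.R`.

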