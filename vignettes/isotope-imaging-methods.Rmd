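---
title: "Methods: quantitative isotope-ratio imaging of nuclear RNA and DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative isotope-ratio imaging of nuclear RNA and DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimsr)
```

## The measurement model

A NanoSIMS raster delivers, for every pixel, independent ion counts for
several species sputtered from the same nanovolume. Counting is modeled as
Poisson: a pixel's count for species $s$ is $N_s \sim \mathrm{Pois}(\mu_s)$.
Incorporation of a stable-isotope tracer multiplies the rare-to-common
ratio of the relevant pair above its natural background $R_0$, so the
quantity of interest at a pixel or region is the enrichment

$$E = 100\left(\frac{R}{R_0} - 1\right), \qquad R = \frac{N}{D},$$

in percent above natural background: $E = 0$ means no tracer, $E = 100$
means twice the background ratio. Raw ratios are conventionally displayed
$\times 10^4$ (the ¹⁵N/¹⁴N background of 0.0037 prints as 37). For a region
of interest the primary statistic is the ratio of summed counts,
$R = \Sigma N / \Sigma D$, whose Poisson standard error is

$$\mathrm{SE}(R) = R\sqrt{\tfrac{1}{\Sigma N} + \tfrac{1}{\Sigma D}}.$$

The ratio of sums is robust at low per-pixel counts; because per-pixel dot
plots presuppose pixel-level ratios, the mean of per-pixel ratios is always
reported alongside, and downstream reports must state which variant they
use — at uniform denominators the two coincide.

Assumptions worth keeping in view: counts are independent across pixels and
species (no detector dead-time or quasi-simultaneous-arrival correction —
out of scope here), the background $R_0$ is spatially constant, and pixels
are treated as independent observations in population statistics (see
Limitations).

## Tracers and backgrounds

`tracer_definitions()` covers the standard multiplexed set:

| tracer | ratio | default $R_0$ | note |
|---|---|---|---|
| ¹⁵N-uridine (new RNA) | ¹²C¹⁵N⁻/¹²C¹⁴N⁻ | 0.0037 | the canonical value |
| ¹³C-thymidine (DNA) | ¹³C¹²C⁻/¹²C₂⁻ | 0.0224 | ≈ 2 × 0.0112 from dimer combinatorics; configurable |
| ²H-thymidine (DNA) | ¹²C₂²H⁻/¹²C₂¹H⁻ | 1.56e−4 | natural D/H; configurable |
| BrdU (DNA) | ⁸¹Br⁻ direct counts | — | no background subtraction; raw counts are the density proxy |

The dimer backgrounds are not settled constants of the instrument
literature; they are exposed as arguments, and every analysis in the
package works in percent above background, where the choice cancels for
within-study comparisons. The ³¹P⁻/³²S⁻ ratio is a label-free ordinal DNA
density proxy (chromatin is phosphorus-rich, sulfur-poor); since no natural
background exists for it, `ps_proxy()` expresses it relative to a
within-image reference — the cytoplasmic median — so it is meaningful only
ordinally and within an image.

## Parameters that matter

* `min_denominator` (default 20 counts): pixels with fewer denominator
  counts are masked invalid before any per-pixel ratio is formed. At 20
  counts the single-pixel ratio's relative SE is already ≈ 22%; below that
  the ratio distribution develops heavy tails and divide-by-zero blow-ups.
  Masked pixels never enter any downstream statistic.
* Hotspot `window` (4 px) and `top_n` (20): square windows scored by the
  pooled ratio of their summed counts, which matches ranking by ion counts
  within the window boundary; the mean of pixel ratios would differ at
  non-uniform denominators. Whether the classical top-N windows may overlap
  is not documented anywhere we know of; the default here is **disjoint**
  (greedy selection skipping overlaps), because overlapping windows return
  N near-copies of a single maximum. `overlap_policy = "free"` restores
  overlapping behavior for fidelity experiments. Ties are broken toward the
  window with more denominator counts (better measured), then row-major
  origin order, making results fully deterministic.
* Nucleolus detection (`fold_threshold` 2× the nuclear mean, equivalent
  diameter 1–3 µm): nucleoli are DNA-poor bodies of intense new-RNA signal
  of about that size; the diameter gate removes bright shot-noise specks.
* Laminar tracing (`threshold` 30% enrichment, 3×3 count pooling): the
  unlabeled-margin metric $100(\mathrm{A_{DNA}} -
  \mathrm{A_{RNA}})/\mathrm{A_{DNA}}$ was originally computed from manually
  traced borders. Manual tracing is not reproducible in software, so both
  borders are traced by thresholding the respective enrichment image at a
  fixed level after pooling counts over a 3×3 box (emulating the regional
  pooling a human eye applies to a noisy image), followed by a 3×3
  morphological opening that removes isolated shot-noise speckles, hole
  filling, and largest-component selection. This is a declared stand-in,
  not a reproduction of manual tracing; the threshold is exposed. Negative
  fractions (RNA border outside the DNA border) are reported with a
  warning, never clamped.
* Dispersion: MAD is the **raw** median absolute deviation without the
  1.4826 normal-consistency constant — it is used comparatively between
  pixel distributions, where the constant cancels; the choice is recorded in
  the result object. COV uses the sample ($n-1$) standard deviation and is
  defined only for positive means.
* Top-percentile subsets use the nearest-rank cutoff with ties included, so
  a top-5% subset holds at least ⌈0.05 n⌉ pixels and more only under ties.

## What the simulator emulates

`scene_spec()` describes one cell: an elliptical nucleus with a laminar rim
(annulus of configurable width inside the boundary), DNA-poor nucleoli
(discs, validated to lie wholly inside the nucleus), dense chromatin foci,
cytoplasm out to a scaled cell boundary, and background. Compartments
partition every pixel exactly once with priority nucleolus > lamina >
chromatin focus > nucleoplasm > cytoplasm > background. Chromatin density
is a smooth seeded correlated field (white noise blurred at the correlation
length) plus hard discs for condensates, clipped positive and normalized to
mean 1 over the nucleus; it multiplies the DNA-tracer enrichment and the
³¹P level and divides ³²S, producing the P-rich/S-poor chromatin signature
and a positive P/S-vs-DNA-label pixel correlation. Each tracer is simulated
directly as its numerator/denominator pair: the expected ratio in
compartment $c$ with multiplier $m$ is exactly $R_0(1+m)$, which makes the
simulator/analyzer closure testable to floating-point tolerance — running
the ratio engine on the expected counts reproduces the configured
enrichment field identically. Dimer chemistry is not modeled
mechanistically, and neither are sputtering depth profiles, dead time, or
3D stacks.

Default study conditions: a 128×128 px field at 100 nm/px (a 12.8 µm
field), nucleus semi-axes 4.2×3.4 µm, two nucleoli of 1.2–1.4 µm diameter
at multiplier 3.0 (300% above background) versus nucleoplasm 1.0, an
RNA-poor lamina (0.1) with doubled DNA label, and a denominator budget of
500 counts/px. Absolute count rates are free parameters of any real
acquisition; 500 was chosen so the nuclear-ROI relative SE of enrichment
stays below 2%, i.e. region-level estimates are measurement-limited by
biology, not shot noise, while per-pixel ¹⁵N numerators remain realistically
sparse (a few counts). Pulse-chase series are modeled as families of scenes
with per-timepoint multipliers, not as kinetic ODEs — only per-timepoint
means are ever compared.

What passing tests on these scenes do **not** show: real nuclei have
irregular (non-elliptical) borders, touching cells, spatially varying
backgrounds and topography artifacts; segmentation and tracing performance
on synthetic ellipses is an upper bound, not an expectation for tissue.

## Recovery experiments and their design

The test suite measures, on seeded scenes:

* hotspot selection against an independent brute-force enumeration of all
  candidate windows (100 random 32×32 instances; equivalence is exact
  because the greedy-disjoint rule *is* the specification);
* Poisson SE calibration: the pooled nuclear ratio ±1.96 SE covers the true
  ratio in 93–97% of 500 draws from a 24×24 scene at 100 counts/px;
* nucleolar fold recovery within 3 SE at 200 counts/px (10 seeds, 128×128);
* slope recovery: scenes built by `regression_scene()` prescribe an exact
  pixel-wise linear relation between the DNA enrichment field (a smooth
  texture spanning 50–150% above background, the intranuclear spread seen
  in practice) and RNA enrichment, with slopes β ∈ {−0.9, 0, 0.15}; the
  fitted 95% CI covers β in ≥ 90% of 50 runs per slope (48×48 px, 2000
  counts/px).

One design choice deserves emphasis: in the slope-recovery experiment the
regressor is the **ground-truth** DNA enrichment field, with Poisson noise
only in the RNA channel. Regressing one noisy channel on another noisy
channel attenuates OLS slopes toward zero (errors-in-variables), by a
factor of roughly $\mathrm{var}(x_{true})/(\mathrm{var}(x_{true}) +
\mathrm{var}(\epsilon_x))$; no OLS implementation can cover the true β
there, so a CI-coverage check would test the scene's noise level, not the
code. Conventional pixel regressions in this field are OLS on two measured
channels and inherit exactly this attenuation — worth remembering when
interpreting shallow empirical slopes. The RNA intercepts (250, 100, 30 for
the three slopes) keep the Poisson noise approximately homoskedastic across
the fitted range so the nominal OLS intervals are valid.

## Numerical and degenerate-input choices

* Invalid pixels carry `NA` behind a logical mask; no NaN/Inf ever escapes
  a ratio computation.
* A constant regressor raises a degenerate-design error rather than
  returning a silent zero slope; a constant response returns slope 0,
  $R^2 = 0$, $p = 1$ exactly (avoiding the numerically meaningless
  $R^2$ of an all-zero residual fit).
* `fold_enrichment()` refuses a non-positive reference mean; its SE is a
  delta-method propagation of the two pixel-level mean SEs, which includes
  compartment heterogeneity and is therefore conservative.
* Coordinates are row-major, 1-based inside R, exported 0-based in tables;
  areas convert to µm² via the pixel size carried on the stack.
* Counts are stored as 16-bit integer TIFF pages (exact for counts ≤ 65535,
  enforced at save time) with a JSON sidecar; loading validates page/species
  agreement and integrality, so a float-valued page is a named format error.
* Segmentation thresholds are data-relative (Otsu on the normalized
  channel), making segmentation invariant to positive rescaling of a
  channel.

## Limitations

* Pixels are treated as independent in regressions, dot plots and SEs of
  pixel means; spatial autocorrelation (from the beam point-spread and from
  biology) makes nominal p-values anti-conservative. This mirrors standard
  practice; a spatially corrected regression is out of scope.
* The laminar-area and nucleolus procedures emulate, not reproduce, manual
  tracing; their thresholds are honest free parameters.
* Inferential machinery (ANOVA, multiple-comparison adjustments, nested t
  tests) is deliberately not re-implemented: the package exports per-ROI
  and per-cell tables from which standard routines compute those.
* The P/S proxy is ordinal and image-relative; slopes against it are per
  proxy unit and not comparable across images with different references.
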