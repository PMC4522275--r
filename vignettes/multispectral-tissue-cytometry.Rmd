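---
title: "Multispectral tissue cytometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral tissue cytometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectracyte)
```

`spectracyte` quantifies per-cell marker expression from multispectral
images of chromogen-stained tissue and aggregates it per tissue region.
This vignette explains the models behind each stage, the parameters that
matter and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical conventions the package commits to.

## The optical model

Brightfield chromogens absorb light. For incident (blank-field) intensity
$I_0$ and per-pixel chromogen amounts $a_k \ge 0$ with absorbance spectra
$s_k(\lambda)$ (peak-normalized to 1), the Beer–Lambert model gives

$$ I(x,\lambda) \;=\; I_0 \, 10^{-\sum_k a_k(x)\, s_k(\lambda)} . $$

Optical density, $\mathrm{OD}(x,\lambda) = -\log_{10} (I/I_0)$, is
therefore *linear* in the chromogen amounts, which is what makes
per-pixel unmixing a linear least-squares problem. `to_optical_density()`
clamps OD to $[0, \mathrm{od\_max}]$ with `od_max = 3` (transmittance
1/1000): deeper absorbance is below the sensor's dynamic range, and the
clamp maps zero-intensity pixels to a finite ceiling rather than
infinity. Fluorescence panels are additive instead — emission plus a
tissue autofluorescence term — so they are unmixed on (AF-corrected) raw
intensities, not OD.

## Spectral libraries and conditioning

Endmember spectra come from single-stain images: foreground pixels are
those whose total signal exceeds the image's 0.90 quantile, and the
endmember is the mean foreground spectrum, peak-normalized
(`build_library()`). Both the quantile and the mean (versus median) are
conventions; they are configurable, and the recovery test (cosine
similarity above 0.9999 on rendered single stains) shows they are not
delicate. Peak normalization fixes the unmixing units: a brightfield
coefficient *is* the chromogen's OD at its peak band, the single number
per marker per cell used everywhere downstream.

Panels with two red chromogens are nearly collinear in spectrum space.
`library_condition_report()` quantifies this with pairwise spectral
angles and the condition number of the endmember matrix, flagging pairs
below 3 degrees; `unmix_cube()` repeats that warning. The default
simulated panel places the two red endmembers at 8 degrees — separable,
but close enough to exercise the noise amplification the report is for.

## Non-negative least squares unmixing

Each pixel solves $\min_{a \ge 0} \lVert S^{\mathsf T} a - x \rVert_2$.
The package implements the Lawson–Hanson active-set algorithm
(`nnls_solve()`), with ties on the entering variable broken by the lowest
endmember index so results are deterministic. `unmix_cube()` first solves
the unconstrained normal equations for all pixels at once; pixels whose
solution is already non-negative are done (the constraint is inactive),
and the rest are solved exactly by enumerating support subsets, which is
equivalent to the active-set optimum because the NNLS minimizer solves
unconstrained least squares on its own support. Tests check both routes
against a brute-force grid oracle and an independent active-set
implementation.

## The synthetic scene generator

`generate_scene()` is the package's source of ground truth. It emulates a
section of secondary lymphoid tissue:

* **Regions.** Disk-shaped B-cell follicles, each with an adjacent
  T-zone disk (the white-pulp arrangement of T-cell zones flanking
  follicles), a left-edge strip of non-immune "other" tissue that serves
  as the negative-control compartment, and stroma (red pulp / lamina
  propria) elsewhere. Thin annular T zones were considered and rejected:
  a region narrower than the classifier's feature window cannot be
  recovered at the required pixel accuracy by any tile-based method, and
  compact adjacent zones are the more common histology.
* **Cells.** Disk nuclei with log-normal radii (median 4 px, sdlog 0.12)
  placed by rejection sampling at per-region densities (follicle 8,
  T zone 7, stroma 5, other 4 cells per 1000 px²; about 1450 cells in the
  default 512×512 scene), with centre distance at least
  $(1-f)(r_1+r_2)$, $f = 0.1$, so nuclei may touch and slightly overlap —
  enough to exercise watershed splitting without making recovery
  ill-posed.
* **Classes and ODs.** Each cell is lineage-positive with its region's
  probability (0.85 / 0.80 / 0.35 / 0) and tetraspanin-bright with its
  region's probability (0.90 / 0.35 / 0.45 / 0); the follicle-versus-
  stroma contrast echoes the roughly two-to-one bright-fraction contrast
  such stains show between follicles and red pulp. Per-cell OD levels
  are log-normal: dim tetraspanin median 0.035 (sdlog 0.18), bright 0.35
  (0.25), lineage-positive 0.45 (0.25), lineage-negative background 0.02
  (0.30), nuclear 0.50 (0.20). Non-immune control cells draw tetraspanin
  from their own background distribution, median 0.04 with sdlog 0.30 —
  a mixed stromal population (fibroblasts, endothelium) is genuinely
  more heterogeneous than a homogeneous dim lymphocyte mode, and that
  extra spread is what puts the 95th-percentile control threshold above
  the dim mode's tail.
* **Geometry of deposition.** The nuclear chromogen fills the nucleus
  disk; lineage and tetraspanin chromogens deposit on a 2 px membrane
  annulus around it, and co-deposits from different cells *add* — the
  linearity that makes crowded tissue hard, reproduced on purpose.
* **Rendering.** Beer–Lambert as above at $I_0 = 255$ over 16 bands
  spanning 420–720 nm, plus Gaussian intensity noise with sd
  $0.01\,I_0$ (about 46 dB SNR at the white level; Poisson resampling is
  available but off by default). Band count and range are declared
  defaults — typical for liquid-crystal multispectral microscopes — not
  values taken from any particular instrument.

Everything is a pure function of `(config, seed)`; the same seed gives
bit-identical scenes. What the generator does **not** emulate: optical
blur (no PSF), chromatic aberration, section thickness variation,
stain gradients across the slide, segmentation-relevant nuclear texture,
or 3D overlap of cells at different depths. Passing recovery tests on
these scenes therefore demonstrates the *algorithmic* correctness of the
chain under realistic density, spectral collinearity and noise — not
robustness to every artefact of real slides.

## Segmentation choices

Nuclei: Gaussian smoothing (sigma 0.8 px), Otsu threshold, Euclidean
distance transform, watershed (`EBImage`), area filter 12–400 px².
The watershed tolerance (0.1) and neighbourhood (1 px) were set by the
recovery requirement on the default scene — count error within 5 % and
95 % of centroids within 3 px — and land at 0.1 % and 98 %; they are the
splitting-sensitivity knobs to revisit first on data with different
nucleus sizes.

Tissue classification is tile-based: 8 px tiles with features
box-averaged over a 7×7-tile window. A tile alone holds about one cell,
far too little to estimate region composition, while the window provides
roughly 50 cells; keeping the *tile* small preserves boundary
resolution, so the two scales are deliberately decoupled. Features per
tile: mean abundance per endmember, nucleus density, mean nucleus area,
tissue fraction, marker-to-nuclear abundance ratios, and two composition
features — the fraction of cells in the window whose membrane-ring OD
clears a global two-class Otsu cut, per marker. The classifier is
Gaussian class-conditional with a pooled, ridge-regularized covariance
(linear discriminant analysis; a per-feature-variance naive Bayes
variant is available), priors from tile frequencies, ties broken by the
fixed priority follicle > T zone > stroma > other, tiles below 5 %
tissue fraction labelled background, and a radius-2 majority smoothing
of the tile labels. Trained on 10 default scenes and tested on 10
held-out scenes this reaches 92 % mean pixel accuracy; most residual
error is the irreducible rasterization band at region boundaries.

## Per-cell quantification and thresholds

Membrane markers live on an annulus *outside* the nucleus label, so each
label is expanded by 2 px with a Voronoi propagation (nearest nucleus
wins contested pixels) and membrane ODs are measured on the ring
(expansion minus nucleus); the nuclear OD on the nucleus itself. The
per-cell statistic is a **0.4 quantile** of the compartment's pixels
rather than the mean: co-deposition is additive, so in dense tissue a
neighbour's membrane inflates part of a cell's ring, and a sub-median
quantile ignores contamination of up to 60 % of the pixels. The small
downward bias this causes is shared by the control cells from which the
thresholds are derived, so class assignment is unaffected; with plain
means, the densest simulated region mis-scores its bright fraction by
nearly 30 percentage points, with the 0.4 ring quantile by under 2.

Thresholds are nearest-rank percentiles of the negative-control cells
(non-immune cells of the "other" region): the 95th percentile of their
tetraspanin OD separates dim from bright, the 99th percentile of their
lineage OD defines positivity; both percentiles and the minimum control
count (50) are configurable, and boundary equality counts as
positive/bright. This is a reproducible surrogate for setting thresholds
by eye from non-immune cells in marker-negative regions. Images whose
tissue fraction (pixels with summed abundance above 0.05 OD) is strictly
below 10 % are discarded before any scoring.

## Region statistics

The statistical unit is one image: summaries (`od_mean`, percent bright,
percent bright within lineage-positive cells) are computed per image ×
region, and planned comparisons collect those per-image values.
`compare_groups()` gates on Shapiro–Wilk normality at 0.05 per group
(groups with fewer than 3 values or constant values count as
non-Gaussian): both Gaussian gives the classic equal-variance unpaired
Student's t (Welch by flag), otherwise a two-sided Mann–Whitney — exact
when the combined sample is at most 20 without ties, else the normal
approximation with tie and continuity corrections. Significance is
$p \le 0.05$. The gated procedure's type-I error under a Gaussian null
at $n = 10$ per group is measured at about 0.05 by simulation in the
test suite. OD histograms use left-closed, right-open bins of width
0.05 OD with heights normalized so the modal bin reads 100 ("% of max");
a value exactly on an edge belongs to the bin to its right. Strata with
fewer than 20 cells are reported but flagged with a low-n warning rather
than suppressed. No multiple-testing correction is applied — each
planned comparison is reported on its own.

## Numerical and I/O conventions

* Coordinates are R-native: 1-based, row = y, column = x; cell centroids
  may be fractional. All masks, label maps and cubes share this frame.
* Cubes and abundance maps are stored as multi-page 32-bit TIFF with a
  JSON sidecar (wavelengths, mode, $I_0$, storage scale). The available
  TIFF writer stores 32-bit *integer* samples of values in $[0,1]$, so
  data are scaled by a recorded power of two and pre-quantized to the
  writer's own grid: precision is $2^{-32}$ of the scale (finer than
  single precision over most of the range) and anything read back
  round-trips bit-identically. Label masks are 16-bit integer TIFF.
* All tabular outputs are UTF-8 CSV with headers and '.' decimals; the
  pipeline manifest records the configuration hash and seed, and rerunning
  with identical inputs reproduces cells.csv and stats.csv byte for byte.
* The only stochastic pipeline step, scatter subsampling (at most 2000
  cells per image × region, without replacement), takes its seed from the
  configuration; no stage consumes ambient randomness.

## Problem sizes used in validation

The packaged tests validate on: 256×256×16 cubes for exact unmixing;
the default 512×512 scene (~1450 nuclei) for segmentation recovery;
10 + 10 default scenes for tissue classification; a ~1950-cell scene for
phenotype recovery; 2000 simulations for the type-I error; and 192×192
four-image batches for end-to-end determinism. These sizes give the
recovery statistics comfortable margins while keeping a full run of the
suite and the acceptance script inexpensive to repeat.

## Known limitations

* Tile-based tissue classification cannot resolve regions thinner than
  its feature window, and its boundary placement is accurate only to
  about a tile.
* The contamination-robust quantile breaks down when more than ~60 % of
  a cell's ring is overlaid by neighbours; beyond the simulated
  densities, compartment-aware unmixing or cell-by-cell deconvolution
  would be needed.
* Thresholds are global per batch (one pair per staining panel), matching
  single-threshold practice; slides with strong staining gradients would
  need per-image or spatially adaptive thresholds, deliberately not
  implemented.
* Fluorescence support covers additive rendering, AF estimation or
  subtraction and intensity-space unmixing, but the synthetic defaults
  and all recovery tests are brightfield.
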