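# spectracyte

Multispectral tissue cytometry in R: quantify how strongly each cell in a
stained tissue section expresses a marker, and how that expression differs
between tissue regions.

Brightfield multiplex immunohistochemistry stains a section with several
enzyme-deposited chromogens — here a lineage marker (e.g. CD3 or CD20 on
Warp Red), a tetraspanin (e.g. CD37 or CD53 on True Blue) and a nuclear
counterstain (Nuclear Red) — and acquires a multispectral cube: one
intensity plane per spectral band at every pixel. Because two of the
chromogens are both red and spectrally near-collinear, per-channel
intensities cannot be read off directly; the cube must be spectrally
unmixed against a library of pure chromogen spectra. `spectracyte`
implements the full analysis chain:

1. **Spectral library** (`build_library`): endmember spectra from
   single-stain images (mean foreground spectrum, peak-normalized), with
   autofluorescence estimation and subtraction for fluorescence panels and
   a conditioning report for near-collinear pairs.
2. **Optical density** (`to_optical_density`): Beer–Lambert conversion
   `OD = -log10(I / I0)`, clamped to `[0, od_max]`, making absorbance
   linear in chromogen amount.
3. **Unmixing** (`unmix_cube`): per-pixel non-negative least squares
   `argmin_{a >= 0} ||S'a - x||_2` against the library; because endmembers
   are peak-normalized, each coefficient is that chromogen's OD at its
   peak band — the per-marker OD used everywhere downstream.
4. **Segmentation** (`segment_nuclei`, `classify_tissue`): watershed
   nucleus segmentation from the counterstain channel, and tile-based
   Gaussian (LDA) classification of tissue into B-cell follicle, T-cell
   zone, stroma (red pulp / lamina propria), other and background.
5. **Phenotyping** (`quantify_cells`, `derive_thresholds`, `score_cells`):
   per-cell marker ODs measured on the membrane ring around each nucleus;
   positivity and dim/bright thresholds derived as nearest-rank
   percentiles of negative-control (non-immune) cells; every cell scored
   `lin-/dim`, `lin+/dim`, `lin+/bright` or `lin-/bright`. Images with
   less than 10 % tissue are discarded (`qc_filter_images`).
6. **Region statistics** (`summarize_regions`, `compare_groups`): per
   image x region OD means and percent-bright (overall and within the
   lineage-positive subset), OD histograms binned per 0.05 OD and
   normalized to % of max, and normality-gated two-group tests (Student's
   t when both groups pass Shapiro–Wilk, exact Mann–Whitney otherwise),
   with one x20 image as the statistical unit.

A synthetic lymphoid-tissue generator (`generate_scene`) renders scenes
with full ground truth — region layout, every cell's position, class and
true ODs, and the multispectral cube via the Beer–Lambert forward model —
so the whole chain is validated end to end against known truth.

## Worked example

```r
library(spectracyte)

em <- default_endmembers()          # Warp Red / True Blue / Nuclear Red panel
em$pairwise_angles_deg["warp_red", "nuclear_red"]
#> [1] 8

sc <- generate_scene(scene_config(seed = 42), em)
nrow(sc$truth$cells)
#> [1] 1446

od  <- to_optical_density(sc$cube)          # Beer-Lambert, I0 = 255
ab  <- unmix_cube(od, em)                   # per-pixel NNLS
seg <- segment_nuclei(ab$coefficients[, , "nuclear_red"])
nrow(seg$cells)
#> [1] 1442

rec <- quantify_cells(seg, ab, sc$truth$region_mask)
thr <- derive_thresholds(rec)               # from non-immune control cells
thr
#> Scoring thresholds (from 131 control cells in other):
#>   lineage positivity OD >= 0.0303 (p99)
#>   tetraspanin bright  OD >= 0.0630 (p95)

rec <- score_cells(rec, thr)
summ <- summarize_regions(rec)
summ[summ$region %in% c("follicle", "stroma"),
     c("region", "n_cells", "od_mean", "pct_bright")]
#>     region n_cells   od_mean pct_bright
#> 1 follicle     266 0.3432809   93.60902
#> 3   stroma     813 0.1883042   47.23247
```

The follicle's cells are mostly tetraspanin-bright (93.6 % scored here
against a 92.6 % ground truth) with a higher mean OD than the stroma,
whose scored bright fraction (47.2 %) matches its 47.0 % ground truth —
the per-region contrast the pipeline is built to quantify. `run_pipeline()` chains all of the above over a
batch of images and writes cells.csv, summaries.csv, stats.csv, qc.csv
and a manifest.

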