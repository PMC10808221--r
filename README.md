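# stedclust

Quantitative cluster analysis for two-channel STED micrographs of membrane
sheets, with a ground-truth synthetic image generator.

Nanoscale membrane proteins such as the tetraspanins CD9, CD81 and CD151
appear in super-resolution micrographs as diffraction-limited spots at a
few clusters per square micrometer. `stedclust` implements the full
measurement chain used to ask whether two immunostained proteins
co-assemble and whether their assemblies agglomerate into larger
"arranged crowds":

* **Detection** — Gaussian noise reduction (σ = 0.5 px), optional spectral
  crosstalk subtraction, and prominence-based local-maxima detection
  (noise tolerance 4 for CD9/CD81/CD151-type stainings), implemented in
  C++ with a pure-R brute-force flood-fill reference implementation used
  as its oracle.
* **Quantification** — per maximum: background-corrected mean intensity in
  a 100 nm (13-pixel) circular ROI in both channels, subpixel fluorescence
  mass center, and horizontal/vertical 31 × 3 px linescan Gaussian fits
  `b + A·exp(−(x−μ)²/2σ²)`. Maxima with best-fit R² > 0.8 and a centered
  peak (|μ − 15| ≤ 5 px) are rated **clusters**; the fit's
  FWHM = 2√(2 ln 2)·σ defines the spot size.
* **Spatial statistics** — directional nearest-neighbor distances between
  cluster mass centers with object-based overlap at ≤ 60 nm;
  neighbored-maxima counts in a 900 nm circle (self excluded); cluster
  densities per µm² over a sheet mask.
* **Statistics** — percentage histograms; one-/two-Gaussian least-squares
  decomposition of the crowding histogram with area fractions A·σ and an
  F-test model preference; through-origin intensity regression
  (slope = Σxy/Σx², about-mean R², 2 a.u. noise gate); replicate
  aggregation with a two-sided unpaired Student's t-test
  (\* p<0.05, \*\* p<0.01, \*\*\* p<0.001).
* **Simulation** — a generative model of membrane sheets: CSR plus
  Thomas-process crowding, i.i.d. channel composition (A / B / both),
  log-normal spot brightness, Gaussian PSF (FWHM 65–100 nm), Poisson +
  read noise, per-channel detection dropout — with a complete ground-truth
  table keyed to the rendered 16-bit TIFFs.

## Worked example

```r
library(stedclust)

cfg <- sim_config(seed = 11)   # 512x512 px, 4 assemblies/um^2, 40% dual-labeled
ds  <- simulate(cfg)           # truth table + rendered channels A and B
res <- analyze_sheet(ds$images$A, ds$images$B)
res
#> <sheet_analysis> A vs B, 104.86 um^2 analyzed
#>   A: 345 maxima, 245 clusters (2.34 clusters/um^2)
#>   B: 329 maxima, 234 clusters (2.23 clusters/um^2)
#>   overlap A->B: 53.9% (threshold 60 nm)
#>   overlap B->A: 54.7% (threshold 60 nm)
summary(res)
#>  channel n_maxima n_clusters density_per_um2 median_fwhm_nm mean_neighbors
#>        A      345        245           2.337          101.5          1.867
#>        B      329        234           2.232          101.1          1.745
#>   slope       r2 pct_both
#>  0.4237 -0.02608    47.35
#>  0.4704  0.01443    48.31
```

Reading the numbers: with 40% of assemblies carrying both labels and 30%
each single-labeled, the expected overlap of A clusters with B clusters is
0.4/0.7 ≈ 57% plus a small chance term; the measured 53.9% sits a few
points below because a co-assembled partner occasionally fails cluster
classification. The median cluster FWHM (~101 nm) reproduces the 100 nm
rendering PSF — sizes are resolution-limited upper bounds. The noise-gated
fraction of A maxima with above-noise B intensity (47%) independently
agrees with the distance-based overlap, and the through-origin regression
R² near zero shows the two channel brightnesses are uncorrelated, as
simulated.

`write_results(res, "out/")` writes `maxima.csv`, `distances.csv`,
`neighbors.csv`, `summary.csv`, `correlation.csv` and a checksummed
`manifest.json`; `fit_crowding_mixture()` decomposes crowding histograms;
`aggregate_replicates()` compares conditions across biological replicates.
A thin CLI (`inst/cli/stedclust`) exposes `simulate`, `analyze`,
`decompose` and `report` subcommands.

## The methods vignette

`vignettes/cluster-analysis-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, the numerical conventions
(plateau tie-breaks, fit bounds, sentinels, degenerate inputs), and known
limitations.
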