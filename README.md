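# vesdist

Spherical modelling of intracellular vesicle distributions in single-cell 3D
fluorescence z-stacks.

## The problem

Early endosomes — the vesicles that route cargo taken up by clathrin-mediated
endocytosis — normally disperse homogeneously through the cytoplasm. In
disease models such as iPSC-derived cardiomyocytes carrying dilated
cardiomyopathy mutations, endosomes instead arrest near the plasma membrane,
producing a spatially *bimodal* vesicle population (a perinuclear pool plus a
membrane-adjacent pool). `vesdist` quantifies this phenotype from one-channel
confocal or STED z-stacks (e.g. an EEA1 immunostain), one stack per cell,
without any segmentation beyond a global intensity threshold.

## The model

For a stack with pixel intensities `y_i` at pixel centers `x_i`:

1. **Background.** The camera background is a Gaussian peak in the pooled
   intensity histogram; true signal lives in the far right tail. The center
   `mu` is the histogram mode and `sigma^2` is the mean squared deviation of
   intensities *below* `mu` (which signal cannot contaminate). The
   binarization threshold is `theta = mu + n_sigma * sigma`, with the
   conservative default `n_sigma = 10`; for STED data a global
   `mean + n_sigma * sd` threshold with `n_sigma = 1` is provided instead.
2. **Geometry.** Suprathreshold pixels get weights
   `w_i ∝ [y_i > theta] (y_i − theta)` (Iverson bracket: sub-threshold pixels
   weigh zero). The cell center is the weighted center of mass
   `c = Σ w_i x_i / Σ w_i`, and cell size is the radius of gyration
   `R_g = sqrt( Σ w_i ‖x_i − c‖² / Σ w_i )`.
3. **Distributions.** Each cell yields a weighted histogram of scaled
   distances `‖x_i − c‖ / R_g` on a fixed grid (100 bins on [0, 2.5]), making
   differently sized cells directly comparable. A homogeneous cell gives a
   unimodal curve; membrane arrest adds a second peak beyond `s ≈ 1`.
4. **Population.** Per-group mean curves, PCA of the binned densities
   (deterministic SVD sign convention), a per-cell membrane fraction
   (integrated mass at `s >` cutoff, default 1), and descriptive group
   comparisons — no hypothesis tests.

A deterministic synthetic-stack generator (`generate_cell()`,
`generate_population()`) emulates homogeneous, membrane-arrested and rescued
phenotypes with known ground truth, plus analytic ball/shell phantoms
(`phantom_stack()`) whose closed-form moments anchor the test suite.

## Worked example

```r
library(vesdist)

cell <- generate_cell(
  synthetic_cell_spec(spatial_model = "bimodal", membrane_weight = 0.5,
                      seed = 42),
  cell_id = "demo", group = "MUT")

bg <- background_model(cell$stack, n_sigma = 10)
bg
#> BackgroundModel: mu = 1867.72, sigma = 149.43, theta = mu + 10 sigma = 3361.98
#>   background fraction (y <= theta): 96.6%

geom <- cell_geometry(cell$stack, bg$theta)
geom
#> CellGeometry demo [MUT]: 36164 suprathreshold pixels (theta = 3361.98)
#>   center (z,y,x) = (88.62, 120.94, 122.81), Rg = 59.736

dist <- distance_distribution(geom)   # scaled, 100 bins on [0, 2.5]
membrane_fraction(dist)
#> [1] 0.4822689

find_peaks(dist$density, dist$bin_edges, min_prominence = 0.1)
#>   bin location   height prominence
#> 1  24   0.5875 0.950124  0.5078968
#> 2  52   1.2875 1.606393  1.6063927
```

The fitted background (mu ≈ 1868, sigma ≈ 149) recovers the generator's
camera model; ~97% of pixels fall below the 10-sigma threshold. The scaled
distance distribution of this membrane-arrested cell is bimodal: a
perinuclear peak at `s ≈ 0.59` and a membrane-adjacent peak at `s ≈ 1.29`,
with 48% of the vesicle mass beyond the radius of gyration. A homogeneous
(`spatial_model = "uniform_ball"`) cell shows a single peak and a lower
membrane fraction.

### Command line

```sh
Rscript inst/cli/vesdist.R simulate   --out demo --seed 5
Rscript inst/cli/vesdist.R analyze    --manifest demo/manifest.csv --out demo/analysis
Rscript inst/cli/vesdist.R population --in demo/analysis --out demo/analysis
```

`analyze` writes per-cell background JSON, geometry and histogram CSVs, a
z-projection QC TIFF, and an exclusions file listing any cell that failed QC
with the reason; `population` writes per-cell membrane fractions with PCA
scores (`population.csv`), per-group mean curves and a JSON report. Exit
codes: 0 success, 2 partial (some cells excluded), 1 fatal.

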