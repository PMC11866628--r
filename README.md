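# eegraph

Global network topology of multichannel EEG, from raw time series to
intervention statistics.

Resting-state EEG studies of neuromodulation interventions (here:
transcranial photobiomodulation, tPBM, delivered to the left or right
forehead in an active/sham crossover) often ask a network-level question: did
the stimulation change how the brain's electrical activity is organized as a
graph, and in which frequency band? `eegraph` implements that analysis
end to end for 19-channel 10–20 recordings:

1. **Cleaning** — zero-phase Butterworth bandpass (1–55 Hz), spike/flat-run
   repair, bad-channel interpolation from montage neighbors, common-average
   re-referencing, ICA-based artifact removal.
2. **Connectivity** — 10-s epochs, multitaper (Slepian) cross-spectral
   densities, and the **imaginary part of coherency**

   $$\mathrm{ICoh}_{xy}(\omega) \;=\; \left|\,\mathrm{Im}\,
   \frac{S_{xy}(\omega)}{\sqrt{S_{xx}(\omega)\,S_{yy}(\omega)}}\right|,$$

   which is insensitive to instantaneous volume conduction (a real, zero-lag
   mixing of sources cannot produce an imaginary cross-spectrum). Band
   averages give five 19×19 adjacency matrices (delta, theta, alpha, beta,
   gamma), each with 171 unique connections.
3. **Graph topology** — each weighted matrix is thresholded over a sparsity
   grid (5%–95%, step 5%), and on each binary graph the global metrics are
   computed: clustering coefficient Cp, characteristic path length Lp, global
   and local efficiency Eg/Eloc, and the small-world indices
   γ = Cp/Cp_rand, λ = Lp/Lp_rand, σ = γ/λ against degree-preserving rewired
   null networks.
4. **Statistics** — per-subject normalized change
   M_nor = (M_post − M_pre)/M_pre in each arm, then paired two-sided t-tests
   of active vs sham per (metric, band, sparsity) cell at p < 0.05
   (uncorrected, with raw p-values reported so corrections can be applied
   downstream).

Because the emulated protocol's human recordings are not publicly deposited,
the package ships a first-class **synthetic-data module**: phase-lagged
narrowband coupled oscillators over the 10–20 montage, 1/f background noise,
optional volume-conduction mixing, and full pre/post × active/sham study
generation with a configurable band-specific coupling effect — so the whole
pipeline can be exercised against known ground truth.

Everything downstream of the signal stage is tidyverse-native: metric curves
and significance maps are tibbles, fitted comparisons support `tidy()` /
`glance()`, and `autoplot()` / `plot_*()` produce the standard figures.

## Worked example

Simulate a 26-subject left-side active/sham study whose post-stimulation
active recordings carry an alpha-band coupling increase, then run the whole
pipeline (shortened recordings and a reduced sparsity grid keep this quick):

```r
library(eegraph)
library(dplyr)

design <- study_design(
  n_subjects = 26,
  conditions = c("active-left", "sham-left"),
  effect     = list(band = "alpha", increment = 0.5, side = "both"),
  fs = 160, duration = 50, seed = 42)
study <- generate_study(design)      # tibble: 26 x 2 x 2 = 104 recordings

cfg <- pipeline_config(epoch_length = 5, half_bandwidth = 1,
                       grid = seq(0.2, 0.6, 0.1), n_null = 20,
                       preprocess = FALSE, seed = 42)
result <- run_pipeline(study, cfg)
result
#> <eeg_study_result> 104 recordings, 26 subjects (config 7ac70990, seed 42)
#> <eeg_comparison> 175 cells tested at alpha = 0.05; 22 significant
#> # A tibble: 14 x 6
#>    side  band  metric direction n_cells sparsity_ranges
#>    <chr> <fct> <fct>  <chr>       <int> <chr>
#>  1 left  delta Lp     up              1 0.20
#>  2 left  theta Cp     down            1 0.20
#>  3 left  theta Eg     up              2 0.20-0.30
#>  4 left  theta Eloc   down            1 0.20
#>  5 left  alpha Cp     up              1 0.20
#>  6 left  alpha Lp     up              1 0.20
#>  7 left  alpha Eloc   up              2 0.20-0.30
#>  8 left  alpha gamma  up              3 0.20-0.40
#>  9 left  alpha lambda up              3 0.20-0.40
#> 10 left  alpha sigma  up              3 0.20-0.40
#> 11 left  beta  lambda up              1 0.20
#> 12 left  gamma Lp     up              1 0.20
#> 13 left  gamma lambda up              1 0.20
#> 14 left  gamma sigma  down            1 0.20
```

The summary reads like the headline finding such a study reports: the
injected alpha-band effect surfaces as a **significant increase of alpha-band
clustering (Cp) and small-worldness (sigma) in the active arm relative to
sham** — the sigma increase over a contiguous sparsity range — while the
other bands show only isolated flags concentrated at the unstable sparse end
of the grid (the vignette explains why flags isolated at sparsity 0.2
deserve skepticism). The cell-level map is a tibble:

```r
tidy(result) |>
  filter(band == "alpha", metric %in% c("Cp", "sigma"), significant) |>
  select(band, metric, sparsity, t, p, mean_active, mean_sham)
#> # A tibble: 4 x 7
#>   band  metric sparsity     t        p mean_active mean_sham
#>   <fct> <fct>     <dbl> <dbl>    <dbl>       <dbl>     <dbl>
#> 1 alpha Cp          0.2  3.47 1.92e- 3       0.469    0.141
#> 2 alpha sigma       0.2 11.4  2.04e-11       1.64     0.216
#> 3 alpha sigma       0.3  4.15 3.35e- 4       0.477    0.0836
#> 4 alpha sigma       0.4  2.07 4.93e- 2       0.114    0.0366
```

`t` and `p` come from the paired t-test on within-subject normalized
changes, and `mean_active`/`mean_sham` are the arm means of
(post − pre)/pre — e.g. 0.477 means a 48% increase of alpha-band sigma after
active stimulation against an 8% drift under sham. Plots:

```r
autoplot(result)                              # significance tile map
plot_change_curves(result, "alpha", "Cp")     # active vs sham curves, starred
plot_band_adjacency(band_connectivity(study$recording[[2]],
                                      epoch_length = 5, half_bandwidth = 1))
```

A thin CLI over the same functions lives in `inst/cli/eegraph`
(`simulate`, `preprocess`, `connectivity`, `metrics`, `compare`, `run`).

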